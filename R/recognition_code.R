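# Random-forest recognition code: per-finger base-preference regression
# from specificity residues, with or without boundary-pair covariates;
# PWM assembly, baseline merging, register alignment and cross-validated
# comparison of the 4-feature and 6-feature models.

# ordered pos1_A..pos1_T, pos2_A.. etc.
RESPONSE_NAMES <- paste(rep(paste0("pos", 1:4), each = 4),
                        rep(BASES, 4), sep = "_")

COVARIATE_LEVELS <- list(
  aa_p6 = AA20, aa_p3 = AA20, aa_m1 = AA20, aa_p2 = AA20,
  plus9_prev = c(AA20, "NONE"), minus2 = AA20)

.finger_block_start <- function(i, n) 3L * (n - i) + 1L

.case_core_pwm <- function(case) {
  p <- case$pwm
  reg <- case$register
  if (is.null(reg)) reg <- list(offset = 0L, orientation = "forward")
  if (identical(reg$orientation, "revcomp")) {
    core_len <- 3L * length(case$array$fingers) + 1L
    p <- revcomp_pwm(p)
    reg$offset <- ncol(p$mat) - reg$offset - core_len
  }
  list(pwm = p, offset = as.integer(reg$offset))
}

.array_covariates <- function(array) {
  n <- length(array$fingers)
  d <- data.frame(
    aa_p6 = vapply(array$fingers, function(f) f$helix_map[["+6"]], ""),
    aa_p3 = vapply(array$fingers, function(f) f$helix_map[["+3"]], ""),
    aa_m1 = vapply(array$fingers, function(f) f$helix_map[["-1"]], ""),
    aa_p2 = vapply(array$fingers, function(f) f$helix_map[["+2"]], ""),
    plus9_prev = c("NONE", vapply(array$fingers[-n],
                                  function(f) f$helix_map[["+9"]], "")),
    minus2 = vapply(array$fingers, function(f) f$helix_map[["-2"]], ""),
    stringsAsFactors = FALSE)
  for (nm in names(COVARIATE_LEVELS))
    d[[nm]] <- factor(d[[nm]], levels = COVARIATE_LEVELS[[nm]])
  d
}

#' Build a recognition-code training set from registered gold-standard cases
#'
#' One training example per finger. The responses are the finger's four
#' motif-strand base columns read off the experimental PWM at the finger's
#' registered position: the 5' triplet base (contacted by +6), the middle
#' base (+3), the 3' triplet base (-1) and the subsite-overlap base (+2,
#' already on the motif strand). Covariates are the four specificity
#' residues, plus -- when `with_boundary` -- residue +9 of the preceding
#' finger (a distinguished `NONE` level for the N-terminal finger) and -2
#' of the subject finger.
#'
#' @param gold List of cases, each `list(array = zf_array, pwm = pwm,
#'   register = list(offset, orientation))`; `offset` is the number of
#'   experimental columns 5' of the 3N+1 core (0 if unpadded). Cases with
#'   an unresolvable register (core falling outside the PWM) are skipped
#'   with a message.
#' @param with_boundary Include the two boundary covariates (default TRUE).
#' @return List with `covariates` (data.frame of factors), `responses`
#'   (n x 16 matrix, blocks `pos1..pos4` x `A,C,G,T`), `case` and `finger`
#'   index vectors, and `with_boundary`.
#' @export
make_training_set <- function(gold, with_boundary = TRUE) {
  cov_list <- list(); resp_list <- list(); case_id <- c(); finger_id <- c()
  for (ci in seq_along(gold)) {
    case <- gold[[ci]]
    n <- length(case$array$fingers)
    core <- .case_core_pwm(case)
    core_cols <- core$offset + seq_len(3L * n + 1L)
    if (core$offset < 0L || max(core_cols) > ncol(core$pwm$mat)) {
      message("case ", ci, ": unresolved register, skipped")
      next
    }
    covs <- .array_covariates(case$array)
    resp <- matrix(NA_real_, nrow = n, ncol = 16L,
                   dimnames = list(NULL, RESPONSE_NAMES))
    for (i in seq_len(n)) {
      s <- .finger_block_start(i, n)
      block <- core$pwm$mat[, core$offset + s + 0:3, drop = FALSE]
      resp[i, ] <- as.vector(block)
    }
    cov_list[[length(cov_list) + 1L]] <- covs
    resp_list[[length(resp_list) + 1L]] <- resp
    case_id <- c(case_id, rep(ci, n))
    finger_id <- c(finger_id, seq_len(n))
  }
  covariates <- do.call(rbind, cov_list)
  if (!with_boundary)
    covariates <- covariates[, c("aa_p6", "aa_p3", "aa_m1", "aa_p2"),
                             drop = FALSE]
  list(covariates = covariates, responses = do.call(rbind, resp_list),
       case = case_id, finger = finger_id, with_boundary = with_boundary)
}

#' Train the random-forest recognition code
#'
#' Fits one random-forest regression (default 2000 trees, bias correction
#' on) per response -- 16 in total, one for each of the four motif
#' positions times the four bases -- on categorical residue covariates.
#' Deterministic given the seed. A zero-variance response yields a
#' degenerate regressor returning the constant.
#'
#' @param examples Output of [make_training_set()].
#' @param n_trees Trees per forest (default 2000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param corr_bias Apply the regression bias correction (default TRUE).
#' @param mtry Covariates sampled per split. The default, half the
#'   feature count, keeps the chance that a split's candidate set
#'   contains the one relevant residue equal (1/2) across the 4- and
#'   6-feature schemas, so model comparisons are not confounded by the
#'   feature-subsampling rate.
#' @param nodesize Minimum terminal-node size (default 1: individual
#'   residue-by-mode cells hold only a handful of training fingers, and
#'   larger leaves average across modes).
#' @return A `zf_recognition_model`.
#' @export
train_recognition_model <- function(examples, n_trees = 2000L, seed = 1L,
                                    corr_bias = TRUE,
                                    mtry = NULL, nodesize = 1L) {
  covs <- examples$covariates
  if (nrow(unique(covs)) < 2L)
    stop("need at least 2 distinct covariate patterns")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(covs) / 2))
  resp <- examples$responses
  observed <- lapply(covs, function(col) unique(as.character(col)))
  forests <- withr_seed(seed, lapply(RESPONSE_NAMES, function(rn) {
    y <- resp[, rn]
    if (sd(y) == 0) return(list(constant = y[1]))
    suppressWarnings(
      randomForest::randomForest(x = covs, y = y, ntree = n_trees,
                                 mtry = mtry, nodesize = nodesize,
                                 corr.bias = corr_bias))
  }))
  names(forests) <- RESPONSE_NAMES
  structure(list(forests = forests, features = names(covs),
                 observed = observed, n_trees = n_trees, seed = seed,
                 corr_bias = corr_bias,
                 with_boundary = examples$with_boundary),
            class = "zf_recognition_model")
}

#' @export
print.zf_recognition_model <- function(x, ...) {
  cat(sprintf("zf_recognition_model: %d covariates (%s), %d trees, seed %d%s\n",
              length(x$features), paste(x$features, collapse = ", "),
              x$n_trees, x$seed,
              if (x$corr_bias) ", bias-corrected" else ""))
  invisible(x)
}

# predict all fingers at once; returns list(blocks = list of 4x4
# matrices (rows A..T, cols pos1..pos4), empty = logical per finger)
.predict_finger_blocks <- function(model, covs) {
  n <- nrow(covs)
  empty <- vapply(seq_len(n), function(i)
    any(vapply(model$features, function(f)
      !(as.character(covs[i, f]) %in% model$observed[[f]]), logical(1))),
    logical(1))
  preds <- matrix(0.25, nrow = n, ncol = 16L,
                  dimnames = list(NULL, RESPONSE_NAMES))
  if (any(!empty)) {
    nd <- covs[!empty, , drop = FALSE]
    for (rn in RESPONSE_NAMES) {
      fo <- model$forests[[rn]]
      preds[!empty, rn] <- if (!is.null(fo$constant)) fo$constant
        else as.numeric(predict(fo, newdata = nd))
    }
  }
  blocks <- lapply(seq_len(n), function(i) {
    block <- matrix(preds[i, ], nrow = 4,
                    dimnames = list(BASES, paste0("pos", 1:4)))
    if (empty[i]) return(block)
    block <- pmin(pmax(block, 0), 1)
    cs <- colSums(block)
    for (j in seq_len(4))
      block[, j] <- if (cs[j] > 0) block[, j] / cs[j] else rep(0.25, 4)
    block
  })
  list(blocks = blocks, empty = empty)
}

#' Predict a binding motif for a zinc-finger array
#'
#' Per-finger four-position predictions are assembled into a motif of
#' length 3N+1 on the motif strand, with fingers mapped N-to-C onto
#' 3'-to-5' triplets (the 5'-most triplet belongs to the C-terminal
#' finger) and the +2-derived subsite-overlap prediction of finger i
#' averaged with the +6-derived prediction of finger i-1 at the shared
#' column. Fingers whose covariate pattern contains a residue unseen in
#' training produce uniform (zero-information) columns, recorded in the
#' `empty_columns` attribute for [merge_with_baseline()].
#'
#' @param array A `zf_array` (single-finger arrays give a 4-column PWM).
#' @param model A `zf_recognition_model`.
#' @return A `pwm` with attribute `empty_columns` (integer vector).
#' @export
predict_array_pwm <- function(array, model) {
  stopifnot(inherits(array, "zf_array"),
            inherits(model, "zf_recognition_model"))
  n <- length(array$fingers)
  if (n < 1L) stop("array has no fingers")
  covs <- .array_covariates(array)[, model$features, drop = FALSE]
  pb <- .predict_finger_blocks(model, covs)
  .assemble_pwm(pb$blocks, pb$empty, paste0(array$protein_id, "_pred"),
                meta = list(model_features = model$features))
}

# assemble per-finger 4x4 blocks (pos1..4 = +6, +3, -1, +2-overlap, motif
# strand) into the 3N+1-column motif with overlap averaging
.assemble_pwm <- function(blocks, empty, id, meta = list()) {
  n <- length(blocks)
  L <- 3L * n + 1L
  acc <- matrix(0, 4, L)
  cnt <- integer(L)
  informative <- logical(L)
  for (i in seq_len(n)) {
    s <- .finger_block_start(i, n)
    for (j in 0:3) {
      acc[, s + j] <- acc[, s + j] + blocks[[i]][, j + 1L]
      cnt[s + j] <- cnt[s + j] + 1L
      if (!empty[i]) informative[s + j] <- TRUE
    }
  }
  mat <- sweep(acc, 2, cnt, "/")
  mat <- sweep(mat, 2, colSums(mat), "/")
  out <- pwm(mat, id = id, meta = meta)
  attr(out, "empty_columns") <- which(!informative)
  out
}

# predict PWMs for several cases with one predict pass per response
.predict_case_pwms <- function(model, cases) {
  covs <- do.call(rbind, lapply(cases, function(c)
    .array_covariates(c$array)[, model$features, drop = FALSE]))
  lens <- vapply(cases, function(c) length(c$array$fingers), integer(1))
  pb <- .predict_finger_blocks(model, covs)
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  lapply(seq_along(cases), function(ci) {
    idx <- starts[ci]:stops[ci]
    .assemble_pwm(pb$blocks[idx], pb$empty[idx],
                  paste0(cases[[ci]]$array$protein_id, "_pred"))
  })
}

#' Merge a mode-aware prediction with a baseline recognition-code PWM
#'
#' Columns of the prediction that are empty (untrained covariate pattern)
#' or carry information content below `ic_threshold` bits are replaced by
#' the corresponding baseline column; all others are kept.
#'
#' @param predicted A `pwm` from [predict_array_pwm()] (its
#'   `empty_columns` attribute, if present, marks untrained columns).
#' @param baseline A `pwm` of equal length and register.
#' @param ic_threshold Bits (default 0.3).
#' @return A `pwm`; attribute `replaced_columns` lists the substitutions.
#' @export
merge_with_baseline <- function(predicted, baseline, ic_threshold = 0.3) {
  stopifnot(inherits(predicted, "pwm"), inherits(baseline, "pwm"))
  if (ncol(predicted$mat) != ncol(baseline$mat))
    stop("predicted and baseline PWMs must have equal length")
  ic <- pwm_ic(predicted)
  empty <- attr(predicted, "empty_columns")
  replace <- ic < ic_threshold
  if (!is.null(empty)) replace[empty] <- TRUE
  mat <- predicted$mat
  mat[, replace] <- baseline$mat[, replace, drop = FALSE]
  out <- pwm(mat, id = predicted$id, meta = predicted$meta)
  attr(out, "replaced_columns") <- which(replace)
  out
}

#' Align a predicted PWM to an experimental motif to identify the register
#'
#' Scans every offset with at least 3 overlapping columns, in both the
#' forward orientation and the reverse complement of the prediction, and
#' returns the placement maximizing the mean per-column Pearson
#' correlation (columns where either PWM is uniform are skipped in the
#' mean). Ties prefer forward orientation, then the smallest absolute
#' offset.
#'
#' @param predicted,experimental `pwm` objects with >= 3 columns.
#' @return List with `offset` (predicted column j aligns experimental
#'   column j + offset), `orientation` (`"forward"` or `"revcomp"`), and
#'   `similarity` (mean per-column Pearson r).
#' @export
align_register <- function(predicted, experimental) {
  stopifnot(inherits(predicted, "pwm"), inherits(experimental, "pwm"))
  Lp <- ncol(predicted$mat); Le <- ncol(experimental$mat)
  if (Lp < 3L || Le < 3L) stop("both PWMs need at least 3 columns")
  E <- experimental$mat
  best <- NULL
  for (orientation in c("forward", "revcomp")) {
    P <- if (orientation == "forward") predicted$mat
         else revcomp_pwm(predicted)$mat
    for (offset in (3L - Lp):(Le - 3L)) {
      js <- seq_len(Lp)
      js <- js[js + offset >= 1L & js + offset <= Le]
      if (length(js) < 3L) next
      rs <- vapply(js, function(j) {
        pj <- P[, j]; ej <- E[, j + offset]
        if (sd(pj) == 0 || sd(ej) == 0) return(NA_real_)
        cor(pj, ej)
      }, numeric(1))
      rs <- rs[!is.na(rs)]
      if (length(rs) == 0L) next
      score <- mean(rs)
      cand <- list(offset = offset, orientation = orientation,
                   similarity = score)
      if (is.null(best) || score > best$similarity + 1e-12) best <- cand
      # ties: forward first (outer loop order), then smallest |offset|
      else if (abs(score - best$similarity) <= 1e-12 &&
               orientation == best$orientation &&
               abs(offset) < abs(best$offset)) best <- cand
    }
  }
  if (is.null(best)) stop("no valid overlap between the two PWMs")
  best
}

#' Cross-validated comparison of the 4- and 6-feature recognition codes
#'
#' Folds partition whole arrays (never single fingers, so a held-out
#' finger's neighbours are never in training), stratified by array length.
#' For each held-out case both models are trained on the remaining arrays
#' and the predicted motif is registered against the experimental PWM with
#' [align_register()]; the per-case similarity is the registered mean
#' per-column Pearson r. Returns both similarity vectors and a paired
#' one-sided Wilcoxon signed-rank test of 6-feature > 4-feature.
#'
#' @param gold List of registered cases as in [make_training_set()].
#' @param k Number of folds (default 10; must not exceed the number of
#'   arrays).
#' @param seed Integer seed controlling fold assignment and training.
#' @param n_trees Trees per forest.
#' @param corr_bias Passed to [train_recognition_model()].
#' @return List with `similarity_4`, `similarity_6` (per-case, in input
#'   order), `p_value`, `folds`.
#' @export
crossvalidate_compare <- function(gold, k = 10L, seed = 1L, n_trees = 2000L,
                                  corr_bias = TRUE) {
  n <- length(gold)
  if (k > n) stop("k exceeds the number of arrays")
  lens <- vapply(gold, function(g) length(g$array$fingers), integer(1))
  ord <- withr_seed(seed, order(lens, runif(n)))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  sim4 <- sim6 <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    train_cases <- gold[folds != f]
    m4 <- train_recognition_model(make_training_set(train_cases, FALSE),
                                  n_trees = n_trees, seed = seed + 1000L * f,
                                  corr_bias = corr_bias)
    m6 <- train_recognition_model(make_training_set(train_cases, TRUE),
                                  n_trees = n_trees, seed = seed + 1000L * f,
                                  corr_bias = corr_bias)
    held <- which(folds == f)
    p4 <- .predict_case_pwms(m4, gold[held])
    p6 <- .predict_case_pwms(m6, gold[held])
    for (hi in seq_along(held)) {
      ci <- held[hi]
      sim4[ci] <- align_register(p4[[hi]], gold[[ci]]$pwm)$similarity
      sim6[ci] <- align_register(p6[[hi]], gold[[ci]]$pwm)$similarity
    }
  }
  p <- if (all(sim6 == sim4)) 1 else
    suppressWarnings(wilcox.test(sim6, sim4, paired = TRUE,
                                 alternative = "greater")$p.value)
  list(similarity_4 = sim4, similarity_6 = sim6, p_value = p, folds = folds)
}

# File-based gold-standard assembly ------------------------------------------

#' Pair finger arrays with experimental motifs into gold-standard cases
#'
#' Matches arrays (as written by [write_zf_arrays()]) with motifs by id.
#' The register is resolved when the motif length minus the 3N+1 core is
#' an even non-negative number of flank columns (offset = half of it, on
#' the motif strand, forward orientation); other cases are skipped with a
#' message, mirroring the exclusion of indeterminable registers from
#' gold-standard compilation.
#'
#' @param arrays_file TSV of arrays ([read_zf_arrays()] format).
#' @param motif_file Motif file whose ids equal the protein ids.
#' @param format Motif format for [read_pwm()].
#' @return List of cases `list(array, pwm, register)` usable by
#'   [make_training_set()] and [crossvalidate_compare()].
#' @export
gold_cases_from_files <- function(arrays_file, motif_file,
                                  format = "meme") {
  arrays <- read_zf_arrays(arrays_file)
  motifs <- read_pwm(motif_file, format = format)
  names(motifs) <- vapply(motifs, `[[`, character(1), "id")
  out <- list()
  for (a in arrays) {
    p <- motifs[[a$protein_id]]
    if (is.null(p)) next
    core <- 3L * length(a$fingers) + 1L
    extra <- ncol(p$mat) - core
    if (extra < 0L || extra %% 2L != 0L) {
      message(a$protein_id, ": indeterminable register, skipped")
      next
    }
    out[[length(out) + 1L]] <- list(array = a, pwm = p,
                                    register = list(offset = extra %/% 2L,
                                                    orientation = "forward"))
  }
  out
}
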