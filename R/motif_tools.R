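# PWM container, motif I/O (MEME minimal, JASPAR), occupancy affinity
# scoring, motif similarity, representative selection and Affinity
# Propagation redundancy clustering.

#' Construct a position weight matrix
#'
#' @param mat Numeric matrix, 4 rows (A, C, G, T) by motif positions
#'   (5' to 3'). Columns must be non-negative and sum to 1 (within 1e-6;
#'   they are renormalized exactly).
#' @param id Motif identifier.
#' @param pseudocount Pseudocount used if the matrix was derived from
#'   counts (metadata only).
#' @param meta Optional named list of source metadata.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, id = "motif", pseudocount = NA_real_, meta = list()) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 1L) stop("PWM must have at least one column")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("PWM entries must be finite and non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-4))
    stop("PWM columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  mat <- sweep(mat, 2, cs, "/")
  dimnames(mat) <- list(BASES, NULL)
  structure(list(mat = mat, id = id, pseudocount = pseudocount, meta = meta),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d columns\n", x$id, ncol(x$mat)))
  print(round(x$mat, 3))
  invisible(x)
}

#' @export
ncol.pwm <- function(x) ncol(x$mat)

#' Reverse complement of a PWM
#'
#' Reverses column order and complements the base order (A<->T, C<->G),
#' i.e. the motif as read on the opposite strand.
#'
#' @param x A `pwm`.
#' @return A `pwm`.
#' @export
revcomp_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- x$mat[COMPLEMENT_IDX, rev(seq_len(ncol(x$mat))), drop = FALSE]
  dimnames(m) <- list(BASES, NULL)
  pwm(m, id = x$id, pseudocount = x$pseudocount, meta = x$meta)
}

#' Per-column information content of a PWM
#'
#' @param x A `pwm`.
#' @return Numeric vector of bits per column: `2 + sum(p * log2(p))`.
#' @export
pwm_ic <- function(x) {
  stopifnot(inherits(x, "pwm"))
  apply(x$mat, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

# Motif file formats ---------------------------------------------------------

#' Read motifs from a MEME-minimal or JASPAR file
#'
#' JASPAR count matrices are converted to probabilities with a pseudocount
#' of 0.5 added to every cell.
#'
#' @param file Path.
#' @param format `"meme"` or `"jaspar"`.
#' @param pseudocount Per-cell pseudocount applied to count matrices.
#' @return List of `pwm` objects (possibly empty).
#' @export
read_pwm <- function(file, format = c("meme", "jaspar"), pseudocount = 0.5) {
  format <- match.arg(format)
  lines <- readLines(file)
  if (format == "meme") .read_meme(lines) else .read_jaspar(lines, pseudocount)
}

.read_meme <- function(lines) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^MOTIF\\s+", lines[i])) {
      id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
      j <- i + 1L
      while (j <= n && !grepl("letter-probability matrix", lines[j])) {
        if (grepl("^MOTIF\\s+", lines[j]))
          stop("malformed MEME record: motif without matrix at line ", i)
        j <- j + 1L
      }
      if (j > n) stop("malformed MEME record: motif without matrix at line ", i)
      w <- suppressWarnings(
        as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
      if (is.na(w)) stop("cannot parse matrix width at line ", j)
      rows <- matrix(NA_real_, nrow = w, ncol = 4)
      k <- j
      got <- 0L
      while (got < w) {
        k <- k + 1L
        if (k > n) stop("truncated matrix for motif ", id, " at line ", j)
        tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
        if (length(tok) == 0L || tok[1] == "") next
        vals <- suppressWarnings(as.numeric(tok))
        if (length(vals) != 4L || any(is.na(vals)))
          stop("malformed matrix row at line ", k)
        if (any(vals < 0)) stop("negative entry at line ", k)
        got <- got + 1L
        rows[got, ] <- vals
      }
      out[[length(out) + 1L]] <- pwm(t(rows), id = id)
      i <- k + 1L
    } else i <- i + 1L
  }
  out
}

.read_jaspar <- function(lines, pseudocount) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^>", lines[i])) {
      id <- strsplit(trimws(sub("^>\\s*", "", lines[i])), "\\s+")[[1]][1]
      vals <- list()
      for (b in BASES) {
        j <- i + match(b, BASES)
        if (j > n) stop("truncated JASPAR record at line ", i)
        ln <- lines[j]
        if (!grepl(paste0("^\\s*", b), ln))
          stop("expected base ", b, " row at line ", j)
        body <- gsub("[][]", " ", sub(paste0("^\\s*", b), "", ln))
        v <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
        if (any(is.na(v))) stop("malformed JASPAR row at line ", j)
        if (any(v < 0)) stop("negative entry at line ", j)
        vals[[b]] <- v
      }
      lens <- lengths(vals)
      if (length(unique(lens)) != 1L)
        stop("unequal row lengths in JASPAR record at line ", i)
      counts <- do.call(rbind, vals)
      # integer-valued matrices are counts and get the pseudocount;
      # fractional matrices are probabilities and are only renormalized
      is_counts <- all(abs(counts - round(counts)) < 1e-9)
      pc <- if (is_counts) pseudocount else 0
      probs <- sweep(counts + pc, 2, colSums(counts + pc), "/")
      out[[length(out) + 1L]] <- pwm(probs, id = id,
                                     pseudocount = if (is_counts) pc else
                                       NA_real_)
      i <- i + 5L
    } else i <- i + 1L
  }
  out
}

#' Write motifs to a MEME-minimal or JASPAR file
#'
#' Probabilities are written with 6 decimals; the round trip through
#' [read_pwm()] is lossless to that precision. JASPAR output stores the
#' probabilities directly (they re-read as "counts" that renormalize to the
#' same columns up to the pseudocount).
#'
#' @param pwms List of `pwm` objects (a single `pwm` is accepted).
#' @param file Output path.
#' @param format `"meme"` or `"jaspar"`.
#' @export
write_pwm <- function(pwms, file, format = c("meme", "jaspar")) {
  format <- match.arg(format)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (format == "meme") {
    lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "")
    for (p in pwms) {
      lines <- c(lines, paste("MOTIF", p$id),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         ncol(p$mat)),
                 apply(p$mat, 2, function(col)
                   paste(sprintf("%.6f", col), collapse = "  ")),
                 "")
    }
  } else {
    lines <- unlist(lapply(pwms, function(p) {
      c(paste0(">", p$id),
        vapply(seq_len(4), function(r)
          sprintf("%s  [ %s ]", BASES[r],
                  paste(sprintf("%.6f", p$mat[r, ]), collapse = " ")),
          character(1)))
    }))
  }
  writeLines(lines, file)
  invisible(file)
}

# Affinity scoring -----------------------------------------------------------

.seq_to_int <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, BASES)
  if (anyNA(idx))
    stop("sequence contains ambiguous/non-ACGT base(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx
}

# Batch occupancy scorer: S is an n x L integer matrix of base indices.
# Returns the per-sequence sum over all windows and both strands of the
# product of column probabilities (method "sum"), or the maximum single
# window term (method "max").
.score_batch <- function(mat, S, method = c("sum", "max")) {
  method <- match.arg(method)
  m <- ncol(mat)
  L <- ncol(S)
  n <- nrow(S)
  if (L < m) stop("sequence shorter than motif")
  agg <- if (method == "sum") {
    function(acc, v) acc + v
  } else function(acc, v) pmax(acc, v)
  total <- if (method == "sum") numeric(n) else rep(-Inf, n)
  for (strand_mat in list(mat, mat[COMPLEMENT_IDX, rev(seq_len(m)),
                                   drop = FALSE])) {
    for (w in seq_len(L - m + 1L)) {
      v <- strand_mat[S[, w], 1L]
      if (m > 1L) for (j in 2L:m) v <- v * strand_mat[S[, w + j - 1L], j]
      total <- agg(total, v)
    }
  }
  unname(total)
}

#' Occupancy affinity score of a PWM on a DNA sequence
#'
#' The default score is the sum over all windows on both strands of the
#' product of the column probabilities for the window's bases (a
#' total-occupancy score, symmetric under reverse complement of the
#' sequence). A best-single-window variant is available via
#' `method = "max"`.
#'
#' @param x A `pwm`.
#' @param sequence DNA string (ACGT only), at least as long as the motif.
#' @param method `"sum"` (default) or `"max"`.
#' @return Non-negative numeric score.
#' @export
affinity_score <- function(x, sequence, method = c("sum", "max")) {
  stopifnot(inherits(x, "pwm"))
  idx <- .seq_to_int(sequence)
  .score_batch(x$mat, matrix(idx, nrow = 1), method = match.arg(method))
}

#' Similarity of two motifs as correlated affinity over random sequences
#'
#' Generates `n` i.i.d. uniform ACGT sequences of the given length from the
#' seed and returns the Pearson correlation of the two motifs' affinity
#' scores across them.
#'
#' @param a,b `pwm` objects.
#' @param n Number of random sequences (default 50000).
#' @param length Sequence length in bp (default 100).
#' @param seed Integer seed for the sequence draw.
#' @param method Scoring method passed to the scorer.
#' @return Pearson r, or `NA` (with a warning) if either score vector has
#'   zero variance.
#' @export
motif_similarity <- function(a, b, n = 50000L, length = 100L, seed = 1L,
                             method = "sum") {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  S <- withr_seed(seed, matrix(sample.int(4L, n * length, replace = TRUE),
                               nrow = n))
  sa <- .score_batch(a$mat, S, method = method)
  sb <- .score_batch(b$mat, S, method = method)
  if (sd(sa) == 0 || sd(sb) == 0) {
    warning("zero-variance affinity score vector; similarity undefined")
    return(NA_real_)
  }
  cor(sa, sb)
}

# run expr with a local RNG seed, restoring the global state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Representative selection and redundancy clustering -------------------------

#' Select a single representative motif for one protein
#'
#' Implements the three-branch rule used when compiling a non-redundant
#' gold-standard set: with more than two motifs, pick the motif with the
#' largest sum of similarities to the others; with exactly two motifs and a
#' characterized homolog motif, pick the one most similar to the homolog;
#' with two motifs and no homolog, pick one at random (seeded). A single
#' motif is returned as is.
#'
#' @param motifs List of `pwm` objects for one protein (length >= 1).
#' @param homolog_motif Optional `pwm` from a characterized homolog.
#' @param seed Seed for both the similarity draws and the random branch.
#' @param n,length Monte-Carlo settings forwarded to [motif_similarity()].
#' @return The selected `pwm`.
#' @export
select_representative <- function(motifs, homolog_motif = NULL, seed = 1L,
                                  n = 50000L, length = 100L) {
  k <- base::length(motifs)
  if (k < 1L) stop("need at least one motif")
  if (k == 1L) return(motifs[[1]])
  if (k == 2L) {
    if (!is.null(homolog_motif)) {
      sims <- vapply(motifs, motif_similarity, numeric(1), b = homolog_motif,
                     n = n, length = length, seed = seed)
      return(motifs[[which.max(sims)]])
    }
    return(motifs[[withr_seed(seed, sample.int(2L, 1L))]])
  }
  sim <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sim[i, j] <- sim[j, i] <- motif_similarity(motifs[[i]], motifs[[j]],
                                               n = n, length = length,
                                               seed = seed)
  }
  sums <- rowSums(sim) - 1
  motifs[[which.max(sums)]]
}

#' Affinity Propagation clustering of a motif similarity matrix
#'
#' Frey-Dueck affinity propagation on a square symmetric similarity matrix
#' (Pearson r between motifs), with the diagonal preference set to the
#' median off-diagonal similarity, damping 0.9 and at most 1000 iterations.
#' Exemplars are members of the input set. If message passing does not
#' converge, every motif becomes its own exemplar and the result is
#' flagged.
#'
#' @param sim Square symmetric numeric matrix (row/col names optional).
#' @param preference Diagonal preference; default median off-diagonal
#'   similarity.
#' @param damping Damping factor in (0.5, 1).
#' @param maxit Maximum iterations.
#' @param convits Stop after the exemplar set is stable this many
#'   iterations.
#' @return List with `exemplars` (integer indices), `assignments`
#'   (exemplar index per motif), `converged` (logical) and `iterations`.
#' @export
cluster_exemplars <- function(sim, preference = NULL, damping = 0.9,
                              maxit = 1000L, convits = 50L) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n != ncol(sim)) stop("similarity matrix must be square")
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix must be symmetric")
  if (n == 1L)
    return(list(exemplars = 1L, assignments = 1L, converged = TRUE,
                iterations = 0L))
  off <- sim[upper.tri(sim)]
  if (max(off) - min(off) < 1e-12) {
    # structureless similarity (all off-diagonal entries equal): no
    # grouping is supported, so every motif is its own exemplar
    return(list(exemplars = seq_len(n), assignments = seq_len(n),
                converged = TRUE, iterations = 0L))
  }
  if (is.null(preference))
    preference <- median(off)
  S <- sim
  diag(S) <- preference
  # tiny deterministic jitter to break exact ties (standard AP practice)
  jit <- withr_seed(7L, matrix(runif(n * n), n, n))
  S <- S + 1e-12 * jit
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  last <- integer(0)
  it <- 0L
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rmax <- matrix(max1, n, n)
    Rmax[cbind(seq_len(n), which1)] <- max2
    Rnew <- S - Rmax
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last) && length(ex) > 0L) stable <- stable + 1L
    else stable <- 0L
    last <- ex
    if (stable >= convits) { converged <- TRUE; break }
  }
  if (!converged || length(last) == 0L) {
    return(list(exemplars = seq_len(n), assignments = seq_len(n),
                converged = FALSE, iterations = it))
  }
  assignments <- vapply(seq_len(n), function(i) {
    if (i %in% last) return(i)
    last[which.max(S[i, last])]
  }, integer(1))
  list(exemplars = last, assignments = assignments, converged = TRUE,
       iterations = it)
}
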