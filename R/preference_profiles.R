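# Mode table (boundary pair -> mode) and mode-resolved residue-to-base
# preference profiles built from gold-standard fingers with known
# triplet-resolved base preferences.

#' Construct a boundary-pair -> mode table
#'
#' Each ordered (+9, -2) residue pair maps to at most one binding mode;
#' a duplicated pair mapped to two different modes is a construction-time
#' error.
#'
#' @param plus9,minus2 Character vectors of boundary residues (one-letter).
#' @param mode Integer/character mode labels.
#' @param provenance Optional per-entry provenance notes.
#' @return A `mode_table` data.frame with columns `plus9`, `minus2`,
#'   `mode`, `provenance`.
#' @export
mode_table <- function(plus9, minus2, mode, provenance = "") {
  stopifnot(length(plus9) == length(minus2),
            length(plus9) == length(mode))
  bad <- setdiff(unique(c(plus9, minus2)), AA20)
  if (length(bad)) stop("non-canonical amino acid(s): ",
                        paste(bad, collapse = ", "))
  key <- paste(plus9, minus2)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- tapply(mode, key, function(m) length(unique(m)) > 1L)
    if (any(conflict))
      stop("boundary pair(s) mapped to more than one mode: ",
           paste(names(conflict)[conflict], collapse = ", "))
    keep <- !dup
    plus9 <- plus9[keep]; minus2 <- minus2[keep]; mode <- mode[keep]
    if (length(provenance) > 1L) provenance <- provenance[keep]
  }
  structure(data.frame(plus9 = plus9, minus2 = minus2, mode = mode,
                       provenance = provenance, stringsAsFactors = FALSE),
            class = c("mode_table", "data.frame"))
}

#' Read / write a mode table as TSV
#'
#' Columns: `plus9`, `minus2`, `mode`, `provenance`.
#'
#' @param file Path.
#' @return A `mode_table`.
#' @export
read_mode_table <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  prov <- if ("provenance" %in% names(d)) d$provenance else ""
  mode_table(d$plus9, d$minus2, d$mode, prov)
}

#' @rdname read_mode_table
#' @param table A `mode_table`.
#' @export
write_mode_table <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Look up the binding mode of a boundary pair
#'
#' Exact lookup, no nearest-neighbour fallback; an absent pair returns
#' `"UNKNOWN"` (a value, not an error).
#'
#' @param pair Character vector `c(plus9, minus2)`.
#' @param table A `mode_table`.
#' @return The mode label (as character) or `"UNKNOWN"`.
#' @export
assign_mode <- function(pair, table) {
  hit <- which(table$plus9 == pair[1] & table$minus2 == pair[2])
  if (length(hit) == 0L) return("UNKNOWN")
  as.character(table$mode[hit[1]])
}

# Profiles -------------------------------------------------------------------

#' A single gold-standard finger record for profile building
#'
#' @param helix Named character vector with at least the four specificity
#'   positions `+6, +3, -1, +2` (a full `zf_finger` helix map works).
#' @param plus9_prev Residue at +9 of the preceding finger, or `NA` for an
#'   N-terminal finger (mode then UNKNOWN).
#' @param columns 4 x 4 numeric matrix, rows A,C,G,T, columns named
#'   `+6, +3, -1, +2`: the finger's experimentally determined base
#'   preference at each specificity position. The `+2` column is given on
#'   the contacted strand (it is complemented to the motif strand at
#'   storage time).
#' @return A `finger_record` list.
#' @export
finger_record <- function(helix, plus9_prev, columns) {
  columns <- as.matrix(columns)
  stopifnot(all(SPEC_POSITIONS %in% names(helix)),
            nrow(columns) == 4L,
            all(SPEC_POSITIONS %in% colnames(columns)))
  cs <- colSums(columns[, SPEC_POSITIONS])
  if (any(abs(cs - 1) > 1e-6)) stop("base columns must sum to 1")
  structure(list(helix = helix[SPEC_POSITIONS], plus9_prev = plus9_prev,
                 columns = columns[, SPEC_POSITIONS, drop = FALSE]),
            class = "finger_record")
}

.empty_profile_arrays <- function(modes) {
  lab <- c("ALL", modes)
  freq <- array(NA_real_,
                dim = c(length(lab), length(SPEC_POSITIONS), length(AA20), 4),
                dimnames = list(lab, SPEC_POSITIONS, AA20, BASES))
  support <- array(0L,
                   dim = c(length(lab), length(SPEC_POSITIONS), length(AA20)),
                   dimnames = list(lab, SPEC_POSITIONS, AA20))
  list(freq = freq, support = support)
}

#' Build mode-resolved residue-to-base preference profiles
#'
#' Groups gold-standard fingers by the binding mode implied by their
#' boundary pair (+9 of the preceding finger, -2 of the subject finger)
#' and, for each (mode, specificity position, amino acid) cell, records
#' the mean base-probability vector and the number of contributing
#' fingers. An `ALL` profile over every finger (including fingers with
#' UNKNOWN mode) is always produced. The `+2` column is complemented
#' (A<->T, C<->G) before storage so that profiles display the
#' motif-strand base rather than the typically cross-stranded contact.
#'
#' @param fingers List of [finger_record()] objects; each must also carry
#'   the subject finger's own `-2` residue inside `helix` if mode lookup
#'   is to succeed -- pass `minus2` explicitly via the record's helix map
#'   (position `-2`) or rely on `helix["-2"]` if present.
#' @param table A `mode_table`.
#' @return A `preference_profile` with arrays `freq[mode, position, aa,
#'   base]` and `support[mode, position, aa]`; unpopulated cells are `NA`
#'   frequency / zero support.
#' @export
build_profiles <- function(fingers, table) {
  modes <- as.character(sort(unique(table$mode)))
  arrs <- .empty_profile_arrays(modes)
  sums <- arrs$freq
  sums[] <- 0
  support <- arrs$support
  for (fr in fingers) {
    m <- "UNKNOWN"
    minus2 <- fr$minus2
    if (is.null(minus2)) minus2 <- NA
    if (!is.na(fr$plus9_prev) && !is.na(minus2))
      m <- assign_mode(c(fr$plus9_prev, minus2), table)
    groups <- "ALL"
    if (m != "UNKNOWN" && m %in% modes) groups <- c("ALL", m)
    cols <- fr$columns
    cols[, "+2"] <- cols[COMPLEMENT_IDX, "+2"]
    for (g in groups) for (pos in SPEC_POSITIONS) {
      aa <- fr$helix[[pos]]
      if (!aa %in% AA20) next
      sums[g, pos, aa, ] <- sums[g, pos, aa, ] + cols[, pos]
      support[g, pos, aa] <- support[g, pos, aa] + 1L
    }
  }
  freq <- sums
  freq[] <- NA_real_
  pop <- which(support > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(pop))) {
    i <- pop[r, ]
    freq[i[1], i[2], i[3], ] <- sums[i[1], i[2], i[3], ] /
      support[i[1], i[2], i[3]]
  }
  structure(list(freq = freq, support = support, modes = modes),
            class = "preference_profile")
}

#' @export
print.preference_profile <- function(x, ...) {
  cat(sprintf("preference_profile: modes {%s}, %d populated cell(s)\n",
              paste(x$modes, collapse = ", "), sum(x$support > 0)))
  invisible(x)
}

# internal: fingers in build_profiles need the -2 residue; convenience
# wrapper turning a zf_array + per-finger columns into records
#' Turn a zinc-finger array plus per-finger base columns into records
#'
#' @param array A `zf_array`.
#' @param columns_list List (length = n fingers) of 4 x 4 matrices as in
#'   [finger_record()].
#' @return List of finger records with `plus9_prev` taken from the actual
#'   preceding finger (`NA` for finger 1) and the subject finger's `-2`
#'   attached for mode lookup.
#' @export
array_finger_records <- function(array, columns_list) {
  stopifnot(inherits(array, "zf_array"),
            length(columns_list) == length(array$fingers))
  lapply(seq_along(array$fingers), function(i) {
    f <- array$fingers[[i]]
    fr <- finger_record(f$helix_map,
                        plus9_prev = if (i == 1L) NA_character_ else
                          array$fingers[[i - 1L]]$helix_map[["+9"]],
                        columns = columns_list[[i]])
    fr$minus2 <- f$helix_map[["-2"]]
    fr
  })
}

#' Per-cell significance of mode differences in a preference profile
#'
#' For every (specificity position, amino acid) cell populated in at least
#' two modes, reconstructs per-mode base-count tables
#' (support x mean frequency, rounded) and applies a chi-square test of
#' homogeneity across modes. When any expected count is below 5 the
#' p-value is computed by Monte-Carlo simulation (seeded, 10000
#' permutations). Cells populated in fewer than two modes are flagged and
#' get `NA`.
#'
#' @param profile A `preference_profile`.
#' @param B Number of Monte-Carlo permutations.
#' @param seed Seed for the simulated p-values.
#' @return data.frame with `position`, `aa`, `n_modes`, `p_value`,
#'   `flagged`.
#' @export
profile_significance <- function(profile, B = 10000L, seed = 1L) {
  modes <- profile$modes
  rows <- list()
  for (pos in SPEC_POSITIONS) for (aa in AA20) {
    sup <- profile$support[modes, pos, aa]
    present <- modes[sup > 0]
    if (all(profile$support[, pos, aa] == 0)) next
    if (length(present) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, aa = aa, n_modes = length(present),
        p_value = NA_real_, flagged = TRUE, stringsAsFactors = FALSE)
      next
    }
    counts <- t(vapply(present, function(m)
      round(profile$support[m, pos, aa] * profile$freq[m, pos, aa, ]),
      numeric(4)))
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    p <- if (nrow(counts) < 2L || ncol(counts) < 2L) NA_real_ else {
      expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
      if (any(expected < 5)) {
        withr_seed(seed, suppressWarnings(
          chisq.test(counts, simulate.p.value = TRUE, B = B)$p.value))
      } else suppressWarnings(chisq.test(counts)$p.value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, aa = aa, n_modes = length(present), p_value = p,
      flagged = is.na(p), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Export a preference profile as a long-format table
#'
#' @param profile A `preference_profile`.
#' @param file Optional TSV path; if `NULL` the data.frame is returned.
#' @return data.frame with one row per populated (mode, position, aa):
#'   support and the four base frequencies.
#' @export
profile_to_table <- function(profile, file = NULL) {
  pop <- which(profile$support > 0, arr.ind = TRUE)
  dn <- dimnames(profile$support)
  d <- do.call(rbind, lapply(seq_len(nrow(pop)), function(r) {
    i <- pop[r, ]
    fq <- profile$freq[i[1], i[2], i[3], ]
    data.frame(mode = dn[[1]][i[1]], position = dn[[2]][i[2]],
               aa = dn[[3]][i[3]], support = profile$support[i[1], i[2], i[3]],
               A = fq[1], C = fq[2], G = fq[3], T = fq[4],
               stringsAsFactors = FALSE)
  }))
  d <- d[order(d$mode, d$position, d$aa), ]
  rownames(d) <- NULL
  if (!is.null(file)) {
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(file))
  }
  d
}

#' Finger records read off a registered gold-standard case
#'
#' Extracts each finger's four specificity columns from the case's
#' experimental PWM at the registered positions (+6, +3, -1 triplet
#' columns and the +2 subsite-overlap column, handed over on the
#' contacted strand as [build_profiles()] expects).
#'
#' @param case A gold-standard case (`array`, `pwm`, `register`).
#' @return List of finger records.
#' @export
case_finger_records <- function(case) {
  n <- length(case$array$fingers)
  offset <- case$register$offset
  cols <- lapply(seq_len(n), function(i) {
    s <- offset + 3L * (n - i) + 1L
    m <- case$pwm$mat[, s + 0:3]
    colnames(m) <- SPEC_POSITIONS
    m[, "+2"] <- m[COMPLEMENT_IDX, "+2"]
    m
  })
  array_finger_records(case$array, cols)
}
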