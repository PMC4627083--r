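# Finger detection and helix-position annotation in protein sequence.
#
# The C2H2 core is matched as C-x(2,4)-C-x(12)-H-x(3,5)-H with x drawn from
# the 20 canonical amino acids (never X). Helix positions are anchored on the
# first coordinating His = +7, so for p >= +1 the residue index is
# His - (7 - p); -1 = His - 7; -2 = His - 8 (there is no position 0); and
# +9 = His + 2, which falls between the two histidines. This reproduces the
# classical Zif268-style numbering in which the recognition helix reads
# (-1)..(+3)..(+6)H.

.zf_core_regex <- function() {
  x <- paste0("[", paste(AA20, collapse = ""), "]")
  sprintf("(C)(%s{2,4})(C)(%s{12})(H)(%s{3,5})(H)", x, x, x)
}

.check_protein_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("`sequence` must be a single character string")
  if (nchar(sequence) == 0L) return(invisible(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad) > 0L)
    stop("sequence contains non-amino-acid character(s): ",
         paste(sQuote(bad), collapse = ", "))
  invisible(sequence)
}

#' Detect C2H2 zinc fingers in a protein sequence
#'
#' Scans for non-overlapping matches of the C2H2 pattern
#' `C-x(2,4)-C-x(12)-H-x(3,5)-H` (leftmost-greedy; `X` voids a candidate
#' match) and annotates each finger with its helix-position residue map.
#'
#' @param sequence Single amino-acid string (canonical one-letter codes;
#'   `X` is tolerated but never matched inside a finger).
#' @return A list of `zf_finger` objects. Each carries:
#'   \describe{
#'     \item{index_in_array}{ordinal, N- to C-terminal}
#'     \item{residues}{the finger span, from 2 residues before the first Cys
#'       to the second His inclusive}
#'     \item{start, end}{1-based span bounds in the input sequence}
#'     \item{core_start, core_end}{bounds of the C..H coordinating core}
#'     \item{helix_map}{named character vector over positions
#'       `-2, -1, +1, +2, +3, +6, +9`}
#'     \item{coordinating}{absolute indices of the two Cys and two His}
#'     \item{his_spacer_len}{number of residues between the two His (3-5)}
#'   }
#' @examples
#' f <- detect_fingers("AAYKCPECGKSFSRSDELTRHIRTHAA")
#' f[[1]]$helix_map
#' @export
detect_fingers <- function(sequence) {
  .check_protein_sequence(sequence)
  if (nchar(sequence) == 0L) return(list())
  rx <- .zf_core_regex()
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  fingers <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    core <- substr(sequence, starts[i], starts[i] + lens[i] - 1L)
    g <- regmatches(core, regexec(rx, core, perl = TRUE))[[1]]
    # groups: C, x(2,4), C, x(12), H, x(3,5), H
    c1 <- starts[i]
    c2 <- c1 + 1L + nchar(g[3])
    h1 <- c2 + 13L
    his_spacer <- nchar(g[7])
    h2 <- h1 + his_spacer + 1L
    stopifnot(substr(sequence, h1, h1) == "H", substr(sequence, h2, h2) == "H")
    span_start <- max(1L, c1 - 2L)
    idx <- h1 + c(-8L, -7L, -6L, -5L, -4L, -1L, 2L)
    helix_map <- setNames(
      vapply(idx, function(j) substr(sequence, j, j), character(1)),
      HELIX_POSITIONS)
    fingers[[i]] <- structure(list(
      index_in_array = i,
      residues = substr(sequence, span_start, h2),
      start = span_start,
      end = h2,
      core_start = c1,
      core_end = h2,
      helix_map = helix_map,
      coordinating = c(c1, c2, h1, h2),
      his_spacer_len = his_spacer
    ), class = "zf_finger")
  }
  fingers
}

#' @export
print.zf_finger <- function(x, ...) {
  cat(sprintf("C2H2 zinc finger #%d [%d-%d], His spacer %d\n",
              x$index_in_array, x$start, x$end, x$his_spacer_len))
  cat("  span: ", x$residues, "\n", sep = "")
  cat("  helix:", paste(names(x$helix_map), x$helix_map, sep = "="), "\n")
  invisible(x)
}

#' Build a zinc-finger array from a protein sequence
#'
#' Runs [detect_fingers()] and records the inter-finger linkers: the
#' residues strictly between consecutive finger spans (a span runs from 2
#' residues before the first Cys to the second His). For tandem fingers
#' this is the classical inter-finger linker whose canonical form is the
#' 5-residue `TGEKP` sitting between the second His and the next span.
#'
#' @param protein_id Identifier for the protein.
#' @param sequence Amino-acid string.
#' @return A `zf_array` object with fields `protein_id`, `fingers`
#'   (list of `zf_finger`, N to C) and `linkers` (character vector of
#'   length `n_fingers - 1`).
#' @export
zf_array <- function(protein_id, sequence) {
  fingers <- detect_fingers(sequence)
  n <- length(fingers)
  linkers <- character(0)
  if (n >= 2L) {
    linkers <- vapply(seq_len(n - 1L), function(i) {
      substr(sequence, fingers[[i]]$end + 1L, fingers[[i + 1L]]$start - 1L)
    }, character(1))
  }
  structure(list(protein_id = protein_id, fingers = fingers,
                 linkers = linkers, sequence = sequence),
            class = "zf_array")
}

#' @export
print.zf_array <- function(x, ...) {
  cat(sprintf("zf_array '%s': %d finger(s)\n", x$protein_id,
              length(x$fingers)))
  for (f in x$fingers)
    cat(sprintf("  #%d [%d-%d] helix %s\n", f$index_in_array, f$start, f$end,
                paste(f$helix_map, collapse = "")))
  if (length(x$linkers))
    cat("  linkers:", paste(x$linkers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.zf_array <- function(x) length(x$fingers)

#' Boundary pairs of a zinc-finger array
#'
#' The ordered residue pair at each inter-finger interface: position +9 of
#' finger i and position -2 of finger i+1. These pairs index the binding
#' mode of the downstream (subject) finger.
#'
#' @param array A `zf_array` with at least two fingers.
#' @return A data.frame with columns `plus9_prev`, `minus2_curr` and
#'   `junction` (i, meaning the boundary between fingers i and i+1),
#'   one row per junction.
#' @export
boundary_pairs <- function(array) {
  stopifnot(inherits(array, "zf_array"))
  n <- length(array$fingers)
  if (n < 2L) stop("no boundary: array has fewer than two fingers")
  data.frame(
    junction = seq_len(n - 1L),
    plus9_prev = vapply(seq_len(n - 1L),
                        function(i) array$fingers[[i]]$helix_map[["+9"]],
                        character(1)),
    minus2_curr = vapply(seq_len(n - 1L),
                         function(i) array$fingers[[i + 1L]]$helix_map[["-2"]],
                         character(1)),
    stringsAsFactors = FALSE)
}

#' Keep only arrays with canonical linker lengths
#'
#' Retains arrays whose every inter-finger linker is 4-6 residues long, the
#' canonical range for tandem C2H2 arrays.
#'
#' @param arrays List of `zf_array` objects.
#' @param min_len,max_len Inclusive linker-length bounds (default 4 and 6).
#' @return The retained subset, in input order.
#' @export
filter_canonical_linkers <- function(arrays, min_len = 4L, max_len = 6L) {
  keep <- vapply(arrays, function(a) {
    lens <- nchar(a$linkers)
    length(lens) == 0L || all(lens >= min_len & lens <= max_len)
  }, logical(1))
  arrays[keep]
}

# Tabular round trip ---------------------------------------------------------

#' Write zinc-finger arrays to a TSV table
#'
#' One row per finger: protein id, finger index, span bounds, span residues,
#' His-spacer length, the seven helix-map residues and the linker that
#' follows the finger (empty for the last finger).
#'
#' @param arrays List of `zf_array` objects.
#' @param file Output path.
#' @export
write_zf_arrays <- function(arrays, file) {
  rows <- do.call(rbind, lapply(arrays, function(a) {
    n <- length(a$fingers)
    do.call(rbind, lapply(seq_len(n), function(i) {
      f <- a$fingers[[i]]
      cbind(data.frame(protein_id = a$protein_id, finger = i,
                       start = f$start, end = f$end,
                       core_start = f$core_start,
                       residues = f$residues,
                       his_spacer_len = f$his_spacer_len,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(
              f$helix_map, paste0("h", gsub("\\+", "p", gsub("-", "m",
                                                             names(f$helix_map)))))),
              stringsAsFactors = FALSE),
            data.frame(linker_after = if (i < n) a$linkers[i] else "",
                       stringsAsFactors = FALSE))
    }))
  }))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read zinc-finger arrays from the TSV written by [write_zf_arrays()]
#'
#' @param file Path to the table.
#' @return List of `zf_array` objects (helix maps restored from columns).
#' @export
read_zf_arrays <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE,
                    colClasses = list(linker_after = "character"))
  hcols <- paste0("h", gsub("\\+", "p", gsub("-", "m", HELIX_POSITIONS)))
  lapply(split(tab, tab$protein_id)[unique(tab$protein_id)], function(d) {
    d <- d[order(d$finger), , drop = FALSE]
    fingers <- lapply(seq_len(nrow(d)), function(i) {
      r <- d[i, ]
      helix_map <- setNames(as.character(unlist(r[hcols])), HELIX_POSITIONS)
      h1 <- r$core_start + 1L + (nchar(r$residues) -
                                   (r$core_start - r$start) - 1L) -
        (r$his_spacer_len + 1L)  # second His back to first His
      structure(list(index_in_array = i, residues = r$residues,
                     start = r$start, end = r$end,
                     core_start = r$core_start, core_end = r$end,
                     helix_map = helix_map,
                     coordinating = NA,
                     his_spacer_len = r$his_spacer_len),
                class = "zf_finger")
    })
    linkers <- d$linker_after[-nrow(d)]
    structure(list(protein_id = d$protein_id[1], fingers = fingers,
                   linkers = as.character(linkers), sequence = NA_character_),
              class = "zf_array")
  })
}
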