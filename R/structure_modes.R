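# Two-finger structure extraction from protein-DNA complexes, Kabsch
# superposition, Calpha RMSD matrices, greedy mode clustering and the
# boundary-pair/conformation correlation test.

#' Construct a two-finger structure record
#'
#' @param source_id Accession + chain (or any unique label).
#' @param finger1_ca,finger2_ca Numeric matrices (n x 3) of ordered Calpha
#'   coordinates in Angstrom for the two adjacent fingers (N to C).
#' @param sequence Concatenated one-letter residues of the two finger
#'   spans; its length must equal the total number of Calpha rows.
#' @param boundary_pair Character vector `c(plus9_prev, minus2_curr)`:
#'   position +9 of finger 1 and -2 of finger 2.
#' @param min_dna_distance Shortest heavy-atom distance (Angstrom) from
#'   either finger to any nucleic-acid atom; `NA` if no DNA was present.
#' @param mode Optional known/planted mode label.
#' @return A `two_finger_structure` object.
#' @export
two_finger_structure <- function(source_id, finger1_ca, finger2_ca, sequence,
                                 boundary_pair = c(NA, NA),
                                 min_dna_distance = NA_real_, mode = NA) {
  finger1_ca <- as.matrix(finger1_ca)
  finger2_ca <- as.matrix(finger2_ca)
  if (ncol(finger1_ca) != 3L || ncol(finger2_ca) != 3L)
    stop("coordinates must be n x 3 matrices")
  if (nrow(finger1_ca) == 0L || nrow(finger2_ca) == 0L)
    stop("coordinate lists must be non-empty")
  if (any(!is.finite(finger1_ca)) || any(!is.finite(finger2_ca)))
    stop("coordinates must be finite")
  if (nchar(sequence) != nrow(finger1_ca) + nrow(finger2_ca))
    stop("sequence length must match the total Calpha count")
  structure(list(source_id = source_id,
                 finger1_ca = finger1_ca, finger2_ca = finger2_ca,
                 sequence = sequence,
                 boundary_pair = boundary_pair,
                 min_dna_distance = min_dna_distance,
                 mode = mode),
            class = "two_finger_structure")
}

#' @export
print.two_finger_structure <- function(x, ...) {
  cat(sprintf("two_finger_structure '%s': %d + %d Calpha, pair (%s,%s), DNA %.2f A\n",
              x$source_id, nrow(x$finger1_ca), nrow(x$finger2_ca),
              x$boundary_pair[1], x$boundary_pair[2], x$min_dna_distance))
  invisible(x)
}

.coords <- function(s) rbind(s$finger1_ca, s$finger2_ca)

# Kabsch ---------------------------------------------------------------------

#' Optimal proper-rotation superposition (Kabsch)
#'
#' Least-squares rigid superposition of point set `b` onto point set `a`
#' using the SVD-based Kabsch algorithm, with the reflection branch
#' excluded (the returned rotation always has determinant +1).
#'
#' @param a,b Equal-length n x 3 coordinate matrices (n >= 3).
#' @return List with `rotation` (3 x 3, applied as `b_centred %*% rotation`),
#'   `translation` (so that `b %*% rotation + translation` superposes onto
#'   `a` -- with the rotation applied about the centroid of `b`), and
#'   `rmsd` in the units of the input.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have equal dimensions")
  if (nrow(a) < 3L) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  H <- crossprod(bc, ac)           # 3x3: t(bc) %*% ac
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- bc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - ac)^2)))
  translation <- ca - as.vector(cb %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# Sequence correspondence ----------------------------------------------------

.global_align <- function(sa, sb) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  list(ia = ia[both], ib = ib[both],
       match = sum(both & pa == pb))
}

#' Sequence identity of two two-finger structures
#'
#' Matches divided by aligned (both-residue) positions under global
#' alignment of the concatenated finger sequences.
#'
#' @param a,b `two_finger_structure` objects (or plain strings).
#' @return Fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  sa <- if (inherits(a, "two_finger_structure")) a$sequence else a
  sb <- if (inherits(b, "two_finger_structure")) b$sequence else b
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("empty sequence")
  if (identical(sa, sb)) return(1)
  g <- .global_align(sa, sb)
  if (length(g$ia) == 0L) return(0)
  g$match / length(g$ia)
}

#' Pairwise sequence-identity matrix for a structure set
#'
#' @param structures List of `two_finger_structure`.
#' @return Symmetric matrix of [sequence_identity()] values with unit
#'   diagonal.
#' @export
sequence_identity_matrix <- function(structures) {
  n <- length(structures)
  ids <- vapply(structures, `[[`, character(1), "source_id")
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- sequence_identity(structures[[i]],
                                            structures[[j]])
  m
}

# Returns index pairs (ia, ib) into the Calpha rows, or NULL if the
# correspondence covers < min_frac of the shorter sequence. Equal-length
# arrays map 1:1 (two-finger spans already share the C2H2 register);
# sequence alignment is only used to bridge length differences, where it
# is the only available anchor.
.ca_correspondence <- function(a, b, min_frac = 0.8) {
  if (nchar(a$sequence) == nchar(b$sequence)) {
    n <- nchar(a$sequence)
    return(list(ia = seq_len(n), ib = seq_len(n)))
  }
  g <- .global_align(a$sequence, b$sequence)
  nmin <- min(nchar(a$sequence), nchar(b$sequence))
  if (length(g$ia) < min_frac * nmin) return(NULL)
  list(ia = g$ia, ib = g$ib)
}

#' All-vs-all Calpha RMSD matrix
#'
#' Superposes every pair of two-finger structures with
#' [kabsch_superpose()] on corresponding Calpha pairs. Equal-length
#' spans correspond 1:1 (two-finger arrays share the C2H2 register);
#' unequal lengths are bridged by a global sequence alignment, and pairs
#' with fewer than `min_aligned_frac` of the shorter sequence aligned
#' are flagged `NA` rather than silently zero.
#'
#' @param structures List of `two_finger_structure`.
#' @param min_aligned_frac Minimum aligned fraction for a valid entry.
#' @return Symmetric numeric matrix (Angstrom) with zero diagonal, with
#'   source ids as dimnames; entries whose correspondence failed are `NA`.
#' @export
ca_rmsd_matrix <- function(structures, min_aligned_frac = 0.8) {
  n <- length(structures)
  ids <- vapply(structures, `[[`, character(1), "source_id")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  coords <- lapply(structures, .coords)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    corr <- .ca_correspondence(structures[[i]], structures[[j]],
                               min_aligned_frac)
    if (is.null(corr) || length(corr$ia) < 3L) {
      m[i, j] <- m[j, i] <- NA_real_
    } else {
      fit <- kabsch_superpose(coords[[i]][corr$ia, , drop = FALSE],
                              coords[[j]][corr$ib, , drop = FALSE])
      m[i, j] <- m[j, i] <- fit$rmsd
    }
  }
  m
}

# Finger-1 anchored alignment ------------------------------------------------

.helix_axis <- function(x) {
  v <- prcomp(x, center = TRUE)$rotation[, 1]
  v / sqrt(sum(v^2))
}

#' Align structures on finger 1 and summarize finger-2 displacement
#'
#' Superposes every structure onto the reference using finger-1 Calpha only
#' and reports, per structure, the displacement of the finger-2 centroid
#' (Angstrom) and the change in finger-2 principal ("helix") axis direction
#' (degrees, folded to \[0, 90\]) relative to the reference.
#'
#' @param structures List of `two_finger_structure` with identical
#'   finger-1 lengths (or identical sequences).
#' @param reference Source id (or index) of the reference; default first.
#' @return data.frame with `source_id`, `displacement`, `angle`.
#' @export
finger1_anchored_alignment <- function(structures, reference = 1L) {
  if (length(structures) < 2L) stop("need at least two structures")
  ids <- vapply(structures, `[[`, character(1), "source_id")
  ref_i <- if (is.character(reference)) match(reference, ids) else reference
  if (is.na(ref_i) || ref_i < 1L || ref_i > length(structures))
    stop("reference not in set")
  ref <- structures[[ref_i]]
  ref_axis <- .helix_axis(ref$finger2_ca)
  ref_cen <- colMeans(ref$finger2_ca)
  out <- lapply(structures, function(s) {
    if (nrow(s$finger1_ca) != nrow(ref$finger1_ca))
      stop("finger-1 length mismatch with reference for ", s$source_id)
    fit <- kabsch_superpose(ref$finger1_ca, s$finger1_ca)
    f2 <- sweep(s$finger2_ca %*% fit$rotation, 2, fit$translation, "+")
    disp <- sqrt(sum((colMeans(f2) - ref_cen)^2))
    ax <- .helix_axis(f2)
    cosang <- min(1, abs(sum(ax * ref_axis)))
    data.frame(source_id = s$source_id, displacement = disp,
               angle = acos(cosang) * 180 / pi, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Mode clustering ------------------------------------------------------------

#' Cluster two-finger geometries into binding modes
#'
#' Greedy leader clustering on a Calpha RMSD matrix: candidates are ordered
#' by descending within-threshold neighbour count (ties broken by source
#' id), each leader absorbs all unassigned structures closer than `within`,
#' and the dual thresholds are enforced post hoc -- any member closer than
#' `between` to another cluster's representative is split off as a
#' singleton. Cluster labels are 1, 2, ... by decreasing size.
#'
#' @param matrix Symmetric RMSD matrix from [ca_rmsd_matrix()] (no `NA`
#'   among clustered members).
#' @param within Maximum member-representative RMSD inside a mode
#'   (default 1.5 Angstrom).
#' @param between Minimum separation from other modes' representatives
#'   (default 2.0 Angstrom).
#' @return A `mode_clustering` object: `assignments` (named integer
#'   vector), `representatives` (source id per mode), `within_threshold`,
#'   `between_threshold`.
#' @export
cluster_modes <- function(matrix, within = 1.5, between = 2.0) {
  n <- nrow(matrix)
  if (is.null(n) || n == 0L)
    return(structure(list(assignments = integer(0),
                          representatives = character(0),
                          within_threshold = within,
                          between_threshold = between),
                     class = "mode_clustering"))
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (anyNA(matrix)) stop("RMSD matrix has missing entries")
  nb <- rowSums(matrix < within) - 1L
  ord <- order(-nb, ids)
  assigned <- rep(NA_integer_, n)
  reps <- integer(0)
  k <- 0L
  for (i in ord) {
    if (!is.na(assigned[i])) next
    k <- k + 1L
    reps[k] <- i
    members <- which(is.na(assigned) & matrix[i, ] < within)
    assigned[members] <- k
    assigned[i] <- k
  }
  # post hoc: split off members too close to a foreign representative
  if (k > 1L) {
    for (i in seq_len(n)) {
      foreign <- reps[-assigned[i]]
      if (length(foreign) && any(matrix[i, foreign] < between) &&
          !(i %in% reps)) {
        k <- k + 1L
        reps[k] <- i
        assigned[i] <- k
      }
    }
  }
  # relabel by decreasing cluster size (ties: representative id)
  sizes <- tabulate(assigned, nbins = k)
  relabel <- order(-sizes, ids[reps])
  newlab <- integer(k)
  newlab[relabel] <- seq_len(k)
  assignments <- setNames(newlab[assigned], ids)
  representatives <- setNames(ids[reps[relabel]], seq_len(k))
  structure(list(assignments = assignments,
                 representatives = representatives,
                 within_threshold = within, between_threshold = between),
            class = "mode_clustering")
}

#' @export
print.mode_clustering <- function(x, ...) {
  k <- length(x$representatives)
  cat(sprintf("mode_clustering: %d structure(s) in %d mode(s) (within < %.1f A, between >= %.1f A)\n",
              length(x$assignments), k, x$within_threshold,
              x$between_threshold))
  for (m in seq_len(k))
    cat(sprintf("  mode %d: %d member(s), representative %s\n", m,
                sum(x$assignments == m), x$representatives[[m]]))
  invisible(x)
}

# Boundary-pair / conformation correlation -----------------------------------

#' Test whether matching boundary pairs imply similar conformations
#'
#' Takes every pair of structures, removes pairs with sequence identity
#' above `identity_cutoff` (so that conserved boundary pairs do not simply
#' reflect overall homology), partitions the remaining Calpha RMSDs by
#' whether the two structures carry the identical ordered (+9, -2)
#' boundary pair, and applies a one-sided Mann-Whitney rank test of
#' match < mismatch.
#'
#' @param structures List of `two_finger_structure` with boundary pairs
#'   populated.
#' @param identity_cutoff Pairs with identity above this are excluded
#'   (default 0.5).
#' @param rmsd Optional precomputed matrix from [ca_rmsd_matrix()].
#' @param identity Optional precomputed pairwise identity matrix (e.g.
#'   from [sequence_identity_matrix()]); both matrices are label-free,
#'   so they can be shared across label permutations in calibration
#'   studies.
#' @return List with `match_rmsds`, `mismatch_rmsds`, `statistic`,
#'   `p_value` and `flagged` (TRUE when either group is empty, in which
#'   case the statistic is `NA`).
#' @export
boundary_pair_rmsd_correlation <- function(structures, identity_cutoff = 0.5,
                                           rmsd = NULL, identity = NULL) {
  if (length(structures) < 2L) stop("need at least two structures")
  if (is.null(rmsd)) rmsd <- ca_rmsd_matrix(structures)
  if (is.null(identity)) identity <- sequence_identity_matrix(structures)
  pairs <- t(combn(length(structures), 2L))
  keep <- apply(pairs, 1, function(p) {
    !is.na(rmsd[p[1], p[2]]) &&
      identity[p[1], p[2]] <= identity_cutoff
  })
  pairs <- pairs[keep, , drop = FALSE]
  bp <- lapply(structures, `[[`, "boundary_pair")
  is_match <- apply(pairs, 1, function(p)
    identical(bp[[p[1]]], bp[[p[2]]]))
  vals <- rmsd[pairs]
  match_rmsds <- vals[is_match]
  mismatch_rmsds <- vals[!is_match]
  if (length(match_rmsds) == 0L || length(mismatch_rmsds) == 0L) {
    return(list(match_rmsds = match_rmsds, mismatch_rmsds = mismatch_rmsds,
                statistic = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  wt <- wilcox.test(match_rmsds, mismatch_rmsds, alternative = "less",
                    exact = FALSE)
  list(match_rmsds = match_rmsds, mismatch_rmsds = mismatch_rmsds,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       flagged = FALSE)
}

# Structure-file extraction --------------------------------------------------

.parse_resolution <- function(lines, cif) {
  if (cif) {
    hit <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(hit)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2]))
      return(v)
    }
    return(NA_real_)
  }
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(hit)) {
    v <- suppressWarnings(
      as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", hit[1])))
    return(v)
  }
  NA_real_
}

.maybe_gunzip <- function(file) {
  if (!grepl("\\.gz$", file)) return(file)
  tmp <- tempfile(fileext = sub("\\.gz$", "", basename(file)))
  writeLines(readLines(gzfile(file)), tmp)
  tmp
}

#' Extract adjacent two-finger arrays from a protein-DNA complex structure
#'
#' Reads a PDB or mmCIF file (gzip accepted; NMR entries use model 1),
#' discards it if the declared crystallographic resolution is worse than
#' `resolution_cutoff`, detects C2H2 fingers on every protein chain via
#' [detect_fingers()], maps finger spans to Calpha coordinates, and
#' returns every adjacent finger pair whose shortest heavy-atom distance
#' to any nucleic-acid atom is at most `dna_distance_cutoff`.
#'
#' @param structure_file Path to `.pdb`, `.cif` (optionally `.gz`).
#' @param resolution_cutoff Discard structures with resolution value above
#'   this (Angstrom, default 3.0); entries without a declared resolution
#'   (e.g. NMR) pass.
#' @param dna_distance_cutoff Maximum finger-DNA distance (Angstrom,
#'   default 10). Pairs with no DNA present are excluded when a DNA chain
#'   exists in the file; if the file has no nucleic chain the distance is
#'   `NA` and pairs are kept.
#' @param helix_only If `TRUE`, measure the DNA distance from the
#'   recognition-helix residues (-2..+9 span) only, rather than the whole
#'   finger.
#' @param verbose Log skip reasons with `message()`.
#' @return List of `two_finger_structure` (possibly empty).
#' @export
extract_two_finger_arrays <- function(structure_file, resolution_cutoff = 3.0,
                                      dna_distance_cutoff = 10.0,
                                      helix_only = FALSE, verbose = FALSE) {
  path <- .maybe_gunzip(structure_file)
  cif <- grepl("\\.cif$", path)
  lines <- readLines(path, warn = FALSE)
  res <- .parse_resolution(lines, cif)
  if (!is.na(res) && res > resolution_cutoff) {
    if (verbose) message(sprintf("%s: resolution %.2f A worse than cutoff, skipped",
                                 structure_file, res))
    return(list())
  }
  pdb <- if (cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  atoms <- pdb$atom
  nuc_sel <- tryCatch(bio3d::atom.select(pdb, "nucleic", verbose = FALSE),
                      error = function(e) NULL)
  nuc_xyz <- if (!is.null(nuc_sel) && length(nuc_sel$atom))
    as.matrix(atoms[nuc_sel$atom, c("x", "y", "z")]) else NULL
  prot_sel <- bio3d::atom.select(pdb, "protein", verbose = FALSE)
  if (length(prot_sel$atom) == 0L) return(list())
  prot <- atoms[prot_sel$atom, , drop = FALSE]
  out <- list()
  base_id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(structure_file))
  for (ch in unique(prot$chain)) {
    chain <- prot[prot$chain == ch, , drop = FALSE]
    ca <- chain[chain$elety == "CA", , drop = FALSE]
    # one row per residue, chain order
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    if (nrow(ca) < 23L) next
    seq1 <- paste(bio3d::aa321(ca$resid), collapse = "")
    seq1 <- gsub("[^A-Z]", "X", seq1)
    fingers <- tryCatch(detect_fingers(seq1), error = function(e) list())
    if (length(fingers) < 2L) next
    for (i in seq_len(length(fingers) - 1L)) {
      f1 <- fingers[[i]]; f2 <- fingers[[i + 1L]]
      idx1 <- f1$start:f1$end
      idx2 <- f2$start:f2$end
      ca1 <- as.matrix(ca[idx1, c("x", "y", "z")])
      ca2 <- as.matrix(ca[idx2, c("x", "y", "z")])
      dist_idx <- function(f) {
        if (!helix_only) return(f$start:f$end)
        (f$coordinating[3] - 8L):min(f$end, f$coordinating[3] + 2L)
      }
      dna_d <- NA_real_
      if (!is.null(nuc_xyz)) {
        resnos <- ca$resno[c(dist_idx(f1), dist_idx(f2))]
        fa <- chain[chain$resno %in% resnos &
                      !grepl("^H", chain$elety), , drop = FALSE]
        fx <- as.matrix(fa[, c("x", "y", "z")])
        d2 <- outer(rowSums(fx^2), rowSums(nuc_xyz^2), "+") -
          2 * fx %*% t(nuc_xyz)
        dna_d <- sqrt(max(0, min(d2)))
        if (dna_d > dna_distance_cutoff) {
          if (verbose) message(sprintf(
            "%s chain %s fingers %d-%d: DNA distance %.1f A > cutoff, skipped",
            base_id, ch, i, i + 1L, dna_d))
          next
        }
      }
      out[[length(out) + 1L]] <- two_finger_structure(
        source_id = sprintf("%s_%s_f%d", base_id, ch, i),
        finger1_ca = ca1, finger2_ca = ca2,
        sequence = paste0(f1$residues, f2$residues),
        boundary_pair = c(f1$helix_map[["+9"]], f2$helix_map[["-2"]]),
        min_dna_distance = dna_d)
    }
  }
  out
}

#' Write extracted two-finger arrays to TSV
#'
#' @param structures List of `two_finger_structure`.
#' @param file Output path.
#' @export
write_structures_tsv <- function(structures, file) {
  d <- do.call(rbind, lapply(structures, function(s)
    data.frame(source_id = s$source_id,
               n_ca = nrow(s$finger1_ca) + nrow(s$finger2_ca),
               sequence = s$sequence,
               plus9_prev = s$boundary_pair[1],
               minus2_curr = s$boundary_pair[2],
               min_dna_distance = s$min_dna_distance,
               mode = if (is.na(s$mode)) "" else as.character(s$mode),
               stringsAsFactors = FALSE)))
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
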