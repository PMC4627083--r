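# Planted-truth simulators: a residue/mode -> base code, a boundary-pair ->
# mode table, gold-standard arrays with triplet-resolved PWMs, and rigid
# two-finger geometries with planted mode labels. All generators are pure
# functions of (parameters, seed). Everything here is synthetic stand-in
# data for validation; none of it is derived from experimental sources.

# default pool of common specificity residues; guarantees training
# coverage at gold-standard sample sizes
SPEC_AA_POOL <- c("A", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T", "V")

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a planted residue/mode -> base-preference code
#'
#' For every (specificity position, amino acid, mode) cell a preferred
#' base is drawn and given probability `specificity`, the rest sharing
#' the remainder. With `mode_dependent = TRUE` the preferred base is
#' redrawn per mode (resampled until at least two modes disagree, so
#' every cell differs across modes by total variation >= 0.5 when
#' `specificity >= 0.75`); with `FALSE` all modes share one preferred
#' base per (position, aa).
#'
#' @param mode_dependent Logical (default TRUE).
#' @param n_modes Number of modes (default 6).
#' @param specificity Probability mass on the preferred base
#'   (default 0.85).
#' @param seed Integer seed.
#' @return A `planted_code`: array `freq[position, aa, mode, base]` plus
#'   the generating parameters.
#' @export
make_planted_code <- function(mode_dependent = TRUE, n_modes = 6L,
                              specificity = 0.85, seed = 1L) {
  modes <- as.character(seq_len(n_modes))
  freq <- array(NA_real_,
                dim = c(length(SPEC_POSITIONS), length(AA20), n_modes, 4),
                dimnames = list(SPEC_POSITIONS, AA20, modes, BASES))
  withr_seed(seed, {
    for (pos in SPEC_POSITIONS) for (aa in AA20) {
      if (mode_dependent) {
        repeat {
          pref <- sample.int(4L, n_modes, replace = TRUE)
          if (length(unique(pref)) > 1L) break
        }
      } else pref <- rep(sample.int(4L, 1L), n_modes)
      for (m in seq_len(n_modes)) {
        v <- rep((1 - specificity) / 3, 4)
        v[pref[m]] <- specificity
        freq[pos, aa, m, ] <- v
      }
    }
  })
  structure(list(freq = freq, mode_dependent = mode_dependent,
                 specificity = specificity, n_modes = n_modes, seed = seed),
            class = "planted_code")
}

#' Generate a boundary-pair -> mode table with disjoint pair sets
#'
#' Samples `n_modes * pairs_per_mode` distinct ordered (+9, -2) amino-acid
#' pairs from the 400 possible and assigns them to modes in blocks.
#'
#' @param n_modes Number of modes (<= 20).
#' @param pairs_per_mode Pairs per mode (>= 3 recommended).
#' @param seed Integer seed.
#' @param pool Amino acids the pair residues are drawn from (default all
#'   20).
#' @return A [mode_table()].
#' @export
make_mode_table <- function(n_modes = 6L, pairs_per_mode = 3L, seed = 1L,
                            pool = AA20) {
  if (n_modes > 20L) stop("n_modes must be <= 20")
  total <- n_modes * pairs_per_mode
  all_pairs <- expand.grid(plus9 = pool, minus2 = pool,
                           stringsAsFactors = FALSE)
  if (total > nrow(all_pairs))
    stop("requested pairs exceed ", nrow(all_pairs))
  pick <- withr_seed(seed, sample.int(nrow(all_pairs), total))
  sel <- all_pairs[pick, ]
  mode_table(sel$plus9, sel$minus2,
             mode = rep(seq_len(n_modes), each = pairs_per_mode),
             provenance = "synthetic")
}

# finger sequence template (23 residues); first His at position 19 so the
# helix map reads -2=11, -1=12, +1=13, +2=14, +3=15, +6=18, +9=21
.FINGER_TEMPLATE <- strsplit("YKCPECGKSFSRSDELTRHIRTH", "")[[1]]
.SLOT <- c(m2 = 11L, m1 = 12L, p2 = 14L, p3 = 15L, p6 = 18L, p9 = 21L)

.finger_sequence <- function(p6, p3, m1, p2, m2, p9) {
  s <- .FINGER_TEMPLATE
  s[.SLOT[["p6"]]] <- p6; s[.SLOT[["p3"]]] <- p3
  s[.SLOT[["m1"]]] <- m1; s[.SLOT[["p2"]]] <- p2
  s[.SLOT[["m2"]]] <- m2; s[.SLOT[["p9"]]] <- p9
  paste(s, collapse = "")
}

#' Simulate a gold-standard set of arrays with triplet-resolved PWMs
#'
#' Arrays of 3-10 fingers are built as real protein sequences (so they
#' pass [detect_fingers()] unmodified): each finger gets specificity
#' residues drawn from a 12-residue pool, consecutive fingers get a
#' boundary pair drawn from the mode table (which fixes the downstream
#' finger's mode), and canonical 5-residue linkers join the fingers. The
#' N-terminal finger's mode is drawn uniformly but is unobservable from
#' covariates. Per-finger base columns are Dirichlet draws centred on the
#' planted code for the finger's mode, and the experimental PWM of length
#' 3N+1 is assembled with subsite-overlap averaging (optionally padded
#' with two low-information flank columns per side).
#'
#' @param code A [make_planted_code()] result.
#' @param table A [mode_table()]; every sampled boundary pair comes from
#'   it.
#' @param n_train,n_test Number of training / test arrays (defaults 36
#'   and 28).
#' @param noise Dirichlet concentration for the per-finger columns
#'   (default 50); `0` or `Inf` disables noise so the columns equal the
#'   planted code exactly.
#' @param pad_flanks Add two Dirichlet(5,5,5,5) low-information columns
#'   at each end of every experimental PWM (register offset becomes 2).
#' @param seed Integer seed.
#' @param aa_pool Specificity-residue pool (default the 12-residue
#'   common pool; pass `AA20` to exercise untrained-pattern fallbacks).
#' @return A `synthetic_gold_standard`: lists `train` and `test` of cases
#'   (`array`, `pwm`, `register`, `finger_true`, `finger_noisy`, `modes`),
#'   plus the `mode_table`, `code` parameters and `seed`.
#' @export
simulate_gold_standard <- function(code, table, n_train = 36L, n_test = 28L,
                                   noise = 50, pad_flanks = FALSE, seed = 1L,
                                   aa_pool = SPEC_AA_POOL) {
  stopifnot(inherits(code, "planted_code"))
  modes <- dimnames(code$freq)[[3]]
  exact <- !is.finite(noise) || noise == 0
  make_case <- function(id) {
    n <- sample(3:10, 1L)
    junc <- table[sample.int(nrow(table), n - 1L, replace = TRUE), ]
    p9 <- c(junc$plus9, sample(aa_pool, 1L))
    m2 <- c(sample(aa_pool, 1L), junc$minus2)
    fmodes <- c(sample(modes, 1L), as.character(junc$mode))
    p6 <- sample(aa_pool, n, replace = TRUE)
    p3 <- sample(aa_pool, n, replace = TRUE)
    m1 <- sample(aa_pool, n, replace = TRUE)
    p2 <- sample(aa_pool, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i)
      .finger_sequence(p6[i], p3[i], m1[i], p2[i], m2[i], p9[i]),
      character(1))
    arr <- zf_array(id, paste(seqs, collapse = "TGEKP"))
    stopifnot(length(arr$fingers) == n)
    finger_true <- finger_noisy <- vector("list", n)
    for (i in seq_len(n)) {
      tc <- t(rbind(code$freq["+6", p6[i], fmodes[i], ],
                    code$freq["+3", p3[i], fmodes[i], ],
                    code$freq["-1", m1[i], fmodes[i], ],
                    code$freq["+2", p2[i], fmodes[i], ]))
      dimnames(tc) <- list(BASES, paste0("pos", 1:4))
      nc <- tc
      if (!exact)
        for (j in 1:4) nc[, j] <- .rdirichlet1(noise * tc[, j])
      finger_true[[i]] <- tc
      finger_noisy[[i]] <- nc
    }
    L <- 3L * n + 1L
    acc <- matrix(0, 4, L); cnt <- integer(L)
    for (i in seq_len(n)) {
      s <- .finger_block_start(i, n)
      for (j in 0:3) {
        acc[, s + j] <- acc[, s + j] + finger_noisy[[i]][, j + 1L]
        cnt[s + j] <- cnt[s + j] + 1L
      }
    }
    mat <- sweep(acc, 2, cnt, "/")
    offset <- 0L
    if (pad_flanks) {
      flank <- function() replicate(2, .rdirichlet1(c(5, 5, 5, 5)))
      mat <- cbind(flank(), mat, flank())
      offset <- 2L
    }
    list(array = arr,
         pwm = pwm(sweep(mat, 2, colSums(mat), "/"), id = id),
         register = list(offset = offset, orientation = "forward"),
         finger_true = finger_true, finger_noisy = finger_noisy,
         modes = fmodes)
  }
  withr_seed(seed, {
    train <- lapply(sprintf("train%02d", seq_len(n_train)), make_case)
    test <- lapply(sprintf("test%02d", seq_len(n_test)), make_case)
    structure(list(train = train, test = test, mode_table = table,
                   code_params = code[c("mode_dependent", "specificity",
                                        "n_modes", "seed")],
                   noise = noise, pad_flanks = pad_flanks, seed = seed),
              class = "synthetic_gold_standard")
  })
}

#' @export
print.synthetic_gold_standard <- function(x, ...) {
  cat(sprintf("synthetic_gold_standard: %d train + %d test arrays, noise %s, seed %d\n",
              length(x$train), length(x$test), format(x$noise), x$seed))
  invisible(x)
}

#' Convert gold-standard cases to finger records for profile building
#'
#' Uses each finger's noisy per-finger columns as the "experimental"
#' preference, with the +2 column handed over on the contacted strand
#' (complemented), matching the input convention of [build_profiles()].
#'
#' @param cases List of gold-standard cases (e.g. `sgs$train`).
#' @return List of finger records.
#' @export
gold_finger_records <- function(cases) {
  unlist(lapply(cases, function(case) {
    cols <- lapply(case$finger_noisy, function(nc) {
      m <- nc[, c(1, 2, 3, 4)]
      colnames(m) <- SPEC_POSITIONS[c(1, 2, 3, 4)]  # pos1..4 = +6 +3 -1 +2
      m[, "+2"] <- m[COMPLEMENT_IDX, "+2"]          # to contacted strand
      m
    })
    array_finger_records(case$array, cols)
  }), recursive = FALSE)
}

# Structure simulation -------------------------------------------------------

.finger_shape <- function() {
  i <- 0:22
  base <- cbind(2.3 * cos(i * 100 * pi / 180),
                2.3 * sin(i * 100 * pi / 180),
                1.5 * i)
  # fixed asymmetric wobble so the shape has no rotational symmetry
  wob <- withr_seed(424242L, matrix(runif(23 * 3, -0.8, 0.8), 23, 3))
  base + wob
}

.rot_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st,
           ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),
           uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st,
           ct + uz^2 * (1 - ct)), 3, 3, byrow = TRUE)
}

.mode_templates <- function(n_modes = 6L, min_sep = 2.5) {
  shape <- .finger_shape()
  f2base <- sweep(shape, 2, c(12, 0, 30), "+")
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  axes <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
                c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  angles <- c(0, 30, 60, 90, 120, 150) * pi / 180
  templates <- lapply(seq_len(n_modes), function(m) {
    cen <- colMeans(f2base)
    R <- .rot_axis(axes[m, ], angles[m])
    f2 <- sweep(sweep(f2base, 2, cen) %*% t(R), 2, cen + 5 * dirs[m, ], "+")
    list(finger1 = shape, finger2 = f2)
  })
  # construction check: pairwise full-structure RMSD must exceed min_sep
  for (a in seq_len(n_modes - 1L)) for (b in (a + 1L):n_modes) {
    r <- kabsch_superpose(rbind(templates[[a]]$finger1, templates[[a]]$finger2),
                          rbind(templates[[b]]$finger1, templates[[b]]$finger2))$rmsd
    if (r < min_sep)
      stop(sprintf("mode templates %d and %d are only %.2f A apart", a, b, r))
  }
  templates
}

#' Simulate two-finger structures with planted binding modes
#'
#' Six rigid template geometries for finger 2 relative to a fixed finger 1
#' (pairwise template Calpha RMSD >= 2.5 Angstrom by construction, checked
#' at run time) are copied with i.i.d. Gaussian coordinate jitter. Each
#' member's boundary pair is drawn from its mode's rows in the table and
#' embedded in a randomized C2H2 sequence (anchor Cys/His and the pair
#' slots fixed, everything else resampled, so unrelated members share
#' little sequence identity).
#'
#' @param table A [mode_table()] whose modes index the templates (at most
#'   6 modes).
#' @param n_per_mode Members per mode (default 10).
#' @param jitter_sd Coordinate jitter standard deviation in Angstrom
#'   (default 0.3). Jitter implying an expected within-mode RMSD at or
#'   above the 1.5 Angstrom mode width is an error.
#' @param seed Integer seed.
#' @return List of `two_finger_structure` with planted `mode` labels.
#' @export
simulate_structures <- function(table, n_per_mode = 10L, jitter_sd = 0.3,
                                seed = 1L) {
  if (jitter_sd * sqrt(6) >= 1.5)
    stop("infeasible jitter: expected within-mode RMSD would reach 1.5 A")
  modes <- as.character(sort(unique(table$mode)))
  if (length(modes) > 6L) stop("at most 6 mode templates are defined")
  templates <- .mode_templates(6L)
  vari <- setdiff(seq_len(23L), c(3L, 6L, 19L, 23L))  # non-anchor slots
  fill_pool <- setdiff(AA20, c("C", "H"))
  withr_seed(seed, {
    out <- list()
    for (mi in seq_along(modes)) {
      m <- modes[mi]
      rows <- which(table$mode == table$mode[match(m, as.character(table$mode))])
      rows <- which(as.character(table$mode) == m)
      tpl <- templates[[mi]]
      for (r in seq_len(n_per_mode)) {
        pick <- table[sample(rows, 1L), ]
        mk_seq <- function(minus2 = NULL, plus9 = NULL) {
          s <- .FINGER_TEMPLATE
          s[vari] <- sample(fill_pool, length(vari), replace = TRUE)
          if (!is.null(minus2)) s[.SLOT[["m2"]]] <- minus2
          if (!is.null(plus9)) s[.SLOT[["p9"]]] <- plus9
          s
        }
        s1 <- mk_seq(plus9 = pick$plus9)
        s2 <- mk_seq(minus2 = pick$minus2)
        out[[length(out) + 1L]] <- two_finger_structure(
          source_id = sprintf("sim_m%s_%02d", m, r),
          finger1_ca = tpl$finger1 + matrix(rnorm(69, 0, jitter_sd), 23, 3),
          finger2_ca = tpl$finger2 + matrix(rnorm(69, 0, jitter_sd), 23, 3),
          sequence = paste(c(s1, s2), collapse = ""),
          boundary_pair = c(pick$plus9, pick$minus2),
          mode = m)
      }
    }
    out
  })
}

# Minimal PDB output ---------------------------------------------------------

.pdb_atom_line <- function(serial, name, resn, chain, resno, xyz, elem) {
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resn, chain, resno, xyz[1], xyz[2], xyz[3],
          1, 0, elem)
}

#' Write simulated two-finger structures as minimal PDB files
#'
#' One Calpha-only file per structure: chain A carries finger 1, a
#' 5-residue glycine-coordinate linker (sequence `TGEKP`, positions
#' interpolated between the fingers) and finger 2; chain B is a dummy
#' 6-nucleotide DNA strand placed so that the shortest protein-DNA
#' distance equals `dna_distance`. A resolution remark is included so the
#' files exercise the extraction filters. The files are synthetic
#' fixtures, not models of real complexes.
#'
#' @param structures List of `two_finger_structure`.
#' @param dir Output directory (created if needed).
#' @param dna_distance Shortest protein-DNA distance in Angstrom
#'   (default 5); `NA` omits the DNA chain.
#' @param resolution Declared resolution in Angstrom (default 2.0).
#' @return Character vector of file paths.
#' @export
write_structures_pdb <- function(structures, dir, dna_distance = 5,
                                 resolution = 2.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  linker <- strsplit("TGEKP", "")[[1]]
  paths <- vapply(structures, function(s) {
    n1 <- nrow(s$finger1_ca); n2 <- nrow(s$finger2_ca)
    aa <- strsplit(s$sequence, "")[[1]]
    lk_from <- s$finger1_ca[n1, ]; lk_to <- s$finger2_ca[1, ]
    lk <- t(vapply(seq_along(linker), function(i)
      lk_from + (lk_to - lk_from) * i / (length(linker) + 1L), numeric(3)))
    res3 <- c(bio3d::aa123(aa[seq_len(n1)]), bio3d::aa123(linker),
              bio3d::aa123(aa[n1 + seq_len(n2)]))
    coords <- rbind(s$finger1_ca, lk, s$finger2_ca)
    lines <- c("HEADER    SYNTHETIC TWO-FINGER FIXTURE",
               sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
    serial <- 0L
    for (i in seq_len(nrow(coords))) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line(serial, " CA ", res3[i], "A", i,
                                       coords[i, ], "C"))
    }
    if (!is.na(dna_distance)) {
      anchor <- which.max(coords[, 1])
      base_xyz <- coords[anchor, ]
      for (k in 1:6) {
        serial <- serial + 1L
        xyz <- c(base_xyz[1] + dna_distance, base_xyz[2],
                 base_xyz[3] + (k - 1L) * 3)
        lines <- c(lines, .pdb_atom_line(serial, " P  ", "DA", "B", k, xyz,
                                         "P"))
        serial <- serial + 1L
        lines <- c(lines, .pdb_atom_line(serial, " C1'", "DA", "B", k,
                                         xyz + c(1.5, 1, 0), "C"))
      }
    }
    path <- file.path(dir, paste0(s$source_id, ".pdb"))
    writeLines(c(lines, "END"), path)
    path
  }, character(1))
  invisible(paths)
}
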