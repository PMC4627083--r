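rot_z <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

test_that("Kabsch recovers rigid motions exactly", {
  x <- zfmode:::withr_seed(1, matrix(rnorm(30), 10))
  y <- sweep(x %*% t(rot_z(pi / 2)), 2, c(3, -1, 7), "+")
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_superpose(x, x)$rotation, diag(3), tolerance = 1e-10)
  expect_error(kabsch_superpose(x, x[1:5, ]), "equal")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 points")
})

test_that("reflections are disallowed and the optimum matches a grid search", {
  # chiral 4-point set and its mirror image
  a <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0.5, 0.5, 1.5))
  b <- a; b[, 3] <- -b[, 3]
  fit <- kabsch_superpose(a, b)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(fit$rmsd, grid_rmsd(a, b), tolerance = 0.05)
})

test_that("superposed RMSD never exceeds the raw RMSD", {
  for (s in 1:10) {
    x <- zfmode:::withr_seed(s, matrix(rnorm(24), 8))
    y <- zfmode:::withr_seed(s + 50, matrix(rnorm(24), 8))
    raw <- sqrt(mean(rowSums((x - y)^2)))
    expect_lte(kabsch_superpose(x, y)$rmsd, raw + 1e-12)
  }
})

make_tfs <- function(id, f2_shift = c(0, 0, 0), jit_seed = NULL, jsd = 0,
                     seq1 = finger_seq(), seq2 = finger_seq()) {
  base <- zfmode:::.finger_shape()
  f2 <- sweep(base, 2, c(12, 0, 30) + f2_shift, "+")
  f1 <- base
  if (!is.null(jit_seed)) {
    f1 <- f1 + zfmode:::withr_seed(jit_seed, matrix(rnorm(69, 0, jsd), 23, 3))
    f2 <- f2 + zfmode:::withr_seed(jit_seed + 1,
                                   matrix(rnorm(69, 0, jsd), 23, 3))
  }
  two_finger_structure(id, f1, f2, paste0(seq1, seq2),
                       boundary_pair = c(substr(seq1, 21, 21),
                                         substr(seq2, 11, 11)))
}

test_that("the RMSD matrix is symmetric, zero-diagonal and rigid-invariant", {
  s1 <- make_tfs("a")
  s2 <- make_tfs("b", f2_shift = c(3, 0, 0))
  s3_coords <- sweep(rbind(s2$finger1_ca, s2$finger2_ca) %*% t(rot_z(1)),
                     2, c(5, 5, 5), "+")
  s3 <- two_finger_structure("c", s3_coords[1:23, ], s3_coords[24:46, ],
                             s2$sequence, s2$boundary_pair)
  m <- ca_rmsd_matrix(list(s1, s2, s3))
  expect_equal(dim(m), c(3, 3))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m), tolerance = 1e-6)
  expect_equal(m["b", "c"], 0, tolerance = 1e-8)   # rigid copy of b
  expect_equal(m["a", "b"], m["a", "c"], tolerance = 1e-8)
})

test_that("sequence identity is match fraction under global alignment", {
  expect_equal(sequence_identity("ACDEF", "ACDEF"), 1)
  expect_equal(sequence_identity("ACDEF", "ACDFF"), 0.8)
  expect_lt(sequence_identity("AAAAA", "WWWWW"), 0.01)
  expect_error(sequence_identity("", "ACD"), "empty")
})

test_that("finger-1 anchored alignment recovers a planted finger-2 motion", {
  ref <- make_tfs("ref")
  # rotate finger 2 about its centroid by 15 degrees about an axis
  # perpendicular to its principal axis, then shift it 3.1 Angstrom
  axis_dir <- zfmode:::.helix_axis(ref$finger2_ca)
  perp <- c(-axis_dir[2], axis_dir[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  R <- zfmode:::.rot_axis(perp, 15 * pi / 180)
  cen <- colMeans(ref$finger2_ca)
  shift_dir <- c(0.6, 0.8, 0)
  f2 <- sweep(sweep(ref$finger2_ca, 2, cen) %*% t(R), 2,
              cen + 3.1 * shift_dir, "+")
  moved <- two_finger_structure("moved", ref$finger1_ca, f2, ref$sequence,
                                ref$boundary_pair)
  res <- finger1_anchored_alignment(list(ref, moved), reference = "ref")
  expect_equal(res$displacement[res$source_id == "ref"], 0, tolerance = 1e-8)
  expect_equal(res$angle[res$source_id == "ref"], 0, tolerance = 1e-6)
  expect_equal(res$displacement[res$source_id == "moved"], 3.1,
               tolerance = 0.1)
  expect_equal(res$angle[res$source_id == "moved"], 15, tolerance = 1)
  expect_error(finger1_anchored_alignment(list(ref, moved), "absent"),
               "reference")
})

test_that("finger-2 centroid displacement matches closed-form arithmetic", {
  ref <- make_tfs("r")
  shifted <- make_tfs("s", f2_shift = c(1, 2, 2))
  res <- finger1_anchored_alignment(list(ref, shifted), reference = "r")
  expect_equal(res$displacement[2], 3, tolerance = 1e-6)
})

test_that("mode clustering respects the dual thresholds on planted groups", {
  g1 <- lapply(1:4, function(i) make_tfs(paste0("g1_", i), jit_seed = i,
                                         jsd = 0.2))
  g2 <- lapply(1:4, function(i) make_tfs(paste0("g2_", i),
                                         f2_shift = c(6, 0, 0),
                                         jit_seed = 100 + i, jsd = 0.2))
  m <- ca_rmsd_matrix(c(g1, g2))
  cl <- cluster_modes(m)
  expect_length(cl$representatives, 2)
  lab <- cl$assignments
  expect_length(unique(lab[1:4]), 1)
  expect_length(unique(lab[5:8]), 1)
  expect_false(lab[1] == lab[5])
  # all mutually close -> one cluster; empty input -> empty clustering
  expect_length(cluster_modes(ca_rmsd_matrix(g1))$representatives, 1)
  expect_length(cluster_modes(matrix(0, 0, 0))$assignments, 0)
})

test_that("mode clustering is invariant to input order on separated data", {
  tab <- make_mode_table(seed = 9)
  st <- simulate_structures(tab, n_per_mode = 3, seed = 9)
  cl1 <- cluster_modes(ca_rmsd_matrix(st))
  perm <- rev(seq_along(st))
  cl2 <- cluster_modes(ca_rmsd_matrix(st[perm]))
  expect_equal(ari(cl1$assignments[names(cl2$assignments)],
                   cl2$assignments), 1)
})

test_that("matching boundary pairs imply closer conformations", {
  tab <- make_mode_table(seed = 4)
  st <- simulate_structures(tab, n_per_mode = 4, seed = 4)
  res <- boundary_pair_rmsd_correlation(st, identity_cutoff = 0.5)
  expect_false(res$flagged)
  expect_gte(length(res$match_rmsds), 10)
  expect_gte(length(res$mismatch_rmsds), 10)
  expect_lt(res$p_value, 0.01)
  expect_lt(median(res$match_rmsds), median(res$mismatch_rmsds))
})

test_that("a single shared boundary pair flags the correlation test", {
  st <- lapply(1:3, function(i) make_tfs(paste0("s", i), jit_seed = i,
                                         jsd = 0.3))
  res <- boundary_pair_rmsd_correlation(st, identity_cutoff = 1)
  expect_true(res$flagged)
  expect_true(is.na(res$p_value))
})

test_that("extraction round-trips simulated structures through PDB files", {
  tab <- make_mode_table(seed = 6)
  st <- simulate_structures(tab, n_per_mode = 1, seed = 6)[1:3]
  dir <- tempfile()
  paths <- write_structures_pdb(st, dir, dna_distance = 5)
  for (i in seq_along(paths)) {
    got <- extract_two_finger_arrays(paths[i])
    expect_length(got, 1)
    expect_identical(got[[1]]$boundary_pair, st[[i]]$boundary_pair)
    expect_identical(got[[1]]$sequence, st[[i]]$sequence)
    # coordinates survive the 3-decimal PDB round trip
    expect_lt(kabsch_superpose(rbind(st[[i]]$finger1_ca, st[[i]]$finger2_ca),
                               rbind(got[[1]]$finger1_ca,
                                     got[[1]]$finger2_ca))$rmsd, 1e-2)
    expect_lte(got[[1]]$min_dna_distance, 10)
  }
})

test_that("extraction enforces the resolution and DNA-distance filters", {
  tab <- make_mode_table(seed = 6)
  st <- simulate_structures(tab, n_per_mode = 1, seed = 6)[1]
  far <- write_structures_pdb(st, tempfile(), dna_distance = 12)
  expect_length(extract_two_finger_arrays(far[1]), 0)
  lowres <- write_structures_pdb(st, tempfile(), resolution = 3.5)
  expect_length(extract_two_finger_arrays(lowres[1]), 0)
  # a worse cutoff readmits the low-resolution entry
  expect_length(extract_two_finger_arrays(lowres[1], resolution_cutoff = 4),
                1)
})

test_that("a three-finger chain yields two adjacent two-finger arrays", {
  tab <- make_mode_table(seed = 2)
  st <- simulate_structures(tab, n_per_mode = 1, seed = 2)[1:2]
  # splice a third finger onto the first structure's chain by stacking
  # the second structure's finger 1 after finger 2
  extra <- sweep(st[[1]]$finger2_ca, 2, c(12, 0, 30), "+")
  s3 <- list(source_id = "threefinger",
             finger1_ca = st[[1]]$finger1_ca,
             finger2_ca = st[[1]]$finger2_ca,
             sequence = st[[1]]$sequence,
             boundary_pair = st[[1]]$boundary_pair, mode = NA)
  class(s3) <- "two_finger_structure"
  dir <- tempfile()
  path <- write_structures_pdb(list(s3), dir, dna_distance = 5)
  # append a third finger manually to the written chain
  lines <- readLines(path[1])
  atom <- grep("^ATOM", lines, value = TRUE)
  prot <- atom[grepl(" A ", atom, fixed = TRUE)]
  last_no <- 23 + 5 + 23
  f3seq <- strsplit(substr(st[[2]]$sequence, 1, 23), "")[[1]]
  add <- c(vapply(1:5, function(i)
    zfmode:::.pdb_atom_line(900 + i, " CA ", "GLY", "A", last_no + i,
                            extra[1, ] - c(0, 0, 6) + i * c(0, 0, 1),
                            "C"), character(1)),
    vapply(1:23, function(i)
      zfmode:::.pdb_atom_line(950 + i, " CA ",
                              bio3d::aa123(f3seq[i]), "A",
                              last_no + 5 + i, extra[i, ], "C"),
      character(1)))
  out <- tempfile(fileext = ".pdb")
  writeLines(c(lines[lines != "END" & !grepl("^ATOM.* B ", lines)],
               add, "END"), out)
  got <- extract_two_finger_arrays(out)
  expect_length(got, 2)
})
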