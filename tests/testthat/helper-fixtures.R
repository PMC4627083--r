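# Shared fixtures and independent oracles used across the test files.

# one-letter alphabets mirrored here so oracle code stays independent of
# package internals
AAs <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
Bs <- c("A", "C", "G", "T")

# Build one finger sequence around the classical Zif268-like template.
# Position of the first His is 19, so -2=11, -1=12, +1=13, +2=14, +3=15,
# +6=18, +9=21 within the 23-residue span.
finger_seq <- function(p6 = "R", p3 = "E", m1 = "R", p2 = "D",
                       m2 = "S", p9 = "R") {
  s <- strsplit("YKCPECGKSFSRSDELTRHIRTH", "")[[1]]
  s[18] <- p6; s[15] <- p3; s[12] <- m1; s[14] <- p2
  s[11] <- m2; s[21] <- p9
  paste(s, collapse = "")
}

# brute-force occupancy score: explicit loop over windows and strands
brute_affinity <- function(mat, sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  one_strand <- function(s) {
    m <- ncol(mat); L <- nchar(s)
    tot <- 0
    for (w in seq_len(L - m + 1)) {
      p <- 1
      for (j in seq_len(m))
        p <- p * mat[match(substr(s, w + j - 1, w + j - 1), Bs), j]
      tot <- tot + p
    }
    tot
  }
  unname(one_strand(sequence) + one_strand(revcomp(sequence)))
}

# brute-force proper-rotation RMSD: coarse Euler grid plus a local
# refinement at 2 degrees
grid_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  euler <- function(z1, y, z2) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    rz(z1) %*% ry(y) %*% rz(z2)
  }
  eval_r <- function(z1, y, z2) {
    R <- euler(z1, y, z2)
    sqrt(mean(rowSums((b %*% t(R) - a)^2)))
  }
  best <- c(0, 0, 0); best_r <- Inf
  step <- 15 * pi / 180
  for (z1 in seq(0, 2 * pi - step, by = step))
    for (y in seq(0, pi, by = step))
      for (z2 in seq(0, 2 * pi - step, by = step)) {
        r <- eval_r(z1, y, z2)
        if (r < best_r) { best_r <- r; best <- c(z1, y, z2) }
      }
  fine <- 2 * pi / 180
  rng <- seq(-step, step, by = fine)
  for (d1 in rng) for (d2 in seq(-step, step, by = fine))
    for (d3 in rng) {
      r <- eval_r(best[1] + d1, best[2] + d2, best[3] + d3)
      if (r < best_r) best_r <- r
    }
  best_r
}

# adjusted Rand index between two labelings (via mclust when available)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small planted gold standard shared by recognition tests
quick_gold <- function(seed = 1, n_train = 12, noise = 50,
                       mode_dependent = TRUE, ...) {
  code <- make_planted_code(mode_dependent = mode_dependent, seed = seed)
  tab <- make_mode_table(seed = seed)
  simulate_gold_standard(code, tab, n_train = n_train, n_test = 0,
                         noise = noise, seed = seed, ...)
}
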