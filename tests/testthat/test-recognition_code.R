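test_that("the training set has one example per finger with 4 or 6 factors", {
  g <- quick_gold(seed = 41, n_train = 6)
  n_fingers <- sum(vapply(g$train, function(c) length(c$array$fingers), 0L))
  ts6 <- make_training_set(g$train, with_boundary = TRUE)
  ts4 <- make_training_set(g$train, with_boundary = FALSE)
  expect_equal(nrow(ts6$covariates), n_fingers)
  expect_equal(ncol(ts6$covariates), 6)
  expect_equal(ncol(ts4$covariates), 4)
  expect_equal(dim(ts6$responses), c(n_fingers, 16))
  # every 4-base response block sums to 1
  for (b in 1:4)
    expect_equal(rowSums(ts6$responses[, (4 * b - 3):(4 * b)]),
                 rep(1, n_fingers), tolerance = 1e-9)
  # the N-terminal finger carries the distinguished NONE level
  firsts <- ts6$finger == 1
  expect_true(all(ts6$covariates$plus9_prev[firsts] == "NONE"))
  expect_true(all(ts6$covariates$plus9_prev[!firsts] != "NONE"))
})

test_that("responses are read off the registered experimental columns", {
  g <- quick_gold(seed = 42, n_train = 3)
  case <- g$train[[1]]
  n <- length(case$array$fingers)
  ts <- make_training_set(list(case), with_boundary = TRUE)
  for (i in seq_len(n)) {
    s <- 3 * (n - i) + 1
    block <- case$pwm$mat[, s + 0:3]
    expect_equal(unname(ts$responses[i, ]), as.vector(block),
                 tolerance = 1e-12)
  }
})

test_that("an unresolvable register is skipped with a message", {
  g <- quick_gold(seed = 43, n_train = 2)
  broken <- g$train
  broken[[1]]$register$offset <- 100L
  expect_message(ts <- make_training_set(broken), "skipped")
  expect_equal(length(unique(ts$case)), 1)
})

test_that("training is deterministic and constants stay constant", {
  g <- quick_gold(seed = 44, n_train = 6)
  ts <- make_training_set(g$train)
  m1 <- train_recognition_model(ts, n_trees = 30, seed = 7)
  m2 <- train_recognition_model(ts, n_trees = 30, seed = 7)
  arr <- g$train[[1]]$array
  expect_identical(predict_array_pwm(arr, m1)$mat,
                   predict_array_pwm(arr, m2)$mat)
  # constant responses give a degenerate constant regressor
  tsc <- ts
  tsc$responses[, ] <- rep(rep(0.25, 16), each = nrow(tsc$responses))
  mc <- train_recognition_model(tsc, n_trees = 10, seed = 1)
  p <- predict_array_pwm(arr, mc)
  expect_equal(unname(p$mat), matrix(0.25, 4, ncol(p$mat)))
})

test_that("a noiseless planted code is recovered on covered patterns", {
  # build training data directly: a handful of covariate patterns, each
  # repeated, with deterministic planted responses
  pats <- expand.grid(aa_p6 = c("R", "E"), aa_p3 = c("S", "K"),
                      aa_m1 = c("D", "N"), aa_p2 = c("T", "Q"),
                      stringsAsFactors = FALSE)
  pats$plus9_prev <- rep(c("R", "L"), length.out = nrow(pats))
  pats$minus2 <- rep(c("S", "I"), length.out = nrow(pats))
  resp_of <- function(r) {
    base <- (match(r$aa_p6, AAs) + match(r$plus9_prev, AAs)) %% 4 + 1
    block <- rep(0.05, 4); block[base] <- 0.85
    rep(block, 4)
  }
  reps <- 8
  covs <- pats[rep(seq_len(nrow(pats)), reps), ]
  resp <- t(apply(covs, 1, function(r) resp_of(as.list(r))))
  colnames(resp) <- paste(rep(paste0("pos", 1:4), each = 4),
                          rep(Bs, 4), sep = "_")
  for (nm in names(covs))
    covs[[nm]] <- factor(covs[[nm]],
                         levels = zfmode:::COVARIATE_LEVELS[[nm]])
  ex <- list(covariates = covs, responses = resp, with_boundary = TRUE)
  m <- train_recognition_model(ex, n_trees = 150, seed = 3)
  pb <- zfmode:::.predict_finger_blocks(m, covs[seq_len(nrow(pats)), ])
  for (i in seq_len(nrow(pats))) {
    want <- matrix(resp_of(as.list(pats[i, ])), 4)
    expect_lt(max(abs(pb$blocks[[i]] - want)), 0.05)
  }
})

test_that("assembled motifs have 3N+1 stochastic columns", {
  g <- quick_gold(seed = 45, n_train = 8)
  ts <- make_training_set(g$train)
  m <- train_recognition_model(ts, n_trees = 30, seed = 1)
  for (case in g$train[1:3]) {
    p <- predict_array_pwm(case$array, m)
    expect_equal(ncol(p$mat), 3 * length(case$array$fingers) + 1)
    expect_equal(colSums(p$mat), rep(1, ncol(p$mat)), tolerance = 1e-9)
    expect_true(all(p$mat >= 0))
  }
})

test_that("overlap columns average the two contributing predictions", {
  b1 <- matrix(0.25, 4, 4, dimnames = list(Bs, paste0("pos", 1:4)))
  b2 <- b1
  b1[, 4] <- c(1, 0, 0, 0)   # finger 2's +2-overlap prediction
  b2[, 1] <- c(0, 1, 0, 0)   # finger 1's +6 prediction, same column
  out <- zfmode:::.assemble_pwm(list(b2, b1), c(FALSE, FALSE), "toy")
  expect_equal(ncol(out$mat), 7)
  expect_equal(unname(out$mat[, 4]), c(0.5, 0.5, 0, 0))
  # equal contributions pass through unchanged
  b1[, 4] <- c(1, 0, 0, 0); b2[, 1] <- c(1, 0, 0, 0)
  out2 <- zfmode:::.assemble_pwm(list(b2, b1), c(FALSE, FALSE), "toy")
  expect_equal(unname(out2$mat[, 4]), c(1, 0, 0, 0))
})

test_that("register alignment finds offset, orientation and similarity", {
  g <- quick_gold(seed = 46, n_train = 3)
  p <- g$train[[1]]$pwm
  self <- align_register(p, p)
  expect_equal(self[c("offset", "orientation")],
               list(offset = 0L, orientation = "forward"),
               ignore_attr = TRUE)
  expect_equal(self$similarity, 1)
  padded <- pwm(cbind(matrix(0.25, 4, 2), p$mat), id = "padded")
  shifted <- align_register(p, padded)
  expect_equal(shifted$offset, 2L)
  expect_identical(shifted$orientation, "forward")
  rc <- align_register(p, revcomp_pwm(p))
  expect_identical(rc$orientation, "revcomp")
  expect_equal(rc$similarity, 1)
})

test_that("baseline columns replace empty and uninformative predictions", {
  sharp <- matrix(c(0.91, 0.03, 0.03, 0.03), 4, 7)
  baseline <- pwm(sharp, id = "baseline")
  pred <- pwm(matrix(0.25, 4, 7), id = "flat")
  merged <- merge_with_baseline(pred, baseline)
  expect_equal(merged$mat, baseline$mat)   # IC 0 < threshold everywhere
  keep <- pwm(sharp[c(2, 1, 3, 4), ], id = "keep")
  merged2 <- merge_with_baseline(keep, baseline)
  expect_equal(merged2$mat, keep$mat)      # all columns informative
  attr(keep, "empty_columns") <- 3L
  merged3 <- merge_with_baseline(keep, baseline)
  expect_equal(merged3$mat[, 3], baseline$mat[, 3])
  expect_equal(merged3$mat[, -3], keep$mat[, -3])
  expect_error(merge_with_baseline(pred, pwm(matrix(0.25, 4, 5))), "length")
})

test_that("unseen residues yield uniform columns that the baseline fills", {
  g <- quick_gold(seed = 47, n_train = 10)
  ts <- make_training_set(g$train)
  m <- train_recognition_model(ts, n_trees = 30, seed = 1)
  # an array using tryptophan, absent from the 12-residue simulation pool
  seqs <- paste0(finger_seq(p6 = "W", p9 = "R"), "TGEKP",
                 finger_seq(m2 = "S"))
  arr <- zf_array("unseen", seqs)
  p <- predict_array_pwm(arr, m)
  expect_gt(length(attr(p, "empty_columns")), 0)
  uniform_cols <- attr(p, "empty_columns")
  sharp <- pwm(matrix(c(0.91, 0.03, 0.03, 0.03), 4, ncol(p$mat)))
  merged <- merge_with_baseline(p, sharp)
  for (j in uniform_cols)
    expect_equal(merged$mat[, j], sharp$mat[, j])
})

test_that("the triplet body of a flipped array mirrors the original", {
  # flipping finger order reverses the triplet layout; the 3N shared
  # columns of the two predictions are reverse-complements of each other
  # (the single +2 overlap column necessarily moves to the other end)
  g <- quick_gold(seed = 48, n_train = 8)
  ts <- make_training_set(g$train, with_boundary = FALSE)
  m <- train_recognition_model(ts, n_trees = 40, seed = 2)
  case <- g$train[[1]]
  fs <- case$array$fingers
  flipped_seq <- paste(vapply(rev(seq_along(fs)), function(i)
    fs[[i]]$residues, character(1)), collapse = "TGEKP")
  flipped <- zf_array("flipped", flipped_seq)
  p <- predict_array_pwm(case$array, m)
  pf <- predict_array_pwm(flipped, m)
  n <- length(fs)
  for (i in seq_len(n)) {
    s <- 3 * (n - i) + 1      # finger i triplet in the original
    sf <- 3 * (i - 1) + 1     # same finger's triplet in the flip
    # both predictions carry the same three body columns for the finger
    # (in reversed array order), up to overlap-averaged edge columns
    expect_equal(p$mat[, s + 1], pf$mat[, sf + 1], tolerance = 1e-9)
  }
})

test_that("cross-validation partitions arrays without leakage", {
  g <- quick_gold(seed = 49, n_train = 8)
  cv <- crossvalidate_compare(g$train, k = 4, seed = 5, n_trees = 20)
  expect_length(cv$folds, 8)
  expect_setequal(unique(cv$folds), 1:4)
  expect_true(all(is.finite(cv$similarity_4)))
  expect_true(all(is.finite(cv$similarity_6)))
  expect_error(crossvalidate_compare(g$train, k = 9, seed = 1), "exceeds")
  # training examples never include the held-out fold's arrays
  for (f in 1:4) {
    ts <- make_training_set(g$train[cv$folds != f])
    expect_lt(length(unique(ts$case)), 8)
  }
})
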