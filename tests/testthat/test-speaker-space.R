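test_that("collinearity filter removes duplicates and keeps orthogonal sets", {
  set.seed(1)
  n <- 60
  a <- rnorm(n)
  tbl <- data.frame(speaker_id = "s", f0_mean = a, f0_max = a,
                    HNR = rnorm(n), ent = rnorm(n))
  kept <- collinearity_filter(tbl, r_max = 0.8,
                              features = c("f0_mean", "f0_max", "HNR", "ent"))
  expect_length(intersect(kept, c("f0_mean", "f0_max")), 1)
  expect_true(all(c("HNR", "ent") %in% kept))

  ortho <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  kept2 <- collinearity_filter(ortho, r_max = 0.8,
                               features = c("x1", "x2", "x3"))
  expect_setequal(kept2, c("x1", "x2", "x3"))
  expect_error(collinearity_filter(tbl, r_max = 1.5), "r_max")
})

test_that("a derived feature and both its parents never survive together", {
  set.seed(2)
  n <- 80
  f0_min <- 150 + 5 * rnorm(n)            # nearly-stable lower extreme
  f0_range <- 40 + 25 * rnorm(n)
  f0_max <- f0_min + f0_range             # child-parent |r| above threshold
  tbl <- data.frame(
    f0_max = f0_max, f0_min = f0_min, f0_range = f0_range, ent = rnorm(n)
  )
  stopifnot(abs(cor(tbl$f0_max, tbl$f0_range)) >= 0.8)
  kept <- collinearity_filter(tbl, r_max = 0.8,
                              features = c("f0_range", "f0_max", "f0_min", "ent"))
  r <- abs(cor(tbl[, kept]))
  diag(r) <- 0
  expect_lt(max(r), 0.8)
  expect_false(all(c("f0_range", "f0_max", "f0_min") %in% kept))
})

test_that("discriminant projections match the brute-force eigen oracle", {
  for (seed in 1:5) {
    G <- 2 + seed %% 3
    p <- 2 + seed %% 4
    tbl <- make_feature_table(G, 12, p, sep = 2, seed = seed)
    m <- fit_lda(tbl, paste0("x", seq_len(p)))
    or <- oracle_lda(tbl, paste0("x", seq_len(p)))
    X <- as.matrix(tbl[, paste0("x", seq_len(p))])
    expect_lt(max(abs(X %*% m$discriminants - X %*% or$A)), 1e-8)
    expect_lt(max(abs(m$eigenvalues - or$eigenvalues)), 1e-8)
  }
})

test_that("classification agrees with the reference LDA implementation", {
  tbl <- make_feature_table(4, 15, 4, sep = 1.5, seed = 9)
  feats <- paste0("x", 1:4)
  m <- fit_lda(tbl, feats)
  ours <- voicemarkers:::classify_nearest(m, tbl)
  ref <- MASS::lda(tbl[, feats], grouping = factor(tbl$speaker_id))
  theirs <- as.character(predict(ref, tbl[, feats])$class)
  expect_gt(mean(ours == theirs), 0.99)
})

test_that("feature rescaling leaves loadings and classification unchanged", {
  tbl <- make_feature_table(3, 12, 3, sep = 2, seed = 4)
  feats <- paste0("x", 1:3)
  m1 <- fit_lda(tbl, feats)
  tbl2 <- tbl
  tbl2$x1 <- tbl2$x1 / 1000  # Hz -> kHz
  m2 <- fit_lda(tbl2, feats)
  expect_equal(abs(m1$loadings), abs(m2$loadings), tolerance = 1e-6)
  expect_identical(voicemarkers:::classify_nearest(m1, tbl),
                   voicemarkers:::classify_nearest(m2, tbl2))
})

test_that("a single separating feature carries the top loading", {
  set.seed(11)
  n <- 40
  tbl <- data.frame(
    speaker_id = rep(c("A", "B"), each = n),
    f0_mean = c(rnorm(n, 180), rnorm(n, 220)),
    noise1 = rnorm(2 * n), noise2 = rnorm(2 * n)
  )
  m <- fit_lda(tbl, c("f0_mean", "noise1", "noise2"))
  expect_equal(rownames(m$loadings)[which.max(abs(m$loadings[, 1]))],
               "f0_mean")
})

test_that("zero within-group variance classifies perfectly; permuted labels at chance", {
  # distinct group means, (near-)zero within-group spread
  set.seed(6)
  means <- matrix(c(0, 0, 4, -4, -4, 4), nrow = 3, byrow = TRUE)
  tbl <- data.frame(
    speaker_id = rep(c("A", "B", "C"), each = 10),
    x1 = rep(means[, 1], each = 10) + 1e-6 * rnorm(30),
    x2 = rep(means[, 2], each = 10) + 1e-6 * rnorm(30)
  )
  m <- suppressMessages(fit_lda(tbl, c("x1", "x2")))
  expect_equal(classification_success(m, tbl, "resubstitution"), 100)

  set.seed(21)
  big <- make_feature_table(15, 10, 4, sep = 2, seed = 12)
  big$speaker_id <- sample(big$speaker_id)
  mp <- fit_lda(big, paste0("x", 1:4))
  succ <- classification_success(mp, big, "loo")  # cross-validated chance
  expect_lt(abs(succ - 100 / 15), 5)
})

test_that("resubstitution success is at least leave-one-out on average", {
  diffs <- vapply(1:20, function(s) {
    tbl <- make_feature_table(3, 8, 3, sep = 1, seed = 100 + s)
    m <- fit_lda(tbl, paste0("x", 1:3))
    classification_success(m, tbl, "resubstitution") -
      classification_success(m, tbl, "loo")
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("marker selection applies the loading threshold exactly", {
  m <- list(loadings = matrix(c(2.0, -1.5, 0.4, 0.1, 1.29, -0.2),
                              nrow = 3,
                              dimnames = list(c("a", "b", "c"), c("LD1", "LD2"))),
            selection_threshold = 1.3)
  expect_identical(select_markers(m), c("a", "b"))
  low <- list(loadings = matrix(c(1.3, -1.2, 0.4), nrow = 3,
                                dimnames = list(c("a", "b", "c"), "LD1")),
              selection_threshold = 1.3)
  expect_warning(sel <- select_markers(low), "threshold")
  expect_length(sel, 0)
})

test_that("acoustic distances are symmetric, nonnegative, translation invariant", {
  owner <- c(f0_mean = 180, ppj = 0.02)
  control <- c(f0_mean = 220, ppj = 0.05)
  d <- acoustic_distance(owner, control, c("f0_mean", "ppj"))
  expect_equal(unname(d["f0_mean"]), 40)
  expect_identical(d, acoustic_distance(control, owner, c("f0_mean", "ppj")))
  expect_true(all(acoustic_distance(owner, owner, names(owner)) == 0))
  shift <- acoustic_distance(owner + 100, control + 100, c("f0_mean", "ppj"))
  expect_equal(d, shift)
  expect_error(acoustic_distance(c(f0_mean = NA), c(f0_mean = 1), "f0_mean"),
               "missing")

  tr <- data.frame(dist_f0_mean = c(1, 4, 2, 9, 3))
  z <- zscore_distances(tr, "f0_mean")
  expect_equal(mean(z$zdist_f0_mean), 0, tolerance = 1e-12)
  expect_equal(sd(z$zdist_f0_mean), 1, tolerance = 1e-12)
})
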