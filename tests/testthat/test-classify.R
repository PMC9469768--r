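test_that("tier binning uses half-open boundaries and sends negatives to the lowest bin", {
  expect_identical(as.character(bin_concentration(-0.1, "multiclass")),
                   "le_0.2")
  expect_identical(as.character(bin_concentration(-0.1, "binary")), "le_0.5")
  expect_identical(as.character(bin_concentration(0.5, "binary")), "le_0.5")
  expect_identical(as.character(bin_concentration(0.50001, "binary")),
                   "gt_0.5")
  expect_identical(as.character(bin_concentration(0.2, "multiclass")),
                   "le_0.2")
  expect_identical(as.character(bin_concentration(0.200001, "multiclass")),
                   "mid_0.2_0.5")
  expect_identical(as.character(bin_concentration(c(0.1, 0.3, 2),
                                                  "multiclass")),
                   c("le_0.2", "mid_0.2_0.5", "gt_0.5"))
  expect_error(bin_concentration(NaN), "NaN")
})

test_that("confusion counts land in (predicted row, true column) position", {
  truth <- c("le_0.5", "gt_0.5", "gt_0.5", "le_0.5")
  pred  <- c("le_0.5", "le_0.5", "gt_0.5", "le_0.5")
  cm <- confusion(truth, pred, "binary")
  expect_equal(cm["le_0.5", "le_0.5"], 2)
  expect_equal(cm["le_0.5", "gt_0.5"], 1)  # predicted positive, truly high
  expect_equal(cm["gt_0.5", "gt_0.5"], 1)
  expect_equal(sum(cm), 4)
  # perfect predictions give a diagonal matrix
  cmd <- confusion(truth, truth, "binary")
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  # labels reconstructed from the published binary training counts map back
  tt <- rep(c("le_0.5", "gt_0.5", "le_0.5", "gt_0.5"), c(46, 9, 1, 41))
  pp <- rep(c("le_0.5", "le_0.5", "gt_0.5", "gt_0.5"), c(46, 9, 1, 41))
  expect_equal(unclass(confusion(tt, pp, "binary")),
               unclass(published_confusion("binary_training")),
               ignore_attr = TRUE)
  # empty inputs: an all-zero matrix whose metrics are undefined
  cm0 <- confusion(character(), character(), "binary")
  expect_equal(sum(cm0), 0)
  expect_error(metrics(cm0), "undefined|empty")
  expect_error(confusion("le_0.5", c("le_0.5", "gt_0.5"), "binary"),
               "length")
  expect_error(confusion("apple", "le_0.5", "binary"), "labels")
})

test_that("the metric suite reproduces the published training/testing summaries", {
  expect_equal(percent_round(
    metrics(published_confusion("binary_training"))$accuracy), 90)
  expect_equal(percent_round(
    metrics(published_confusion("binary_testing"))$accuracy), 94)
  expect_equal(percent_round(
    metrics(published_confusion("multiclass_training"))$weighted_f1), 79)
  expect_equal(percent_round(
    metrics(published_confusion("multiclass_testing"))$weighted_f1), 88)
})

test_that("metric identities hold on random confusion matrices", {
  for (seed in 1:10) {
    cm <- withr::with_seed(seed, {
      as_tier_confusion(matrix(rpois(9, 12), 3, 3), "multiclass")
    })
    mt <- suppressWarnings(metrics(cm))
    expect_equal(mt$micro_f1, mt$accuracy, tolerance = 1e-12)
    expect_gte(mt$weighted_f1, min(mt$per_class$f1) - 1e-12)
    expect_lte(mt$weighted_f1, max(mt$per_class$f1) + 1e-12)
    expect_true(all(unlist(mt[c("accuracy", "micro_f1", "weighted_f1")]) >= 0))
    expect_true(all(unlist(mt[c("accuracy", "micro_f1", "weighted_f1")]) <= 1))
    # simultaneous row/column permutation with relabeling leaves metrics alone
    perm <- withr::with_seed(seed + 50, sample(3))
    mcm <- unclass(cm)[perm, perm]
    mt2 <- suppressWarnings(metrics(as_tier_confusion(mcm, "multiclass")))
    expect_equal(mt2$accuracy, mt$accuracy)
    expect_equal(mt2$weighted_f1, mt$weighted_f1)
  }
  # one-class predictor on balanced binary truth
  one <- as_tier_confusion(c(10, 10, 0, 0), "binary")
  expect_equal(suppressWarnings(metrics(one))$accuracy, 0.5)
})

test_that("stratified split preserves the group proportions of the reference table", {
  rows <- tibble::tibble(group = rep(1:6, times = c(21, 27, 54, 36, 46, 8)))
  sp <- stratified_split(rows, 0.67, seed = 3)
  expect_equal(as.integer(table(sp$train$group)),
               c(14, 18, 36, 24, 31, 6))
  expect_equal(nrow(sp$train), 129)
  expect_equal(nrow(sp$test), 63)
  sp2 <- stratified_split(rows, 0.67, seed = 3)
  expect_identical(sp$train, sp2$train)
  expect_warning(stratified_split(rows, 1, seed = 1), "empty test")
})

test_that("resampled validation repeats splits and has zero spread on noiseless data", {
  rows <- ref_calibration_rows(seq(0.05, 3.8, length.out = 48))
  rv <- resampled_validation(rows, n_repeats = 10, seed = 2)
  expect_equal(nrow(rv$per_repeat), 10)
  expect_true(all(rv$per_repeat$ok))
  expect_equal(rv$summary$n_ok, c(10, 10))
  # noiseless color-to-concentration mapping: every repeat classifies its
  # held-out set almost perfectly, so the spread collapses
  expect_gt(min(rv$per_repeat$accuracy), 0.85)
  rv1 <- resampled_validation(rows, n_repeats = 1, seed = 2)
  expect_equal(rv1$per_repeat$accuracy[1], rv$per_repeat$accuracy[1])
})

test_that("pooled z-test matches hand arithmetic and is null-calibrated", {
  eq <- proportion_z_test(10, 20, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  zt <- proportion_z_test(90, 100, 50, 100)
  pool <- 140 / 200
  z_hand <- (0.9 - 0.5) / sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  expect_equal(zt$z, z_hand)
  expect_equal(zt$p, 2 * pnorm(-abs(z_hand)))
  expect_error(proportion_z_test(0, 10, 0, 10), "variance")
  # null p-values are uniform
  ps <- withr::with_seed(7, {
    n <- 1000
    s1 <- rbinom(1500, n, 0.4); s2 <- rbinom(1500, n, 0.4)
    vapply(seq_along(s1), function(i) {
      proportion_z_test(s1[i], n, s2[i], n)$p
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("multi-group proportions get pairwise z-tests plus a chi-square", {
  pt <- proportion_tests(c(30, 28, 20), c(40, 40, 40))
  expect_equal(nrow(pt$pairwise), 3)
  expect_s3_class(pt$chisq, "htest")
  expect_true(all(pt$pairwise$p >= 0 & pt$pairwise$p <= 1))
})
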