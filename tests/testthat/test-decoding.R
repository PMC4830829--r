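test_that("sensitivity and specificity follow the confusion-table definitions", {
  m <- classification_metrics(tp = 3, fn = 1, tn = 2, fp = 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 5 / 8)
  expect_equal(mae(c(5, 7), c(4, 8)), 1)
  expect_equal(mae(c(2, 9, 4), c(2, 9, 4)), 0)
})

test_that("pattern aggregation modes produce the documented predictor layout", {
  fm <- make_tiny_fm(8, seed = 1)
  pats <- lapply(1:5, function(i) structure(
    list(name = paste0("p", i), phase = "post", features = ((i - 1) * 3 + 1):(i * 3),
         sign = 1L, cluster_p = 0.01), class = "pattern"))
  Xp <- aggregate_pattern_features(fm, pats, "mean")
  expect_equal(dim(Xp), c(8L, 5L))
  expect_identical(colnames(Xp), paste0("p", 1:5))
  expect_equal(Xp[, 2], rowMeans(fm$values[, 4:6]))

  single <- structure(list(name = "s", phase = "pre", features = 7L,
                           sign = 1L, cluster_p = 0.01), class = "pattern")
  expect_equal(as.numeric(aggregate_pattern_features(fm, list(single), "mean")),
               as.numeric(aggregate_pattern_features(fm, list(single), "pixels")))

  fm_const <- make_tiny_fm(2, values = matrix(4.2, 2, 24))
  expect_equal(as.numeric(aggregate_pattern_features(fm_const, pats[1], "mean")),
               c(4.2, 4.2))
  expect_error(aggregate_pattern_features(fm, list()), "no patterns")
})

test_that("raw-scale aggregation adds back the energy-group means", {
  fm <- normalize_by_energy(make_tiny_fm(12, seed = 2))
  pat <- structure(list(name = "p", phase = "post", features = 1:4, sign = 1L,
                        cluster_p = 0.01), class = "pattern")
  raw <- aggregate_pattern_features(fm, list(pat), "mean", scale = "raw")
  norm <- aggregate_pattern_features(fm, list(pat), "mean")
  expect_false(isTRUE(all.equal(as.numeric(raw), as.numeric(norm))))
  expect_equal(as.numeric(raw), rowMeans(raw_values(fm)[, 1:4]))
})

test_that("linearly separated classes are classified perfectly", {
  set.seed(13)
  ratings <- c(rep(2, 10), rep(8, 10))
  Xp <- cbind(ratings + rnorm(20, sd = 0.01), rnorm(20))
  res <- loocv_classify(Xp, ratings)
  expect_equal(res$metrics$accuracy, 1)
  expect_equal(res$metrics$sensitivity, 1)
  expect_equal(res$metrics$specificity, 1)
})

test_that("a class with fewer than 2 trials aborts so the subject can be skipped", {
  Xp <- matrix(rnorm(10), 10, 1)
  expect_error(loocv_classify(Xp, c(9, rep(2, 9))), "skipped")
})

test_that("noiseless linear targets are regressed within the epsilon tube", {
  set.seed(14)
  x <- rnorm(40)
  energies <- rep("E1", 40)            # one group: no group-mean confound
  y <- 5 + 2 * x
  res <- loocv_regress(cbind(x), y, energies, target_mode = "normalized")
  expect_lt(res$metrics$mae, 0.1)
  res_raw <- loocv_regress(cbind(x), y, energies, target_mode = "raw")
  expect_lt(res_raw$metrics$mae, 0.2)
})

test_that("an energy unseen in training raises an error", {
  x <- rnorm(7)
  energies <- c("E4", rep("E1", 3), rep("E2", 3))
  expect_error(loocv_regress(cbind(x), rnorm(7) + 5, energies), "E4")
})

test_that("stored aggregates are recomputable from per-trial records", {
  set.seed(15)
  Xp <- matrix(rnorm(40 * 2), 40, 2)
  ratings <- pmin(pmax(rnorm(40, 5, 2), 0), 10)
  cls <- loocv_classify(Xp, ratings)
  tr <- cls$trials
  tp <- sum(tr$true_class == "high" & tr$pred_class == "high")
  fn <- sum(tr$true_class == "high" & tr$pred_class == "low")
  tn <- sum(tr$true_class == "low" & tr$pred_class == "low")
  fp <- sum(tr$true_class == "low" & tr$pred_class == "high")
  expect_identical(cls$metrics[c("tp", "fn", "tn", "fp")],
                   list(tp = tp, fn = fn, tn = tn, fp = fp))
  expect_equal(cls$metrics$sensitivity * (tp + fn), tp, tolerance = 1e-12)
  expect_equal(cls$metrics$specificity * (tn + fp), tn, tolerance = 1e-12)

  reg <- loocv_regress(Xp, ratings, rep(energy_levels(), 10))
  expect_equal(reg$metrics$mae,
               mean(abs(reg$trials$true_value - reg$trials$pred_value)),
               tolerance = 1e-12)
})

test_that("LOOCV never leaks the held-out trial into its own prediction", {
  set.seed(16)
  Xp <- matrix(rnorm(30 * 3), 30, 3)
  ratings <- pmin(pmax(rnorm(30, 5, 2), 0), 10)
  energies <- rep(energy_levels(), length.out = 30)
  j <- 11L
  reg1 <- loocv_regress(Xp, ratings, energies, target_mode = "raw")
  corrupted <- ratings
  corrupted[j] <- 0.12
  reg2 <- loocv_regress(Xp, corrupted, energies, target_mode = "raw")
  expect_equal(reg1$trials$pred_value[j], reg2$trials$pred_value[j],
               tolerance = 1e-12)

  cls1 <- loocv_classify(Xp, ratings)
  flipped <- ratings
  flipped[j] <- if (ratings[j] >= 5) 1 else 9
  cls2 <- loocv_classify(Xp, flipped)
  expect_identical(cls1$trials$pred_class[j], cls2$trials$pred_class[j])
})

test_that("an all-noise extra predictor only mildly perturbs separable decoding", {
  set.seed(17)
  ratings <- c(rep(2, 12), rep(8, 12))
  Xp <- cbind(signal = ratings + rnorm(24, sd = 0.3))
  clean <- loocv_classify(Xp, ratings)$metrics$accuracy
  noisy <- loocv_classify(cbind(Xp, noise = rnorm(24)), ratings)$metrics$accuracy
  expect_gte(noisy, 0.9 * clean)
})

test_that("feature-set comparisons flag their degenerate edge cases", {
  a <- c(S1 = 0.8, S2 = 0.7, S3 = 0.9)
  same <- compare_feature_sets(a, a)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "identical")

  shifted <- compare_feature_sets(a + 0.05, a)
  expect_equal(shifted$flag, "constant-difference")
  expect_equal(shifted$mean_diff, 0.05)
  expect_true(is.na(shifted$p))

  set.seed(18)
  b <- a + rnorm(3, 0.1, 0.01)
  ok <- compare_feature_sets(b, a)
  expect_equal(ok$flag, "ok")
  expect_equal(sign(ok$t), sign(ok$mean_diff))
  expect_true(ok$p > 0 && ok$p <= 1)

  expect_error(compare_feature_sets(a, a[1:2]), "mismatch")
  expect_error(compare_feature_sets(a, rev(a)), "mismatch")
})

test_that("ranking requires two patterns and returns one row per pattern", {
  fm <- normalize_by_energy(make_tiny_fm(16, seed = 20, meta = make_meta(16)))
  pats <- lapply(1:3, function(i) structure(
    list(name = paste0("p", i), phase = if (i == 1) "pre" else "post",
         features = ((i - 1) * 4 + 1):(i * 4), sign = 1L, cluster_p = 0.01),
    class = "pattern"))
  fm2 <- normalize_by_energy(make_tiny_fm(16, seed = 21, meta = make_meta(16)))
  fm3 <- normalize_by_energy(make_tiny_fm(16, seed = 22, meta = make_meta(16)))
  expect_error(rank_patterns(list(fm), pats[1]), "2 patterns")
  rk <- rank_patterns(list(fm, fm2, fm3), pats)
  expect_equal(nrow(rk), 3)
  expect_setequal(rk$pattern, c("p1", "p2", "p3"))
  expect_true(all(diff(rk$mean_accuracy) <= 0))
  ps <- attr(rk, "per_subject")
  expect_length(ps$p1$accuracy, 3)
})
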