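test_that("make_splits produces stratified 80/10/10 partitions", {
  y <- c(rep(0, 50), rep(1, 50))
  sp <- make_splits(y, seed = 3)
  expect_length(sp$test, 10)
  expect_length(sp$validation, 10)
  expect_length(sp$train, 80)
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_along(y))
  # stratification within one sample of global proportions
  for (part in list(sp$test, sp$validation, sp$train)) {
    expect_lte(abs(mean(y[part]) - 0.5) * length(part), 1)
  }
  # the real cohort's shape: 1013 = 680 + 333 gives 811/101/101
  y2 <- c(rep(0, 680), rep(1, 333))
  sp2 <- make_splits(y2, seed = 1)
  expect_length(sp2$train, 811)
  expect_length(sp2$test, 101)
  expect_length(sp2$validation, 101)
  # deterministic given seed
  expect_identical(make_splits(y2, seed = 9), make_splits(y2, seed = 9))
  expect_error(make_splits(c(rep(0, 5), rep(1, 50))), "at least 10")
})

test_that("cv folds are stratified, disjoint and exhaustive", {
  y <- rep(c(0, 1), 5)
  folds <- make_cv_folds(y, k = 5, seed = 2)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_along(y))
  for (f in folds) {
    expect_identical(sum(y[f$test]), 1)      # one of each class per fold
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), seq_along(y))
  }
  y3 <- c(rep(0, 37), rep(1, 18))
  folds3 <- make_cv_folds(y3, k = 5, seed = 7)
  glob <- mean(y3)
  for (f in folds3) {
    expect_lte(abs(sum(y3[f$test]) - glob * length(f$test)), 1)
  }
  expect_error(make_cv_folds(c(0, 0, 0, 1, 1), k = 3), "minority")
})

test_that("AUC equals the pair-counting oracle, including ties", {
  expect_equal(compute_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc,
               0.75)
  expect_equal(compute_metrics(c(0, 1), c(0.1, 0.9))$auc, 1)
  expect_equal(compute_metrics(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  # exhaustive-style property: random score vectors with heavy ties, n <= 50
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(2:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))       # both classes guaranteed
    s <- sample(seq(0, 1, by = 0.1), n, TRUE)    # many exact ties
    expect_equal(rank_auc(y, s), pair_count_auc(y, s),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("threshold metrics and AUPRC behave at the edges", {
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_identical(m$auprc, 1)
  expect_identical(m$accuracy, 1)
  expect_identical(m$f1, 1)
  # no positive predictions: precision undefined -> 0 and flagged
  m2 <- compute_metrics(c(0, 1), c(0.1, 0.2))
  expect_false(m2$precision_defined)
  expect_identical(m2$precision, 0)
  # AUPRC against a hand case: y ordered by score (1, 0, 1):
  # recall steps at prec 1/1 and 2/3
  m3 <- compute_metrics(c(1, 0, 1), c(0.9, 0.5, 0.3))
  expect_equal(m3$auprc, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_warning(ms <- compute_metrics(c(1, 1), c(0.2, 0.8)), "one class")
  expect_true(is.na(ms$auc) && is.na(ms$auprc))
})

test_that("DeLong test matches oracles and is symmetric", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  dt <- delong_test(y, s, rev(s))
  expect_equal(dt$auc_a, pair_count_auc(y, s), tolerance = 1e-12)
  # identical scores: zero variance of the difference, p = 1
  expect_identical(delong_test(y, s, s)$p_value, 1)
  # symmetry
  set.seed(5)
  y2 <- rep(c(0, 1), 20)
  a <- rnorm(40) + y2; b <- rnorm(40) + 0.3 * y2
  expect_equal(delong_test(y2, a, b)$p_value,
               delong_test(y2, b, a)$p_value, tolerance = 1e-12)
  # cross-check p-value and AUCs against pROC's DeLong implementation
  pr <- pROC::roc.test(pROC::roc(y2, a, quiet = TRUE),
                       pROC::roc(y2, b, quiet = TRUE), method = "delong")
  mine <- delong_test(y2, a, b)
  expect_equal(mine$p_value, unname(pr$p.value), tolerance = 1e-9)
  expect_equal(mine$auc_a, as.numeric(pr$estimate[1]), tolerance = 1e-12)
})

test_that("bootstrap comparison is smoothed, two-sided and seeded", {
  y <- rep(c(0, 1), 15)
  set.seed(1)
  s <- rnorm(30) + y
  b1 <- bootstrap_median_test(y, s, s, n_boot = 200, seed = 3)
  expect_identical(b1$p_value, 1)
  # determinism
  set.seed(99)
  s2 <- rnorm(30) + 0.5 * y
  p_a <- bootstrap_median_test(y, s, s2, n_boot = 300, seed = 7)$p_value
  p_b <- bootstrap_median_test(y, s, s2, n_boot = 300, seed = 7)$p_value
  expect_identical(p_a, p_b)
  # the add-one smoothing floor: a overwhelmingly better than b
  yy <- rep(c(0, 1), 25)
  strong <- yy + stats::rnorm(50, sd = 0.01)
  weak <- stats::rnorm(50)
  p_min <- bootstrap_median_test(yy, strong, weak, n_boot = 2000, seed = 1)$p_value
  expect_equal(p_min, 2 / 2001, tolerance = 1e-12)
})

test_that("BH adjustment matches hand-computed examples and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_identical(fdr_adjust(0.2), 0.2)
  expect_identical(fdr_adjust(rep(1, 4)), rep(1, 4))
  # sorted (0.005, 0.03, 0.04): 0.005*3/1, min-forward of 0.03*3/2 and
  # 0.04*3/3 -> (0.015, 0.04, 0.04)
  expect_equal(fdr_adjust(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
  # permutation equivariance
  set.seed(2)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("chi-squared with Yates correction uses the clamped statistic", {
  r <- chi2_yates(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(r$statistic, 5.4, tolerance = 1e-12)
  expect_true(all(r$expected == 15))
  expect_identical(chi2_yates(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi2_yates(matrix(c(0, 0, 5, 5), 2, 2)), "margins")
  expect_error(chi2_yates(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
})

test_that("log-rank test reproduces the hand-computed toy example", {
  # identical groups: no difference
  r0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  # group A events at 1, 2; group B events at 3, 4: O - E = 7/6, V = 17/36
  r <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(r$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-6)
  expect_equal(r$statistic, 2.88, tolerance = 0.01)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "at least one event")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two non-empty")
})

test_that("learning curve self-comparison yields p = 1 and sorted sizes", {
  co <- tiny_cohort(seed = 12, n = 120, p1 = 0.5)
  X <- as_input_matrix(co$tensor)
  lb <- pnet:::builder_logistic()
  lc <- learning_curve(X, co$labels,
                       list(log_a = lb, log_b = lb),
                       sizes = c(100, 60), k = 5, seeds = 1,
                       metrics = "auc")
  expect_identical(unique(lc$tests$size), c(60, 100))
  expect_true(all(lc$tests$p_value == 1))        # identical builders
  expect_true(all(lc$summary$mean >= 0 & lc$summary$mean <= 1))
  expect_error(learning_curve(X, co$labels, list(a = lb), sizes = 5, k = 5),
               "2 \\* k")
})

test_that("baselines separate separable data and handle degenerate input", {
  co <- tiny_cohort(seed = 14, n = 80, p1 = 1, p0 = 0)
  X <- as_input_matrix(co$tensor)
  sp <- make_splits(co$labels, seed = 2)
  tr <- c(sp$train, sp$validation)
  bl <- baselines(X[tr, ], co$labels[tr], X[sp$test, ], co$labels[sp$test])
  expect_identical(bl$logistic$metrics$auc, 1)
  expect_identical(bl$svm_linear$metrics$auc, 1)
  # constant features: majority-class fallback accuracy
  Xc <- matrix(1, 60, 4)
  yc <- rep(c(0, 0, 1), 20)
  blc <- suppressWarnings(
    baselines(Xc[1:48, ], yc[1:48], Xc[49:60, ], yc[49:60]))
  expect_equal(blc$decision_tree$metrics$accuracy,
               mean(yc[49:60] == 0), tolerance = 1e-12)
})

test_that("null calibration: tests reject at about the nominal rate", {
  # label permutation null, moderate rep count for the module test (the
  # acceptance suite runs the full 200-rep version)
  set.seed(31)
  n <- 80
  y <- rep(c(0, 1), n / 2)
  a <- rnorm(n); b <- rnorm(n)
  reject_d <- 0; reps <- 60
  for (r in 1:reps) {
    yp <- sample(y)
    if (delong_test(yp, a, b)$p_value < 0.05) reject_d <- reject_d + 1
  }
  expect_lte(reject_d / reps, 0.15)
})
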