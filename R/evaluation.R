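#' Stratified train/validation/test split
#'
#' Splits by label into test (`test_frac`), validation (same size as test)
#' and training (the rest). Per class the test count is `round(n_c *
#' test_frac)` (round-half-even, R's `round`); validation matches it, so on
#' 1013 samples (680/333) the split is 811 train / 101 validation / 101
#' test.
#'
#' @param labels 0/1 vector.
#' @param test_frac Test fraction (default 0.10).
#' @param seed RNG seed.
#' @return List of class `split_spec` with integer index vectors `train`,
#'   `validation`, `test`.
#' @export
make_splits <- function(labels, test_frac = 0.10, seed = 1) {
  y <- as.integer(labels)
  if (min(table(y)) < 10) stop("each class needs at least 10 samples")
  set.seed(seed)
  test <- integer(0); val <- integer(0); train <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    n_test <- round(length(idx) * test_frac)
    if (n_test < 1) stop("class ", cls, " too small for test fraction")
    test <- c(test, idx[seq_len(n_test)])
    val <- c(val, idx[n_test + seq_len(n_test)])
    train <- c(train, idx[-(seq_len(2 * n_test))])
  }
  structure(list(train = sort(train), validation = sort(val),
                 test = sort(test), seed = seed),
            class = "split_spec")
}

#' Stratified k-fold cross-validation folds
#'
#' @param labels 0/1 vector (the development set labels).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return List of `k` elements, each `list(train =, test =)` index
#'   vectors; the test sets partition the input and class proportions per
#'   fold are within one sample of the global proportions.
#' @export
make_cv_folds <- function(labels, k = 5, seed = 1) {
  y <- as.integer(labels)
  stopifnot(k >= 2)
  if (k > min(table(y))) stop("k exceeds the minority class size")
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' AUC of the ROC curve by the rank statistic
#'
#' Equivalent to the probability that a random positive outscores a random
#' negative; midranks give ties a half count. `NA` when a class is absent.
#'
#' @param y 0/1 labels.
#' @param s Scores.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(y, s) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# step-interpolated area under the precision-recall curve
step_auprc <- function(y, s) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == length(y)) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  # evaluate at the last index of each tied-score block
  last <- which(c(ss[-length(ss)] != ss[-1], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics at a fixed threshold plus ranking metrics
#'
#' AUC is the rank statistic with midrank tie correction; AUPRC is the
#' step-interpolated precision-recall area. Accuracy, F1, precision and
#' recall use the 0.5 threshold by default. With no positive predictions,
#' precision is undefined: it is reported as 0 and flagged.
#'
#' @param y 0/1 labels.
#' @param scores Predicted scores.
#' @param threshold Classification cutoff (default 0.5).
#' @return List of class `metric_set`: `auc`, `auprc`, `accuracy`, `f1`,
#'   `precision`, `recall`, `precision_defined`.
#' @export
compute_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(length(y) == length(scores))
  single_class <- length(unique(y)) < 2
  if (single_class) {
    warning("only one class present: AUC and AUPRC are undefined (NA)")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (sum(y == 1) > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(
    auc = if (single_class) NA_real_ else rank_auc(y, scores),
    auprc = if (single_class) NA_real_ else step_auprc(y, scores),
    accuracy = mean(pred == y),
    f1 = f1,
    precision = precision,
    recall = recall,
    precision_defined = precision_defined
  ), class = "metric_set")
}

#' @exportS3Method base::print
print.metric_set <- function(x, ...) {
  v <- unlist(x[c("auc", "auprc", "accuracy", "f1", "precision", "recall")])
  print(round(v, 4))
  invisible(x)
}

#' DeLong test for two correlated ROC AUCs
#'
#' Paired nonparametric comparison of the AUCs of two score vectors on the
#' same samples, using the DeLong structural-component covariance estimate
#' and a two-sided normal test. With identical scores (zero variance of the
#' difference) the p-value is 1.
#'
#' @param y 0/1 labels.
#' @param scores_a,scores_b Score vectors of the two models.
#' @return List: `auc_a`, `auc_b`, `statistic` (z), `p_value`.
#' @export
delong_test <- function(y, scores_a, scores_b) {
  y <- as.integer(y)
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0 || length(neg) == 0) stop("both classes required")
  comp <- function(s) {
    X <- s[pos]; Y <- s[neg]
    psi <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  ca <- comp(scores_a); cb <- comp(scores_b)
  m <- length(pos); n <- length(neg)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, statistic = z, p_value = p)
}

#' Bootstrap test for a difference in a performance metric
#'
#' Resamples the evaluation set with replacement (stratified by class so
#' ranking metrics stay defined) `n_boot` times, computes the metric for
#' both models on each resample, and derives a two-sided p-value from the
#' position of zero in the bootstrap distribution of the difference, with
#' add-one smoothing: `p = 2 * min(#(d <= 0) + 1, #(d >= 0) + 1) / (n_boot + 1)`,
#' capped at 1. The smallest attainable p with 2000 resamples is about
#' 1/2001.
#'
#' @param y 0/1 labels.
#' @param scores_a,scores_b Score vectors of the two models.
#' @param metric Metric name (`"auc"`, `"auprc"`, `"accuracy"`, `"f1"`,
#'   `"precision"`, `"recall"`) or a function `(y, scores) -> numeric`.
#' @param n_boot Number of resamples (default 2000).
#' @param seed RNG seed.
#' @return List: `p_value`, `observed_diff`, `median_diff` (median of the
#'   bootstrap differences), `n_boot`.
#' @export
bootstrap_median_test <- function(y, scores_a, scores_b, metric = "auc",
                                  n_boot = 2000, seed = 1) {
  y <- as.integer(y)
  stopifnot(n_boot >= 1)
  mfun <- if (is.function(metric)) metric else {
    nm <- match.arg(metric, c("auc", "auprc", "accuracy", "f1",
                              "precision", "recall"))
    switch(nm,
           auc = rank_auc,
           auprc = step_auprc,
           function(yy, ss) compute_metrics(yy, ss)[[nm]])
  }
  pos <- which(y == 1); neg <- which(y == 0)
  set.seed(seed)
  d <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    d[b] <- mfun(y[idx], scores_a[idx]) - mfun(y[idx], scores_b[idx])
  }
  p <- 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (n_boot + 1)
  list(p_value = min(1, p),
       observed_diff = mfun(y, scores_a) - mfun(y, scores_b),
       median_diff = stats::median(d),
       n_boot = n_boot)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (step-up with monotonicity enforcement).
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

# stratified subsample of given total size, preserving class proportions
stratified_subsample <- function(y, size, seed) {
  y <- as.integer(y)
  set.seed(seed)
  n <- length(y)
  stopifnot(size <= n)
  out <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    take <- round(size * length(idx) / n)
    out <- c(out, sample(idx, min(take, length(idx))))
  }
  # rounding can leave us off by one; fix up deterministically
  short <- size - length(out)
  if (short > 0) {
    pool <- setdiff(seq_len(n), out)
    out <- c(out, sample(pool, short))
  } else if (short < 0) {
    out <- out[seq_len(size)]
  }
  sort(out)
}

# equal-variance two-sample t-test on fold scores; zero pooled variance is
# reported as p = 1 when the means agree (self-comparison) and 0 otherwise
equal_var_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0))
  }
  tt <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tt, p_value = 2 * stats::pt(-abs(tt), na + nb - 2))
}

#' Learning curves over logarithmically spaced training sizes
#'
#' For each size, draws a stratified subsample, runs stratified k-fold
#' cross-validation for every model builder, and records per-fold metrics.
#' Builders are functions `(x_train, y_train, x_test) -> scores`. Per size
#' and metric, the fold scores of the first two builders are compared with
#' an equal-variance two-sided t-test of means.
#'
#' @param x Input matrix or `profile_tensor`.
#' @param y 0/1 labels.
#' @param model_builders Named list of builder functions (>= 1; the t-test
#'   needs >= 2).
#' @param sizes Training-set sizes; default 6 log-spaced points from 100 to
#'   `length(y)`.
#' @param k CV folds (default 5).
#' @param seeds One or more seeds; folds are redrawn per seed.
#' @param metrics Metric names to record.
#' @return List of class `learning_curve`: `folds` (tidy per-fold data
#'   frame), `summary` (mean and sd per size/model/metric), `tests`
#'   (t-test per size/metric between the first two models).
#' @export
learning_curve <- function(x, y, model_builders,
                           sizes = NULL, k = 5, seeds = 1,
                           metrics = c("auc", "auprc", "f1", "accuracy")) {
  X <- if (inherits(x, "profile_tensor")) as_input_matrix(x) else as.matrix(x)
  y <- as.integer(y)
  stopifnot(length(model_builders) >= 1, !is.null(names(model_builders)))
  if (is.null(sizes)) {
    sizes <- unique(round(exp(seq(log(min(100, length(y))), log(length(y)),
                                  length.out = 6))))
  }
  sizes <- sort(unique(sizes))
  if (any(sizes < 2 * k)) stop("every size must be at least 2 * k")
  if (max(sizes) > length(y)) stop("size exceeds available samples")

  rows <- list()
  for (size in sizes) {
    for (seed in seeds) {
      sub <- stratified_subsample(y, size, seed = seed)
      folds <- make_cv_folds(y[sub], k = k, seed = seed)
      for (f in seq_along(folds)) {
        tr <- sub[folds[[f]]$train]; te <- sub[folds[[f]]$test]
        for (mn in names(model_builders)) {
          sc <- model_builders[[mn]](X[tr, , drop = FALSE], y[tr],
                                     X[te, , drop = FALSE])
          ms <- compute_metrics(y[te], sc)
          for (metric in metrics) {
            rows[[length(rows) + 1]] <- data.frame(
              model = mn, size = size, seed = seed, fold = f,
              metric = metric, value = ms[[metric]])
          }
        }
      }
    }
  }
  folds_df <- do.call(rbind, rows)
  summary_df <- stats::aggregate(value ~ model + size + metric, folds_df,
                                 function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary_df <- cbind(summary_df[c("model", "size", "metric")],
                      mean = summary_df$value[, "mean"],
                      sd = summary_df$value[, "sd"])
  tests <- NULL
  if (length(model_builders) >= 2) {
    ma <- names(model_builders)[1]; mb <- names(model_builders)[2]
    tl <- list()
    for (size in sizes) {
      for (metric in metrics) {
        a <- folds_df$value[folds_df$model == ma & folds_df$size == size &
                              folds_df$metric == metric]
        b <- folds_df$value[folds_df$model == mb & folds_df$size == size &
                              folds_df$metric == metric]
        tt <- equal_var_t(a, b)
        tl[[length(tl) + 1]] <- data.frame(
          size = size, metric = metric, model_a = ma, model_b = mb,
          mean_a = mean(a), mean_b = mean(b),
          statistic = tt$statistic, p_value = tt$p_value)
      }
    }
    tests <- do.call(rbind, tl)
  }
  structure(list(folds = folds_df, summary = summary_df, tests = tests),
            class = "learning_curve")
}

# ---- model builders -------------------------------------------------------

#' Builder functions for cross-validated comparisons
#'
#' Each returns a function `(x_train, y_train, x_test) -> scores` suitable
#' for [learning_curve()] and [baselines()].
#'
#' @param net A `layered_network` (masked or dense topology).
#' @param config A `pnet_config`.
#' @name builders
NULL

#' @rdname builders
#' @export
builder_pnet <- function(net, config = pnet_config()) {
  force(net); force(config)
  function(x_train, y_train, x_test) {
    m <- pnet_model(net, head_loss_weights = config$head_loss_weights,
                    seed = config$seed)
    m <- train_pnet(m, x_train, y_train, config)
    predict(m, x_test)
  }
}

#' @rdname builders
#' @export
builder_dense_equivalent <- function(net, config = pnet_config()) {
  force(config)
  dense <- build_dense_equivalent(net)
  builder_pnet(dense, config)
}

#' @rdname builders
#' @export
builder_dense_same_nodes <- function(net, config = pnet_config()) {
  force(config)
  dense <- build_dense_network(unname(layer_sizes(net)))
  builder_pnet(dense, config)
}

# degenerate training data (for example all-constant features) falls back
# to the training-set positive rate, i.e. a majority-class predictor
with_majority_fallback <- function(fit_predict) {
  function(x_train, y_train, x_test) {
    tryCatch(fit_predict(x_train, y_train, x_test),
             error = function(e) rep(mean(y_train), nrow(x_test)))
  }
}

builder_logistic <- function(lambda = 0.01) {
  with_majority_fallback(function(x_train, y_train, x_test) {
    fit <- glmnet::glmnet(x_train, factor(y_train), family = "binomial",
                          alpha = 0, lambda = lambda)
    drop(stats::predict(fit, x_test, type = "response"))
  })
}

builder_svm <- function(kernel = "linear") {
  with_majority_fallback(function(x_train, y_train, x_test) {
    fit <- e1071::svm(x_train, factor(y_train), kernel = kernel,
                      probability = TRUE, scale = FALSE)
    pr <- attr(stats::predict(fit, x_test, probability = TRUE), "probabilities")
    pr[, "1"]
  })
}

builder_tree <- function() {
  function(x_train, y_train, x_test) {
    df <- data.frame(y = factor(y_train), x_train, check.names = FALSE)
    fit <- rpart::rpart(y ~ ., data = df, method = "class")
    stats::predict(fit, data.frame(x_test, check.names = FALSE))[, "1"]
  }
}

#' Classical baseline models on flattened profiles
#'
#' Fits L2-regularized logistic regression, linear and RBF support vector
#' machines, a decision tree and - when a network topology is supplied -
#' two dense neural comparators (one with the same parameter count, one
#' with the same layer sizes), then scores the held-out set.
#'
#' @param x_train,y_train Training inputs (matrix or `profile_tensor`) and
#'   0/1 labels.
#' @param x_test,y_test Held-out inputs and labels.
#' @param net Optional `layered_network` for the dense comparators.
#' @param config `pnet_config` for the neural comparators.
#' @return List per model: `metrics` (a `metric_set`) and `scores`.
#' @export
baselines <- function(x_train, y_train, x_test, y_test, net = NULL,
                      config = pnet_config()) {
  Xtr <- if (inherits(x_train, "profile_tensor")) as_input_matrix(x_train) else
    as.matrix(x_train)
  Xte <- if (inherits(x_test, "profile_tensor")) as_input_matrix(x_test) else
    as.matrix(x_test)
  builders <- list(
    logistic = builder_logistic(),
    svm_linear = builder_svm("linear"),
    svm_rbf = builder_svm("radial"),
    decision_tree = builder_tree()
  )
  if (!is.null(net)) {
    builders$dense_same_params <- builder_dense_equivalent(net, config)
    builders$dense_same_nodes <- builder_dense_same_nodes(net, config)
  }
  out <- list()
  for (mn in names(builders)) {
    sc <- builders[[mn]](Xtr, as.integer(y_train), Xte)
    out[[mn]] <- list(scores = sc,
                      metrics = compute_metrics(as.integer(y_test), sc))
  }
  out
}

#' Chi-squared test with Yates continuity correction on a 2x2 table
#'
#' `statistic = sum(max(|O - E| - 0.5, 0)^2 / E)` with 1 degree of freedom
#' (the correction is clamped at zero, so a table with O = E scores 0).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List: `statistic`, `p_value`, `expected`.
#' @export
chi2_yates <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(res$statistic),
       p_value = unname(res$p.value),
       expected = res$expected)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic (1 degree of freedom) comparing
#' the hazard experience of two groups at each observed event time.
#'
#' @param times Follow-up times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @param groups Two-level grouping vector.
#' @return List: `statistic`, `p_value`, `n_events`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("exactly two non-empty groups required")
  }
  if (sum(events) < 1) stop("at least one event is required")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  stat <- unname(fit$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n_events = sum(events))
}
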