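test_that("standardizer centers and scales, and rejects constant columns", {
  x <- cbind(a = c(-1, 1), b = c(3, 7))
  std <- fit_standardizer(x)
  z <- predict(std, x)
  expect_equal(unname(z[, 1]), c(-1, 1))  # population sd of {-1, 1} is 1
  set.seed(9)
  x2 <- matrix(rnorm(200 * 6, mean = 5, sd = 3), ncol = 6)
  std2 <- fit_standardizer(x2)
  z2 <- predict(std2, x2)
  expect_lt(max(abs(colMeans(z2))), 1e-9)
  n <- nrow(x2)
  popsd <- apply(z2, 2, function(v) sqrt(var(v) * (n - 1) / n))
  expect_lt(max(abs(popsd - 1)), 1e-9)
  xc <- cbind(good = rnorm(10), flat = rep(2, 10))
  err <- tryCatch(fit_standardizer(xc), error = identity)
  expect_s3_class(err, "standardization_error")
  expect_match(conditionMessage(err), "flat")
  # sample-sd variant differs by the expected factor
  std_s <- fit_standardizer(x2, sd_type = "sample")
  expect_equal(std_s$sds, std2$sds * sqrt(n / (n - 1)))
})

test_that("class balancing undersamples the majority without replacement", {
  labels <- rep(c("well", "bad"), c(773, 178))
  idx <- balance_binary(labels, seed = 42)
  expect_length(idx, 356)
  expect_equal(as.integer(table(labels[idx])), c(178L, 178L))
  expect_false(any(duplicated(idx)))
  expect_identical(idx, balance_binary(labels, seed = 42))     # deterministic
  expect_false(identical(idx, balance_binary(labels, seed = 43)))
  even <- rep(c("a", "b"), each = 50)
  expect_length(balance_binary(even, seed = 1), 100)           # unchanged size
  expect_error(balance_binary(rep("a", 10), seed = 1), class = "parameter_error")
})

test_that("stratified splits hit the rounded sizes and partition the data", {
  labels <- rep(c("well", "bad"), each = 178)
  sp <- split_dataset(labels, 0.7, seed = 7)
  expect_length(sp$train, 249)
  expect_length(sp$test, 107)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # stratification: each class near its share
  expect_true(all(abs(table(labels[sp$train]) - 124.6) <= 1))
  labels2 <- rep(c("alive", "dead"), c(200, 166))
  sp2 <- split_dataset(labels2, 0.8, seed = 1)
  expect_length(sp2$train, 293)
  expect_length(sp2$test, 73)
  expect_identical(sp2, split_dataset(labels2, 0.8, seed = 1))
  expect_error(split_dataset(labels, 1.2, seed = 1), class = "parameter_error")
  expect_error(split_dataset(c("a", "b"), 0.01, seed = 1),
               class = "parameter_error")
})

test_that("logistic fit separates separable data and recovers planted models", {
  # null model: zero weights give probability one half
  gg <- fixture_gaussian_classes(30, 2, shift = 1, seed = 2)
  fit0 <- fit_logistic(gg$x, gg$labels)
  fit0$weights[] <- 0; fit0$intercept <- 0
  expect_true(all(predict(fit0, gg$x, type = "prob") == 0.5))
  # ties at the threshold go to the positive class
  expect_true(all(predict(fit0, gg$x) == "pos"))
  # linearly separable data: accuracy >= 99% with a separation warning
  sep <- fixture_gaussian_classes(100, 2, shift = 30, seed = 3)
  expect_warning(fit_sep <- fit_logistic(sep$x, sep$labels),
                 "separation|rank-deficient")
  expect_gte(mean(predict(fit_sep, sep$x) == sep$labels), 0.99)
  # planted-coefficient recovery within 3 standard errors
  set.seed(5)
  n <- 3000; p <- 6
  beta <- c(0.4, -0.8, 0.2, 0, 1.1, -0.5)
  x <- matrix(rnorm(n * p), ncol = p)
  y <- factor(ifelse(runif(n) < plogis(0.3 + x %*% beta), "pos", "neg"),
              levels = c("neg", "pos"))
  fit <- fit_logistic(x, y, positive = "pos")
  expect_false(fit$separable)
  expect_true(all(abs(fit$weights - beta) <= 3 * fit$se[-1]))
  expect_error(fit_logistic(x, factor(rep("pos", n))), class = "parameter_error")
})

test_that("pipeline predictions are invariant to affine feature rescaling", {
  gg <- fixture_gaussian_classes(120, 4, shift = 0.8, seed = 11)
  run <- function(x) {
    std <- fit_standardizer(x)
    z <- predict(std, x)
    fit <- fit_logistic(z, gg$labels)
    predict(fit, z)
  }
  x_scaled <- gg$x
  x_scaled[, 2] <- x_scaled[, 2] * 10
  x_scaled[, 4] <- x_scaled[, 4] * 0.01 + 7
  expect_identical(run(gg$x), run(x_scaled))
})

test_that("accuracy and recall match the station validation figures", {
  counts <- stain_validation_counts()
  top <- classification_metrics(with(counts[counts$view == "top", ],
    confusion_matrix(tp = tp, tn = tn, fp = fp, fn = fn)))
  expect_equal(top$accuracy_pct, 87.6)
  expect_equal(top$recall_2dp, 0.77)
  bottom <- classification_metrics(with(counts[counts$view == "bottom", ],
    confusion_matrix(tp = tp, tn = tn, fp = fp, fn = fn)))
  expect_equal(bottom$accuracy_pct, 89.6)
  expect_equal(bottom$recall_2dp, 0.79)
  perfect <- classification_metrics(confusion_matrix(tp = 10, tn = 20, fp = 0, fn = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$recall, 1)
  expect_error(
    classification_metrics(confusion_matrix(tp = 0, tn = 5, fp = 2, fn = 0)),
    class = "metric_error")
  # counting identity: metrics from a matrix equal direct per-sample counting
  set.seed(13)
  truth <- sample(c("pos", "neg"), 60, replace = TRUE)
  pred <- sample(c("pos", "neg"), 60, replace = TRUE)
  cm <- confusion_matrix(truth, pred, positive = "pos")
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, mean(truth == pred))
  expect_equal(m$recall, mean(pred[truth == "pos"] == "pos"))
})

test_that("reported percentages round half away from zero", {
  expect_equal(round_half_up(87.55, 1), 87.6)
  expect_equal(round_half_up(0.775, 2), 0.78)
  expect_equal(round_half_up(249.2), 249)
  expect_equal(round_half_up(292.8), 293)
})

test_that("Monte Carlo cross-validation is reproducible and well-formed", {
  gg <- fixture_gaussian_classes(80, 3, shift = 1, seed = 17)
  rep1 <- monte_carlo_cv(gg$x, gg$labels, 0.7, n_iter = 15, seed = 99)
  expect_length(rep1$train_accuracies, 15)
  expect_length(rep1$test_accuracies, 15)
  expect_equal(rep1$mean_test, mean(rep1$test_accuracies))
  expect_equal(rep1$mean_train, mean(rep1$train_accuracies))
  rep2 <- monte_carlo_cv(gg$x, gg$labels, 0.7, n_iter = 15, seed = 99)
  expect_identical(rep1, rep2)
  # per-iteration rebalancing is supported and differs from balance-once
  rep3 <- monte_carlo_cv(gg$x, gg$labels, 0.7, n_iter = 15, seed = 99,
                         balance = "per_iteration")
  expect_length(rep3$test_accuracies, 15)
})
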