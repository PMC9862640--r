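#' Z-score standardizer
#'
#' Fits per-feature means and standard deviations so features on very
#' different supports become comparable; the transform is (X - m) / s.
#' Population standard deviations (divisor n) are the default; the choice is
#' immaterial downstream of a logistic fit but is exposed for comparability.
#'
#' @param x numeric matrix or data frame (rows = samples).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return object of class `standardizer` with `means`, `sds`, `sd_type`,
#'   `feature_names`.
#' @export
fit_standardizer <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop_cocoon("fit_standardizer: need at least two rows",
                class = "standardization_error")
  m <- colMeans(x)
  v <- apply(x, 2, stats::var)
  if (sd_type == "population") v <- v * (nrow(x) - 1) / nrow(x)
  s <- sqrt(v)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0] %||% which(s == 0)
    stop_cocoon("fit_standardizer: constant column(s): ",
                paste(bad, collapse = ", "), class = "standardization_error")
  }
  structure(list(means = m, sds = s, sd_type = sd_type,
                 feature_names = colnames(x)),
            class = "standardizer")
}

#' @export
print.standardizer <- function(x, ...) {
  cat(sprintf("<standardizer: %d features, %s sd>\n",
              length(x$means), x$sd_type))
  invisible(x)
}

#' @param object a `standardizer`.
#' @param newdata matrix/data frame with the same columns as the fitting set.
#' @param ... unused.
#' @rdname fit_standardizer
#' @export
predict.standardizer <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$means))
    stop_cocoon("standardizer: newdata has ", ncol(newdata),
                " columns, expected ", length(object$means),
                class = "standardization_error")
  scale(newdata, center = object$means, scale = object$sds)[, , drop = FALSE]
}

#' Balance a binary dataset by undersampling the majority class
#'
#' Randomly draws, without replacement, as many majority-class samples as
#' there are minority-class samples, so the returned index set holds the two
#' classes at exactly equal counts (for the machine's shape data: 178
#' bad-shaped joined with 178 of the 773 well-shaped, 356 in all).
#'
#' @param labels factor or vector of two class labels.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return integer vector of retained row indices, sorted.
#' @export
balance_binary <- function(labels, seed = NULL) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) != 2 || any(tab == 0))
    stop_cocoon("balance_binary: need two non-empty classes",
                class = "parameter_error")
  n_min <- min(tab)
  keep <- with_seed(seed, {
    unlist(lapply(levels(labels), function(lv) {
      i <- which(labels == lv)
      if (length(i) > n_min) sort(sample(i, n_min)) else i
    }))
  })
  sort(keep)
}

#' Stratified train/test split
#'
#' Randomly partitions samples into a training and a test set. The training
#' size is the rounded (half-up) fraction of the total; the split is
#' stratified so each class contributes its proportional share, with
#' largest-remainder apportionment making the per-class training counts sum
#' to the target (356 samples at 70% give 249 train / 107 test; 366 at 80%
#' give 293 / 73).
#'
#' @param labels class label per sample (any length-n vector).
#' @param train_fraction fraction in (0, 1) (0.7 for the shape model, 0.8 for
#'   the alive/dead model).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(labels, train_fraction, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_cocoon("split_dataset: train_fraction must be in (0, 1)",
                class = "parameter_error")
  labels <- as.factor(labels)
  n <- length(labels)
  target <- round_half_up(n * train_fraction)
  if (target < 1 || target > n - 1)
    stop_cocoon("split_dataset: fraction yields an empty partition",
                class = "parameter_error")
  tab <- table(labels)
  exact <- as.numeric(tab) * train_fraction
  base <- floor(exact)
  extra <- target - sum(base)
  if (extra > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(exact - base)
    base[ord[seq_len(-extra)]] <- base[ord[seq_len(-extra)]] - 1
  }
  # keep both partitions inhabited per class where the class allows it
  base <- pmin(pmax(base, ifelse(tab >= 2, 1, 0)), as.numeric(tab) - ifelse(tab >= 2, 1, 0))
  train <- with_seed(seed, {
    unlist(lapply(seq_along(levels(labels)), function(k) {
      i <- which(labels == levels(labels)[k])
      sample(i, base[k])
    }))
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

# Ridge-penalized logistic IRLS; intercept unpenalized. Fallback for
# separated data, where the unpenalized likelihood has no finite maximum.
ridge_logistic <- function(x, y01, lambda = 1e-8, max_iter = 100, tol = 1e-10) {
  x1 <- cbind(1, x)
  p <- ncol(x1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- drop(x1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y01 - mu) / w
    xtw <- t(x1 * w)
    beta_new <- solve(xtw %*% x1 + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Fit a binary logistic classifier
#'
#' Maximum-likelihood (unpenalized) logistic regression on standardized
#' features via [stats::glm()]. When the classes are linearly separable the
#' unpenalized likelihood has no finite maximizer; the fit then falls back to
#' a tiny-ridge (lambda = 1e-8) penalized fit with a warning, which leaves
#' predictions essentially unchanged while keeping the weights finite.
#'
#' Prediction thresholds the class-probability at `decision_threshold`
#' (default 0.5); a probability exactly at the threshold goes to the positive
#' class.
#'
#' @param x numeric feature matrix (rows = samples), normally Z-scores.
#' @param labels two-class factor (or coercible); `positive` names the
#'   positive class, by default the second factor level.
#' @param positive positive class label.
#' @param decision_threshold probability cut in (0, 1).
#' @param lambda_fallback ridge penalty used only on separation.
#' @return object of class `cocoon_logit` with elements `weights`,
#'   `intercept`, `decision_threshold`, `feature_schema`, `levels`,
#'   `positive`, `se` (standard errors; `NA` under the ridge fallback) and
#'   `separable`.
#' @export
fit_logistic <- function(x, labels, positive = NULL, decision_threshold = 0.5,
                         lambda_fallback = 1e-8) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2 || any(table(labels) == 0))
    stop_cocoon("fit_logistic: need two classes present in training data",
                class = "parameter_error")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop_cocoon("fit_logistic: decision_threshold must be in (0, 1)",
                class = "parameter_error")
  positive <- positive %||% levels(labels)[2]
  if (!positive %in% levels(labels))
    stop_cocoon("fit_logistic: positive class not among labels",
                class = "parameter_error")
  y01 <- as.integer(labels == positive)
  separable <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind("(Intercept)" = 1, x), y01,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separable <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  rank_deficient <- fit$rank < ncol(x) + 1
  if (separable || !fit$converged || rank_deficient) {
    warning("fit_logistic: ",
            if (rank_deficient) "rank-deficient design" else "separation detected",
            "; refitting with ridge penalty ", format(lambda_fallback),
            call. = FALSE)
    separable <- TRUE
    beta <- ridge_logistic(x, y01, lambda = lambda_fallback)
    se <- rep(NA_real_, length(beta))
  } else {
    beta <- stats::coef(fit)
    # observed-information standard errors
    qrr <- fit$qr
    cov <- tryCatch(chol2inv(qrr$qr[seq_len(qrr$rank), seq_len(qrr$rank), drop = FALSE]),
                    error = function(e) NULL)
    se <- rep(NA_real_, length(beta))
    if (!is.null(cov)) se[qrr$pivot[seq_len(qrr$rank)]] <- sqrt(diag(cov))
  }
  structure(list(weights = stats::setNames(beta[-1], colnames(x)),
                 intercept = unname(beta[1]),
                 decision_threshold = decision_threshold,
                 feature_schema = colnames(x),
                 levels = levels(labels),
                 positive = positive,
                 se = stats::setNames(se, c("(Intercept)", colnames(x))),
                 separable = separable),
            class = "cocoon_logit")
}

#' @export
print.cocoon_logit <- function(x, ...) {
  cat(sprintf("<cocoon_logit: %d features, positive class '%s', threshold %.2f%s>\n",
              length(x$weights), x$positive, x$decision_threshold,
              if (x$separable) ", ridge fallback" else ""))
  invisible(x)
}

#' @export
coef.cocoon_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
summary.cocoon_logit <- function(object, ...) {
  tab <- data.frame(estimate = coef(object), std_error = object$se)
  cat("Binary logistic classifier (positive class:", object$positive, ")\n")
  if (object$separable) cat("Note: separation detected, tiny-ridge fit.\n")
  print(tab)
  invisible(tab)
}

#' @param object a `cocoon_logit`.
#' @param newdata feature matrix matching the training schema.
#' @param type `"class"`, `"prob"`, or `"both"`.
#' @param ... unused.
#' @rdname fit_logistic
#' @export
predict.cocoon_logit <- function(object, newdata, type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights))
    stop_cocoon("predict.cocoon_logit: feature count mismatch",
                class = "parameter_error")
  p <- stats::plogis(object$intercept + drop(newdata %*% object$weights))
  neg <- setdiff(object$levels, object$positive)
  cls <- factor(ifelse(p >= object$decision_threshold, object$positive, neg),
                levels = object$levels)
  switch(type, prob = p, class = cls,
         both = data.frame(class = cls, prob = p))
}

#' Confusion matrix
#'
#' Builds the 2 x 2 confusion counts, either from parallel truth/prediction
#' vectors and a declared positive class, or directly from the four counts.
#'
#' @param truth,predicted class vectors (ignored when counts are given).
#' @param positive positive class label.
#' @param tp,tn,fp,fn direct counts.
#' @return object of class `confusion_matrix` with `tp`, `tn`, `fp`, `fn`,
#'   `positive`.
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL, positive = NULL,
                             tp = NULL, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tp)) {
    stopifnot(length(truth) == length(predicted), length(truth) > 0)
    positive <- positive %||% sort(unique(as.character(truth)))[2]
    t_pos <- as.character(truth) == positive
    p_pos <- as.character(predicted) == positive
    tp <- sum(t_pos & p_pos);  fn <- sum(t_pos & !p_pos)
    fp <- sum(!t_pos & p_pos); tn <- sum(!t_pos & !p_pos)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || sum(counts) == 0)
    stop_cocoon("confusion_matrix: counts must be non-negative with total > 0",
                class = "parameter_error")
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Overall accuracy and recall
#'
#' The two station metrics: overall accuracy A = (Tp + Tn) / (Tp + Tn + Fp +
#' Fn) and recall R = Tp / (Tp + Fn). For reporting, accuracy is formatted as
#' a percentage with one decimal (half-up) and recall with two decimals.
#'
#' @param cm a [confusion_matrix].
#' @return list with `accuracy`, `recall` (proportions), `accuracy_pct`
#'   (percent, one decimal), `recall_2dp`, and the counts.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (cm$tp + cm$fn == 0)
    stop_cocoon("classification_metrics: recall undefined (Tp + Fn = 0)",
                class = "metric_error")
  acc <- (cm$tp + cm$tn) / total
  rec <- cm$tp / (cm$tp + cm$fn)
  list(accuracy = acc, recall = rec,
       accuracy_pct = round_half_up(100 * acc, 1),
       recall_2dp = round_half_up(rec, 2),
       tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
}

#' Monte Carlo cross-validation of the standardize-and-fit pipeline
#'
#' Repeats `n_iter` independent evaluation rounds, each with its own derived
#' seed: (optionally) balance the classes, split stratified at
#' `train_fraction`, fit the Z-score standardizer and the logistic model on
#' the training part only, and record train and test accuracy. `balance =
#' "once"` balances a single time with the master seed and re-splits each
#' round (the protocol used to validate the machine's shape model);
#' `"per_iteration"` redraws the majority-class subsample every round;
#' `"none"` skips balancing.
#'
#' @param x feature matrix (raw, not yet standardized).
#' @param labels two-class labels.
#' @param train_fraction training fraction per round.
#' @param n_iter number of rounds (default 100).
#' @param seed master seed; per-round seeds are derived from it.
#' @param balance `"once"`, `"per_iteration"` or `"none"`.
#' @param positive positive class passed to [fit_logistic()].
#' @return object of class `cv_report`: `n_iterations`, `train_accuracies`,
#'   `test_accuracies`, `mean_train`, `mean_test`.
#' @export
monte_carlo_cv <- function(x, labels, train_fraction, n_iter = 100,
                           seed = NULL, balance = c("once", "per_iteration", "none"),
                           positive = NULL) {
  balance <- match.arg(balance)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (balance == "once") {
    keep <- balance_binary(labels, seed = seed)
    x <- x[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  train_acc <- test_acc <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    s <- derive_seed(seed %||% 0, i)
    xi <- x; li <- labels
    if (balance == "per_iteration") {
      keep <- balance_binary(li, seed = s)
      xi <- xi[keep, , drop = FALSE]
      li <- droplevels(li[keep])
    }
    sp <- split_dataset(li, train_fraction, seed = derive_seed(s, 1))
    std <- fit_standardizer(xi[sp$train, , drop = FALSE])
    ztr <- predict(std, xi[sp$train, , drop = FALSE])
    zte <- predict(std, xi[sp$test, , drop = FALSE])
    fit <- suppressWarnings(fit_logistic(ztr, li[sp$train], positive = positive))
    train_acc[i] <- mean(predict(fit, ztr) == li[sp$train])
    test_acc[i] <- mean(predict(fit, zte) == li[sp$test])
  }
  structure(list(n_iterations = n_iter,
                 train_accuracies = train_acc,
                 test_accuracies = test_acc,
                 mean_train = mean(train_acc),
                 mean_test = mean(test_acc)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d iterations, mean accuracy train %.1f%% / test %.1f%%>\n",
              x$n_iterations, 100 * x$mean_train, 100 * x$mean_test))
  invisible(x)
}
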