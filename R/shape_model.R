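#' Fit the cocoon shape classifier
#'
#' The full shape-station training pipeline: generalized Procrustes
#' alignment of the digitized outlines, elliptic Fourier decomposition up to
#' the Nyquist limit, truncation at the harmonic where the average cumulative
#' power reaches 99.999% of the average total power, class balancing by
#' undersampling the majority class, a stratified 70/30 split, Z-score
#' standardization of the 4k retained coefficients (fitted on the training
#' part), and a logistic fit. The truncation order, mean shape and
#' standardizer are frozen into the model so new outlines can be classified
#' consistently.
#'
#' @param outlines list of [outline] objects (equal point counts).
#' @param labels two-class labels, one per outline; `positive` names the
#'   defective class (default `"bad"` when present, else the second level).
#' @param seed seed driving balancing and splitting.
#' @param train_fraction default 0.7.
#' @param power_fraction truncation rule (default 0.99999).
#' @param balance undersample to class parity before splitting (default TRUE).
#' @param positive positive class label.
#' @return object of class `cocoon_shape_model`: `mean_shape`, `k`
#'   (truncation order), `n_harmonics` (Nyquist), `standardizer`, `logit`,
#'   `balance_idx`, `split`, `train_accuracy`, `test_accuracy`, `train_cm`,
#'   `test_cm`.
#' @export
fit_shape_model <- function(outlines, labels, seed = NULL,
                            train_fraction = 0.7, power_fraction = 0.99999,
                            balance = TRUE, positive = NULL) {
  labels <- as.factor(labels)
  stopifnot(length(outlines) == length(labels))
  positive <- positive %||% (if ("bad" %in% levels(labels)) "bad"
                             else levels(labels)[2])
  aligned <- procrustes_align(outlines)
  nyq <- floor(nrow(aligned$mean_shape) / 2)
  descs <- lapply(aligned$outlines, efa_decompose, n = nyq)
  k <- truncation_order(descs, fraction = power_fraction)
  feats <- t(vapply(descs, function(d) coef(d, k = k), numeric(4 * k)))
  keep <- if (balance) balance_binary(labels, seed = seed) else seq_along(labels)
  xb <- feats[keep, , drop = FALSE]
  lb <- droplevels(labels[keep])
  sp <- split_dataset(lb, train_fraction, seed = derive_seed(seed %||% 0, 1))
  # coefficients constant across the set (e.g. sine terms pinned by the
  # digitizer's fixed starting ray) carry no shape information: drop them
  sds <- apply(xb[sp$train, , drop = FALSE], 2, stats::sd)
  keep_col <- sds > 1e-12
  std <- fit_standardizer(xb[sp$train, keep_col, drop = FALSE])
  ztr <- predict(std, xb[sp$train, keep_col, drop = FALSE])
  zte <- predict(std, xb[sp$test, keep_col, drop = FALSE])
  fit <- suppressWarnings(fit_logistic(ztr, lb[sp$train], positive = positive))
  ptr <- predict(fit, ztr); pte <- predict(fit, zte)
  structure(list(mean_shape = aligned$mean_shape, k = k, n_harmonics = nyq,
                 feature_columns = which(keep_col),
                 standardizer = std, logit = fit,
                 balance_idx = keep, split = sp, positive = positive,
                 train_accuracy = mean(ptr == lb[sp$train]),
                 test_accuracy = mean(pte == lb[sp$test]),
                 train_cm = confusion_matrix(lb[sp$train], ptr, positive = positive),
                 test_cm = confusion_matrix(lb[sp$test], pte, positive = positive)),
            class = "cocoon_shape_model")
}

#' @export
print.cocoon_shape_model <- function(x, ...) {
  cat(sprintf("<cocoon_shape_model: k = %d harmonics (%d features), positive '%s',\n  accuracy train %.1f%% / test %.1f%%>\n",
              x$k, length(x$feature_columns), x$positive,
              100 * x$train_accuracy, 100 * x$test_accuracy))
  invisible(x)
}

# Outline (or mask) -> retained, standardized shape features of a fitted model.
shape_features <- function(model, o) {
  if (inherits(o, "binary_mask")) o <- digitize_outline(o, nrow(model$mean_shape))
  al <- align_to_reference(o, model$mean_shape)
  d <- efa_decompose(al, model$n_harmonics)
  v <- coef(d, k = model$k)[model$feature_columns]
  predict(model$standardizer, matrix(v, nrow = 1))
}

#' @param object a `cocoon_shape_model`.
#' @param newdata an [outline], a [binary_mask], or a list of either.
#' @param ... passed on (`type = "prob"` for probabilities).
#' @rdname fit_shape_model
#' @export
predict.cocoon_shape_model <- function(object, newdata, ...) {
  items <- if (inherits(newdata, c("outline", "binary_mask"))) list(newdata)
           else newdata
  z <- do.call(rbind, lapply(items, function(o) shape_features(object, o)))
  predict(object$logit, z, ...)
}

#' Persist fitted station models as versioned JSON
#'
#' Serializes the shape and/or alive-dead models (Z-score parameters,
#' logistic weights, decision threshold, truncation order, mean shape) to a
#' self-describing JSON file, and restores them.
#'
#' @param models named list with any of `shape` (a `cocoon_shape_model`) and
#'   `vital` (a `pupa_model`).
#' @param path JSON path.
#' @return `write_models_json` returns `path` invisibly; `read_models_json`
#'   the restored named list.
#' @export
write_models_json <- function(models, path) {
  ser_logit <- function(l) list(weights = as.list(l$weights),
                                intercept = l$intercept,
                                decision_threshold = l$decision_threshold,
                                levels = l$levels, positive = l$positive)
  ser_std <- function(s) list(means = as.list(s$means), sds = as.list(s$sds),
                              sd_type = s$sd_type)
  out <- list(format = "cocoonsort-models", version = 1L)
  if (!is.null(models$shape)) {
    m <- models$shape
    out$shape <- list(k = m$k, n_harmonics = m$n_harmonics,
                      feature_columns = m$feature_columns,
                      mean_shape = unname(as.matrix(m$mean_shape)),
                      positive = m$positive,
                      standardizer = ser_std(m$standardizer),
                      logit = ser_logit(m$logit))
  }
  if (!is.null(models$vital)) {
    m <- models$vital
    out$vital <- list(positive = m$positive,
                      standardizer = ser_std(m$standardizer),
                      logit = ser_logit(m$logit))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "cocoonsort-models"))
    stop_cocoon("read_models_json: not a cocoonsort model file",
                class = "format_error")
  de_std <- function(s) structure(list(means = unlist(s$means),
                                       sds = unlist(s$sds),
                                       sd_type = s$sd_type,
                                       feature_names = names(s$means)),
                                  class = "standardizer")
  de_logit <- function(l) structure(list(weights = unlist(l$weights),
                                         intercept = l$intercept,
                                         decision_threshold = l$decision_threshold,
                                         feature_schema = names(l$weights),
                                         levels = l$levels, positive = l$positive,
                                         se = NULL, separable = FALSE),
                                    class = "cocoon_logit")
  out <- list()
  if (!is.null(j$shape)) {
    s <- j$shape
    out$shape <- structure(list(mean_shape = as.matrix(s$mean_shape),
                                k = s$k, n_harmonics = s$n_harmonics,
                                feature_columns = as.integer(s$feature_columns),
                                standardizer = de_std(s$standardizer),
                                logit = de_logit(s$logit),
                                positive = s$positive),
                           class = "cocoon_shape_model")
  }
  if (!is.null(j$vital)) {
    v <- j$vital
    out$vital <- structure(list(standardizer = de_std(v$standardizer),
                                logit = de_logit(v$logit),
                                positive = v$positive),
                           class = "pupa_model")
  }
  out
}
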