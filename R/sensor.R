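#' Photodiode sensor frames
#'
#' The alive/dead station reads the light transmitted through a cocoon with a
#' 7 x 5 photodiode matrix sampled by a 10-bit ADC, so one acquisition is 35
#' integer counts in 0..1023. A `sensor_frame` carries the 7 x 5 count
#' matrix, the acquisition timestamp and the progressive cocoon id that
#' traces the cocoon across stations. The feature layout is fixed row-major
#' (the acquisition order: row selected first, then column), so matrix entry
#' (r, c) (0-based) sits at vector index r * 5 + c (0-based).
#'
#' @param values 7 x 5 integer matrix (or length-35 row-major vector) of ADC
#'   counts in 0..1023.
#' @param timestamp acquisition time (any scalar; stored as character).
#' @param cocoon_id progressive integer id.
#' @return object of class `sensor_frame`.
#' @export
sensor_frame <- function(values, timestamp = "", cocoon_id = NA_integer_) {
  if (is.null(dim(values))) {
    if (length(values) != 35)
      stop_cocoon("sensor_frame: need 35 values", class = "format_error")
    values <- matrix(as.integer(values), nrow = 7, ncol = 5, byrow = TRUE)
  }
  if (!all(dim(values) == c(7, 5)))
    stop_cocoon("sensor_frame: values must be a 7 x 5 matrix",
                class = "format_error")
  if (any(is.na(values)) || any(values < 0) || any(values > 1023))
    stop_cocoon("sensor_frame: ADC counts must lie in [0, 1023]",
                class = "range_error")
  storage.mode(values) <- "integer"
  structure(list(values = values, timestamp = as.character(timestamp),
                 cocoon_id = as.integer(cocoon_id)),
            class = "sensor_frame")
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame id %s @ %s, counts %d-%d>\n",
              x$cocoon_id, x$timestamp, min(x$values), max(x$values)))
  invisible(x)
}

#' Flatten a sensor frame to its 35-element feature vector
#'
#' Fixed positional "alignment" of the 35 channels: row-major, matching the
#' acquisition order (row first, then column).
#'
#' @param frame a [sensor_frame].
#' @return named numeric vector of length 35 (`p00` .. `p64`).
#' @export
frame_to_features <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  v <- as.numeric(t(frame$values))
  names(v) <- sensor_channel_names()
  v
}

sensor_channel_names <- function() {
  paste0("p", rep(0:6, each = 5), rep(0:4, times = 7))
}

#' Read and write photodiode CSV files
#'
#' The sensor log dialect: comma-separated with header
#' `timestamp,id,p00,...,p64`, one row per cocoon, 35 counts row-major.
#' Reading validates the column count and the 10-bit ADC range (naming the
#' offending row) and returns frames ordered by progressive id; writing
#' round-trips bit-exactly.
#'
#' @param path CSV path.
#' @param frames list of [sensor_frame] objects.
#' @return `read_sensor_csv` returns a list of [sensor_frame]s;
#'   `write_sensor_csv` returns `path` invisibly.
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  expected <- c("timestamp", "id", sensor_channel_names())
  if (!identical(names(df), expected))
    stop_cocoon("read_sensor_csv: expected columns timestamp,id,p00..p64 (",
                length(expected), " columns), got ", ncol(df),
                class = "format_error")
  frames <- lapply(seq_len(nrow(df)), function(i) {
    counts <- suppressWarnings(as.numeric(df[i, -(1:2)]))
    if (any(is.na(counts)))
      stop_cocoon("read_sensor_csv: non-numeric count in row ", i,
                  class = "format_error")
    if (any(counts < 0 | counts > 1023))
      stop_cocoon("read_sensor_csv: ADC count outside [0, 1023] in row ", i,
                  " (id ", df$id[i], ")", class = "range_error")
    sensor_frame(counts, timestamp = df$timestamp[i],
                 cocoon_id = as.integer(df$id[i]))
  })
  frames[order(vapply(frames, function(f) f$cocoon_id, integer(1)))]
}

#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(frames, path) {
  rows <- vapply(frames, function(f) {
    paste(c(f$timestamp, f$cocoon_id, as.vector(t(f$values))), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("timestamp", "id", sensor_channel_names()),
                     collapse = ","), rows), path)
  invisible(path)
}

#' Fit the alive/dead pupa classifier
#'
#' Z-score standardization of the 35 photodiode channels followed by
#' logistic regression, with a stratified 80/20 train/test split. Dead is
#' the positive class: the station exists to discard dead cocoons. Monte
#' Carlo cross-validation of the same pipeline is available via
#' [monte_carlo_cv()] on the feature matrix.
#'
#' @param frames list of [sensor_frame]s.
#' @param labels vector with levels `"alive"`/`"dead"` (or any two labels
#'   with `positive` naming the dead class).
#' @param seed split seed.
#' @param train_fraction default 0.8.
#' @param positive positive class (default `"dead"` when present).
#' @return object of class `pupa_model`: `standardizer`, `logit`, `split`,
#'   `train_accuracy`, `test_accuracy`, `train_cm`, `test_cm`.
#' @export
fit_pupa_model <- function(frames, labels, seed = NULL, train_fraction = 0.8,
                           positive = NULL) {
  x <- t(vapply(frames, frame_to_features, numeric(35)))
  labels <- as.factor(labels)
  positive <- positive %||% (if ("dead" %in% levels(labels)) "dead"
                             else levels(labels)[2])
  sp <- split_dataset(labels, train_fraction, seed = seed)
  std <- fit_standardizer(x[sp$train, , drop = FALSE])
  ztr <- predict(std, x[sp$train, , drop = FALSE])
  zte <- predict(std, x[sp$test, , drop = FALSE])
  fit <- fit_logistic(ztr, labels[sp$train], positive = positive)
  ptr <- predict(fit, ztr); pte <- predict(fit, zte)
  structure(list(standardizer = std, logit = fit, split = sp,
                 positive = positive,
                 train_accuracy = mean(ptr == labels[sp$train]),
                 test_accuracy = mean(pte == labels[sp$test]),
                 train_cm = confusion_matrix(labels[sp$train], ptr, positive = positive),
                 test_cm = confusion_matrix(labels[sp$test], pte, positive = positive)),
            class = "pupa_model")
}

#' @export
print.pupa_model <- function(x, ...) {
  cat(sprintf("<pupa_model: positive '%s', accuracy train %.1f%% / test %.1f%%>\n",
              x$positive, 100 * x$train_accuracy, 100 * x$test_accuracy))
  invisible(x)
}

#' @param object a `pupa_model`.
#' @param newdata list of [sensor_frame]s or a numeric matrix of 35 columns.
#' @param ... passed to the logistic predictor (`type` etc.).
#' @rdname fit_pupa_model
#' @export
predict.pupa_model <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && inherits(newdata[[1]], "sensor_frame"))
    t(vapply(newdata, frame_to_features, numeric(35)))
  else as.matrix(newdata)
  predict(object$logit, predict(object$standardizer, x), ...)
}
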