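#' Pipeline configuration
#'
#' Nested configuration for the sorting cascade. `default_config()` gives
#' the machine's reference operating point (full-resolution camera geometry:
#' size band 81,900-124,500 px^2 at 273 px^2/mm^2, the two stain camera
#' profiles with the 144 px^2 object rule, epsilon of the edge map, and all
#' four stations enabled). `load_config()` reads a YAML file and merges it
#' over the defaults, so files only need to state what differs.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    imaging = list(eps = 1e-6, polarity = "auto"),
    size = list(min_px2 = 81900, max_px2 = 124500, px2_per_mm2 = 273),
    stain = list(
      top = list(h_range = c(0, 80), s_range = c(60, 255), b_range = c(0, 255)),
      bottom = list(h_range = c(0, 255), s_range = c(220, 255), b_range = c(0, 255)),
      min_area_px2 = 144,
      roi = TRUE
    ),
    shape = list(train_fraction = 0.7, power_fraction = 0.99999, n_points = 180),
    vital = list(train_fraction = 0.8),
    select = list(stations = c("size", "shape", "stain", "vital"))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @param path YAML file.
#' @rdname default_config
#' @export
load_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

config_profiles <- function(config) {
  list(
    top = stain_profile("top", h_range = config$stain$top$h_range,
                        s_range = config$stain$top$s_range,
                        b_range = config$stain$top$b_range,
                        min_object_area_px2 = config$stain$min_area_px2),
    bottom = stain_profile("bottom", h_range = config$stain$bottom$h_range,
                           s_range = config$stain$bottom$s_range,
                           b_range = config$stain$bottom$b_range,
                           min_object_area_px2 = config$stain$min_area_px2)
  )
}

config_thresholds <- function(config) {
  size_thresholds(config$size$min_px2, config$size$max_px2,
                  config$size$px2_per_mm2)
}

# Parse "<timestamp>_<camera>_<id>.bmp" names; returns data frame.
scan_camera_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(bmp|png)$")
  if (!length(files))
    return(data.frame(id = integer(0), file = character(0),
                      timestamp = character(0)))
  parts <- regmatches(files, regexec("^([0-9]+)_(.+)_([0-9]+)\\.(bmp|png)$", files))
  ok <- lengths(parts) == 5
  data.frame(id = as.integer(vapply(parts[ok], `[`, "", 4)),
             file = files[ok],
             timestamp = vapply(parts[ok], `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Acquisition mode: store a dataset in the canonical layout
#'
#' Mirrors the machine's first operating mode: images are stored in one
#' folder per camera in BMP format and the photodiode frames in a CSV in
#' their own folder, every filename carrying the acquisition timestamp, the
#' camera name and the progressive number. The input directory must already
#' contain the three camera folders and a sensor CSV (as produced by
#' [make_benchmark_set()] or a physical acquisition); files are validated,
#' copied, and the CSV is re-read and re-written (a bit-exact round trip).
#'
#' @param input_dir source directory.
#' @param output_dir destination directory (created).
#' @return invisibly, a summary list with per-camera counts and frame count.
#' @export
run_acquire <- function(input_dir, output_dir) {
  cams <- camera_names()
  counts <- integer(0)
  for (cam in cams) {
    src <- file.path(input_dir, cam)
    if (!dir.exists(src))
      stop_cocoon("run_acquire: missing camera folder ", src, class = "io_error")
    dst <- file.path(output_dir, cam)
    dir.create(dst, recursive = TRUE, showWarnings = FALSE)
    tab <- scan_camera_dir(src)
    for (f in tab$file) file.copy(file.path(src, f), file.path(dst, f),
                                  overwrite = TRUE)
    counts[cam] <- nrow(tab)
  }
  src_csv <- file.path(input_dir, "sensor", "frames.csv")
  if (!file.exists(src_csv))
    stop_cocoon("run_acquire: missing sensor CSV ", src_csv, class = "io_error")
  frames <- read_sensor_csv(src_csv)
  dir.create(file.path(output_dir, "sensor"), showWarnings = FALSE)
  write_sensor_csv(frames, file.path(output_dir, "sensor", "frames.csv"))
  for (extra in c("manifest.csv", "config.yaml")) {
    p <- file.path(input_dir, extra)
    if (file.exists(p)) file.copy(p, file.path(output_dir, extra),
                                  overwrite = TRUE)
  }
  invisible(list(images = counts, frames = length(frames)))
}

#' Train the shape and alive/dead station models on a labeled dataset
#'
#' Uses the dataset's ground-truth manifest: segments and digitizes every
#' shape-camera image to fit the shape classifier (balance, 70/30 split,
#' Z-scores of the truncated EFA coefficients, logistic regression), and
#' fits the alive/dead model on the photodiode CSV (80/20 split). Either
#' station can be trained alone.
#'
#' @param dataset_dir dataset in the canonical layout with `manifest.csv`.
#' @param station `"shape"`, `"vital"`, or both (default).
#' @param config pipeline configuration; defaults to the dataset's
#'   `config.yaml` merged over [default_config()].
#' @param seed seed for balancing/splitting.
#' @return named list of fitted models (classes `cocoon_shape_model`,
#'   `pupa_model`).
#' @export
train_stations <- function(dataset_dir, station = c("shape", "vital"),
                           config = NULL, seed = 1) {
  station <- match.arg(station, several.ok = TRUE)
  config <- config %||% dataset_config(dataset_dir)
  manifest <- utils::read.csv(file.path(dataset_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  models <- list()
  if ("shape" %in% station) {
    outlines <- lapply(seq_len(nrow(manifest)), function(i) {
      img <- read_image(file.path(dataset_dir, manifest$shape_file[i]))
      digitize_outline(segment_cocoon(img, eps = config$imaging$eps,
                                      polarity = config$imaging$polarity),
                       n_points = config$shape$n_points)
    })
    models$shape <- fit_shape_model(
      outlines, factor(manifest$true_shape_class, levels = c("well", "bad")),
      seed = seed, train_fraction = config$shape$train_fraction,
      power_fraction = config$shape$power_fraction, positive = "bad")
  }
  if ("vital" %in% station) {
    frames <- read_sensor_csv(file.path(dataset_dir, "sensor", "frames.csv"))
    ids <- vapply(frames, function(f) f$cocoon_id, integer(1))
    lab <- manifest$true_vital_state[match(ids, manifest$id)]
    models$vital <- fit_pupa_model(frames,
                                   factor(lab, levels = c("alive", "dead")),
                                   seed = seed,
                                   train_fraction = config$vital$train_fraction,
                                   positive = "dead")
  }
  models
}

dataset_config <- function(dataset_dir) {
  p <- file.path(dataset_dir, "config.yaml")
  if (file.exists(p)) load_config(p) else default_config()
}

#' Selection mode: run the sorting cascade over a stored dataset
#'
#' Mirrors the machine's second operating mode. For every progressive id
#' found on the shape camera, all enabled stations are evaluated (so the
#' report covers every station even for rejected cocoons): (1) size gate on
#' the segmented silhouette area, (2) the logistic shape model, (3) HSB
#' stain detection on the top and bottom views (OR-combined), (4) the
#' alive/dead photodiode model. The final route is decided by the first
#' failing station in the physical order size, shape, stain, vital:
#' `discard:size`, `discard:shape`, `class:stained`, `class:dead`, and
#' `grade:first` when every station passes. Records missing any enabled
#' station's input are flagged `incomplete` and excluded from metrics.
#'
#' The run is fully deterministic: the same dataset, configuration and
#' models reproduce a byte-identical decisions file.
#'
#' @param dataset_dir dataset directory in the canonical layout.
#' @param models named list with `shape` and/or `vital` fitted models (see
#'   [train_stations()], [read_models_json()]).
#' @param config configuration; defaults to the dataset's `config.yaml`.
#' @param out_path optional path for the decisions CSV.
#' @return decisions data frame (one row per cocoon id).
#' @export
run_select <- function(dataset_dir, models = list(), config = NULL,
                       out_path = NULL) {
  config <- config %||% dataset_config(dataset_dir)
  stations <- config$select$stations
  cams <- camera_names()
  profs <- config_profiles(config)
  thr <- config_thresholds(config)
  shape_tab <- scan_camera_dir(file.path(dataset_dir, cams["shape"]))
  top_tab <- scan_camera_dir(file.path(dataset_dir, cams["top"]))
  bot_tab <- scan_camera_dir(file.path(dataset_dir, cams["bottom"]))
  frames <- tryCatch(read_sensor_csv(file.path(dataset_dir, "sensor", "frames.csv")),
                     error = function(e) list())
  frame_ids <- vapply(frames, function(f) f$cocoon_id, integer(1))
  if (nrow(shape_tab) == 0)
    stop_cocoon("run_select: no shape-camera images found", class = "io_error")

  rows <- lapply(sort(shape_tab$id), function(id) {
    rec <- list(id = id, incomplete = FALSE,
                area_px2 = NA_integer_, size_verdict = NA_character_,
                shape_verdict = NA_character_, shape_prob = NA_real_,
                stain_top = NA, stain_bottom = NA, stained = NA,
                vital_verdict = NA_character_, vital_prob = NA_real_)
    seg <- NULL
    if (any(c("size", "shape") %in% stations)) {
      f <- shape_tab$file[shape_tab$id == id][1]
      seg <- tryCatch(
        segment_cocoon(read_image(file.path(dataset_dir, cams["shape"], f)),
                       eps = config$imaging$eps,
                       polarity = config$imaging$polarity),
        cocoonsort_error = function(e) NULL)
      if (is.null(seg)) rec$incomplete <- TRUE
    }
    if ("size" %in% stations && !is.null(seg)) {
      g <- measure_and_gate_size(seg, thr)
      rec$area_px2 <- g$area_px2
      rec$size_verdict <- g$verdict
    }
    if ("shape" %in% stations && !is.null(seg)) {
      if (is.null(models$shape)) rec$incomplete <- TRUE
      else {
        p <- predict(models$shape, seg, type = "prob")
        rec$shape_prob <- p
        rec$shape_verdict <- if (p >= models$shape$logit$decision_threshold)
          models$shape$positive else setdiff(models$shape$logit$levels,
                                             models$shape$positive)
      }
    }
    if ("stain" %in% stations) {
      for (v in c("top", "bottom")) {
        tab <- if (v == "top") top_tab else bot_tab
        f <- tab$file[tab$id == id]
        if (!length(f)) { rec$incomplete <- TRUE; next }
        img <- read_image(file.path(dataset_dir, cams[[v]], f[1]))
        roi <- if (isTRUE(config$stain$roi)) NULL else binary_mask(
          matrix(TRUE, nrow(img), ncol(img)))
        verd <- check_stains(img, profs[[v]], roi = roi, cocoon_id = id)
        rec[[paste0("stain_", v)]] <- verd$stained
      }
      rec$stained <- isTRUE(rec$stain_top) || isTRUE(rec$stain_bottom)
    }
    if ("vital" %in% stations) {
      k <- match(id, frame_ids)
      if (is.na(k) || is.null(models$vital)) rec$incomplete <- TRUE
      else {
        p <- predict(models$vital, list(frames[[k]]), type = "prob")
        rec$vital_prob <- p
        rec$vital_verdict <- if (p >= models$vital$logit$decision_threshold)
          models$vital$positive else setdiff(models$vital$logit$levels,
                                             models$vital$positive)
      }
    }
    rec$route <- route_decision(rec, stations)
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, rows)
  if (!is.null(out_path)) write_decisions_csv(decisions, out_path)
  decisions
}

# First failing station in physical order decides the route.
route_decision <- function(rec, stations) {
  if (isTRUE(rec$incomplete)) return("incomplete")
  if ("size" %in% stations && !is.na(rec$size_verdict) &&
      rec$size_verdict != "ok") return("discard:size")
  if ("shape" %in% stations && !is.na(rec$shape_verdict) &&
      rec$shape_verdict == "bad") return("discard:shape")
  if ("stain" %in% stations && isTRUE(rec$stained)) return("class:stained")
  if ("vital" %in% stations && !is.na(rec$vital_verdict) &&
      rec$vital_verdict == "dead") return("class:dead")
  "grade:first"
}

write_decisions_csv <- function(decisions, path) {
  d <- decisions
  for (col in c("shape_prob", "vital_prob"))
    d[[col]] <- ifelse(is.na(d[[col]]), "", sprintf("%.6f", d[[col]]))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate sorting decisions against ground truth
#'
#' Joins the decisions to the manifest on the progressive id and reports,
#' per station, the confusion matrix, the overall accuracy (as a percentage
#' with one decimal) and the recall (two decimals). Positive cases are the
#' defects: undersized-or-oversized, bad-shaped, stained, and dead cocoons.
#' Incomplete records are excluded (with a message); ids present in the
#' decisions but absent from the manifest (or vice versa when `strict`) are
#' a join error.
#'
#' @param decisions data frame from [run_select()].
#' @param manifest ground-truth manifest data frame (or its CSV path).
#' @param strict error when manifest ids are missing from the decisions too.
#' @return named list of per-station metric lists (as
#'   [classification_metrics()]), plus `n_evaluated`.
#' @export
evaluate_decisions <- function(decisions, manifest, strict = FALSE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  missing <- setdiff(decisions$id, manifest$id)
  if (length(missing))
    stop_cocoon("evaluate_decisions: decision ids missing from manifest: ",
                paste(utils::head(missing, 10), collapse = ", "),
                class = "join_error")
  if (strict) {
    unmatched <- setdiff(manifest$id, decisions$id)
    if (length(unmatched))
      stop_cocoon("evaluate_decisions: manifest ids missing from decisions: ",
                  paste(utils::head(unmatched, 10), collapse = ", "),
                  class = "join_error")
  }
  if (!nrow(decisions))
    stop_cocoon("evaluate_decisions: empty decisions", class = "join_error")
  inc <- decisions$incomplete
  if (any(inc)) message(sum(inc), " incomplete record(s) excluded from metrics")
  d <- decisions[!inc, , drop = FALSE]
  m <- manifest[match(d$id, manifest$id), , drop = FALSE]
  out <- list()
  station_cm <- function(truth_pos, pred_pos) {
    keep <- !is.na(pred_pos) & !is.na(truth_pos)
    if (!any(keep)) return(NULL)
    tryCatch(
      classification_metrics(confusion_matrix(
        ifelse(truth_pos[keep], "pos", "neg"),
        ifelse(pred_pos[keep], "pos", "neg"), positive = "pos")),
      cocoonsort_error = function(e) NULL)  # no positive truth cases
  }
  out$size <- station_cm(m$true_size_class != "ok",
                         d$size_verdict != "ok")
  out$shape <- station_cm(m$true_shape_class == "bad",
                          d$shape_verdict == "bad")
  out$stain <- station_cm(as.logical(m$true_stain), d$stained)
  if (!is.null(m$true_stain_top))
    out$stain_top <- station_cm(as.logical(m$true_stain_top), d$stain_top)
  if (!is.null(m$true_stain_bottom))
    out$stain_bottom <- station_cm(as.logical(m$true_stain_bottom), d$stain_bottom)
  out$vital <- station_cm(m$true_vital_state == "dead",
                          d$vital_verdict == "dead")
  out$n_evaluated <- nrow(d)
  out
}
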