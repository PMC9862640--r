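#' Build an elliptic Fourier descriptor from a coefficient matrix
#'
#' Helper for specifying shapes directly in EFA space (the parameterization
#' the synthetic generator uses, so fixture shape classes have controllable
#' harmonic structure).
#'
#' @param coefficients n x 4 matrix, columns a, b, c, d.
#' @param dc length-2 DC offset (A0, C0).
#' @param n_points nominal outline sampling (default 180).
#' @return an `efa` descriptor.
#' @export
efa_from_coefficients <- function(coefficients, dc = c(0, 0), n_points = 180) {
  coefficients <- as.matrix(coefficients)
  if (ncol(coefficients) != 4)
    stop_cocoon("efa_from_coefficients: need 4 columns (a, b, c, d)",
                class = "parameter_error")
  colnames(coefficients) <- c("a", "b", "c", "d")
  structure(list(n_harmonics = nrow(coefficients),
                 coefficients = coefficients,
                 dc = c(A0 = dc[1], C0 = dc[2]),
                 harmonic_power = rowSums(coefficients^2) / 2,
                 t_norm = (seq_len(n_points) - 1) / n_points,
                 method = "uniform",
                 n_points = as.integer(n_points)),
            class = "efa")
}

# Even-odd scanline polygon rasterization; poly is n x 2 (x, y), 0-based
# coordinates, pixel centers at integers. Returns binary_mask.
polygon_mask <- function(poly, width, height) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  m <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    y <- row - 1
    cross <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(cross)) next
    xi <- x1[cross] + (y - y1[cross]) * (x2[cross] - x1[cross]) / (y2[cross] - y1[cross])
    xi <- sort(xi)
    for (j in seq(1, length(xi) - 1, by = 2)) {
      lo <- ceiling(xi[j]); hi <- floor(xi[j + 1])
      if (xi[j + 1] == floor(xi[j + 1])) hi <- hi - 1  # right edge exclusive
      lo <- max(lo, 0); hi <- min(hi, width - 1)
      if (lo <= hi) m[row, (lo + 1):(hi + 1)] <- TRUE
    }
  }
  binary_mask(m)
}

#' Specify a synthetic cocoon image
#'
#' Declares everything needed to render one cocoon with exact ground truth:
#' the silhouette as a band-limited elliptic Fourier shape, an isotropic
#' pixel scale, surface stains (position relative to the cocoon center,
#' requested area, HSB color), pose, colors and texture noise. Rendered
#' colors are specified in HSB on 0-255 because every detection threshold
#' lives on that scale.
#'
#' @param efa_coefficients n x 4 coefficient matrix of the unit shape
#'   (typical extent around 1; `scale_px` carries the size).
#' @param scale_px isotropic scale factor from shape units to pixels.
#' @param stains list of stains, each `list(center = c(dx, dy), area_px2,
#'   hsb = c(h, s, b))`, center in pixels relative to the cocoon center.
#' @param pose `list(rotation = radians, translation = c(dx, dy))` applied to
#'   the silhouette; translation is relative to the image center.
#' @param cocoon_hsb,background_hsb fill colors.
#' @param noise_sd Gaussian texture noise (in brightness counts) on the
#'   cocoon surface; 0 gives the zero-noise benchmark.
#' @param width,height image dimensions in pixels.
#' @param seed per-image seed (drives the texture only).
#' @return object of class `cocoon_spec`.
#' @export
cocoon_spec <- function(efa_coefficients, scale_px = 50, stains = list(),
                        pose = list(rotation = 0, translation = c(0, 0)),
                        cocoon_hsb = c(30, 25, 235),
                        background_hsb = c(0, 0, 40),
                        noise_sd = 0, width = 323, height = 241, seed = 1) {
  structure(list(efa_coefficients = as.matrix(efa_coefficients),
                 scale_px = scale_px, stains = stains, pose = pose,
                 cocoon_hsb = cocoon_hsb, background_hsb = background_hsb,
                 noise_sd = noise_sd, width = width, height = height,
                 seed = seed),
            class = "cocoon_spec")
}

#' Render a synthetic cocoon image with ground truth
#'
#' Rasterizes the EFA-defined silhouette (even-odd scanline fill of a
#' densely resampled polygon), fills it with the cocoon color plus optional
#' Gaussian brightness texture, composites the requested stains as discs
#' clipped to the silhouette, and returns the image together with a ground
#' truth record: the true outline polygon, the analytic (shoelace) and
#' rendered pixel areas, and per-stain requested vs rendered areas. The same
#' seed renders a byte-identical image.
#'
#' @param spec a [cocoon_spec].
#' @return list with `image` (an [rgb_image]) and `truth` (list: `polygon`,
#'   `analytic_area_px2`, `area_px2`, `centroid`, `stains` data frame).
#' @export
render_cocoon <- function(spec) {
  stopifnot(inherits(spec, "cocoon_spec"))
  d <- efa_from_coefficients(spec$efa_coefficients)
  poly <- efa_reconstruct(d, n_points = 720)$points * spec$scale_px
  ang <- spec$pose$rotation %||% 0
  if (ang != 0) {
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    poly <- poly %*% rot
  }
  ctr <- c((spec$width - 1) / 2, (spec$height - 1) / 2) +
    (spec$pose$translation %||% c(0, 0))
  poly <- sweep(poly, 2, ctr, "+")
  if (min(poly[, 1]) < 1 || max(poly[, 1]) > spec$width - 2 ||
      min(poly[, 2]) < 1 || max(poly[, 2]) > spec$height - 2)
    stop_cocoon("render_cocoon: silhouette does not fit inside the image",
                class = "spec_error")
  xs <- poly[, 1]; ys <- poly[, 2]
  analytic_area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  mask <- polygon_mask(poly, spec$width, spec$height)

  hsb <- array(0, dim = c(spec$height, spec$width, 3))
  for (ch in 1:3) hsb[, , ch] <- spec$background_hsb[ch]
  fg <- which(unclass(mask))
  npx <- spec$height * spec$width
  for (ch in 1:3) hsb[fg + (ch - 1) * npx] <- spec$cocoon_hsb[ch]
  if (spec$noise_sd > 0) {
    bvals <- hsb[fg + 2 * npx] +
      with_seed(spec$seed, stats::rnorm(length(fg), 0, spec$noise_sd))
    hsb[fg + 2 * npx] <- pmin(pmax(bvals, 0), 255)
  }

  xg <- matrix(rep(0:(spec$width - 1), each = spec$height), spec$height)
  yg <- matrix(rep(0:(spec$height - 1), spec$width), spec$height)
  stain_rows <- list()
  for (i in seq_along(spec$stains)) {
    st <- spec$stains[[i]]
    cx <- ctr[1] + st$center[1]; cy <- ctr[2] + st$center[2]
    row <- round(cy) + 1; col <- round(cx) + 1
    if (row < 1 || row > spec$height || col < 1 || col > spec$width ||
        !mask[row, col])
      stop_cocoon("render_cocoon: stain ", i, " center outside the silhouette",
                  class = "spec_error")
    r <- sqrt(st$area_px2 / pi)
    inside <- (xg - cx)^2 + (yg - cy)^2 <= r^2
    px <- which(inside & unclass(mask))
    for (ch in 1:3) hsb[px + (ch - 1) * npx] <- st$hsb[ch]
    stain_rows[[i]] <- data.frame(stain = i, center_x = cx, center_y = cy,
                                  requested_area_px2 = st$area_px2,
                                  rendered_area_px2 = length(px))
  }
  img <- hsb_to_rgb(hsb_image(hsb))
  truth <- list(polygon = poly,
                analytic_area_px2 = analytic_area,
                area_px2 = sum(mask),
                centroid = ctr,
                mask = mask,
                stains = if (length(stain_rows)) do.call(rbind, stain_rows)
                         else data.frame())
  list(image = img, truth = truth)
}

#' Cocoon shape coefficient generator
#'
#' Draws a band-limited EFA coefficient matrix for a unit-size cocoon.
#' Well-shaped cocoons are ovoids: an ellipse of aspect about 1.5 with only
#' faint higher harmonics. Bad-shaped ("peanut", waisted or malformed)
#' cocoons carry a pronounced waist, i.e. extra power in harmonic 3 (the
#' radial perturbation r -> r (1 - w cos 2t) of an ellipse lands on
#' harmonics 1 and 3), plus stronger irregular harmonics 2-5.
#'
#' @param class `"well"` or `"bad"`.
#' @param seed per-shape seed.
#' @return 8 x 4 coefficient matrix (unit scale).
#' @export
random_cocoon_coefficients <- function(class = c("well", "bad"), seed = 1) {
  class <- match.arg(class)
  with_seed(seed, {
    a <- stats::runif(1, 0.88, 1.0)          # semi-major (x)
    b <- a / stats::runif(1, 1.45, 1.65)     # ovoid aspect ratio
    w <- if (class == "bad") stats::runif(1, 0.28, 0.40)
         else stats::runif(1, 0, 0.06)
    irr <- if (class == "bad") 0.025 else 0.012
    cf <- matrix(0, 8, 4)
    cf[1, ] <- c(a * (1 - w / 2), 0, 0, b * (1 + w / 2))
    cf[3, ] <- c(-a * w / 2, 0, 0, -b * w / 2)
    for (h in 2:5) cf[h, ] <- cf[h, ] + stats::rnorm(4, 0, irr / h)
    cf
  })
}

#' Specify a synthetic photodiode population
#'
#' Two-class generative model for sensor frames: each of the 35 channels is
#' Gaussian around a per-channel mean with common spread, and the dead class
#' is shifted by `separation` pooled standard deviations on every channel (a
#' dead, desiccated pupa lets more light through). Counts are rounded and
#' clipped to the 10-bit ADC range.
#'
#' @param class_label `"alive"` or `"dead"`.
#' @param means per-channel alive-class means (length 35 or scalar).
#' @param sd common channel standard deviation.
#' @param separation between-class mean shift in units of `sd`.
#' @param seed generator seed.
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(class_label = c("alive", "dead"), means = 480,
                        sd = 60, separation = 3, seed = 1) {
  class_label <- match.arg(class_label)
  if (length(means) == 1) means <- rep(means, 35)
  stopifnot(length(means) == 35, sd > 0, separation >= 0)
  structure(list(class_label = class_label, means = means, sd = sd,
                 separation = separation, seed = seed),
            class = "sensor_spec")
}

#' Draw synthetic sensor frames
#'
#' @param spec a [sensor_spec].
#' @param n number of frames.
#' @param start_id progressive id of the first frame.
#' @param timestamp timestamp recorded on every frame.
#' @return list of `n` [sensor_frame]s.
#' @export
render_sensor_frames <- function(spec, n, start_id = 1, timestamp = "") {
  stopifnot(inherits(spec, "sensor_spec"), n >= 1)
  mu <- spec$means + (spec$class_label == "dead") * spec$separation * spec$sd
  with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      counts <- round(stats::rnorm(35, mu, spec$sd))
      sensor_frame(pmin(pmax(counts, 0), 1023),
                   timestamp = timestamp,
                   cocoon_id = start_id + i - 1)
    })
  })
}

benchmark_categories <- function() {
  data.frame(
    category = 1:6,
    shape = c("well", "bad", "well", "well", "well", "well"),
    stain = c("mixed", "mixed", "stained", "white", "mixed", "mixed"),
    vital = c("mixed", "mixed", "mixed", "mixed", "alive", "dead"),
    stringsAsFactors = FALSE
  )
}

camera_names <- function() c(shape = "camera1-shape", top = "camera2-top",
                             bottom = "camera3-bottom")

benchmark_timestamp <- function(id) {
  format(as.POSIXct("2022-09-01 12:00:00", tz = "UTC") + id, "%Y%m%d%H%M%S")
}

#' Generate a full synthetic benchmark dataset
#'
#' Builds an on-disk acquisition mimicking the machine's layout: one folder
#' of BMP images per camera (shape, stain-top, stain-bottom), the photodiode
#' CSV, a ground-truth manifest, and a matching `config.yaml`. Cocoons are
#' drawn from the six sample categories used to exercise every station
#' (well/bad shape, stained/white, alive/dead pupae, in the mixes listed by
#' `benchmark_categories()`), with an independent share of under- and
#' oversized cocoons. Filenames carry the acquisition timestamp, the camera
#' name and the progressive number. All randomness fans out from `seed`
#' through per-cocoon derived seeds.
#'
#' @param out_dir output directory (created).
#' @param n_per_category cocoons per category (default 100).
#' @param seed master seed.
#' @param scale optical scale relative to the reference camera geometry
#'   (default 0.25: quarter-resolution images, areas scaled by scale^2).
#' @param noise_sd cocoon surface texture noise (0 = zero-noise benchmark).
#' @param p_stain probability a "mixed"-stain cocoon is stained.
#' @param p_size_defect probability of an under- or oversized cocoon.
#' @param sensor_separation class separation of the photodiode model.
#' @return the manifest data frame, invisibly; side effect: files under
#'   `out_dir`.
#' @export
make_benchmark_set <- function(out_dir, n_per_category = 100, seed = 1,
                               scale = 0.25, noise_sd = 0, p_stain = 0.5,
                               p_size_defect = 0.2, sensor_separation = 3) {
  width <- round(1292 * scale); height <- round(964 * scale)
  px2_per_mm2 <- 273 * scale^2
  cams <- camera_names()
  for (cam in cams) dir.create(file.path(out_dir, cam), recursive = TRUE,
                               showWarnings = FALSE)
  dir.create(file.path(out_dir, "sensor"), showWarnings = FALSE)

  cats <- benchmark_categories()
  rows <- list(); frames <- list()
  id <- 0
  for (ci in seq_len(nrow(cats))) {
    for (j in seq_len(n_per_category)) {
      id <- id + 1
      s <- derive_seed(seed, id)
      item <- with_seed(s, {
        shape_class <- cats$shape[ci]
        stained <- switch(cats$stain[ci], stained = TRUE, white = FALSE,
                          mixed = stats::runif(1) < p_stain)
        vital <- switch(cats$vital[ci], alive = "alive", dead = "dead",
                        mixed = sample(c("alive", "dead"), 1))
        u <- stats::runif(1)
        area_mm2 <- if (u < p_size_defect / 2) stats::runif(1, 180, 240)
          else if (u < p_size_defect) stats::runif(1, 540, 620)
          else stats::runif(1, 330, 420)
        list(shape_class = shape_class, stained = stained, vital = vital,
             area_mm2 = area_mm2,
             rotation = stats::runif(1, -0.3, 0.3),
             translation = stats::runif(2, -6, 6),
             stain_side = sample(c("top", "bottom", "both"), 1,
                                 prob = c(0.4, 0.4, 0.2)),
             # physical stain size 2-5 mm^2, well above the object-area rule
             # (144 px^2 at the reference optics is about 0.53 mm^2)
             stain_area = stats::runif(1, 2, 5) * px2_per_mm2,
             stain_offset = stats::runif(2, -0.12, 0.12))
      })
      cf <- random_cocoon_coefficients(item$shape_class, seed = derive_seed(s, 7))
      base_poly <- efa_reconstruct(efa_from_coefficients(cf), n_points = 360)$points
      xs <- base_poly[, 1]; ys <- base_poly[, 2]
      unit_area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
      scale_px <- sqrt(item$area_mm2 * px2_per_mm2 / unit_area)

      mkspec <- function(stains) cocoon_spec(
        cf, scale_px = scale_px, stains = stains,
        pose = list(rotation = item$rotation, translation = item$translation),
        noise_sd = noise_sd, width = width, height = height,
        seed = derive_seed(s, 11))
      stain_for <- function(view) {
        if (!item$stained || !(item$stain_side %in% c(view, "both")))
          return(list())
        col <- if (view == "top") c(20, 180, 200) else c(10, 235, 120)
        list(list(center = item$stain_offset * scale_px, area_px2 = item$stain_area,
                  hsb = col))
      }
      ts <- benchmark_timestamp(id)
      files <- character(3); names(files) <- names(cams)
      truth_area <- NA
      for (v in names(cams)) {
        stains <- if (v == "shape") list() else stain_for(v)
        rend <- render_cocoon(mkspec(stains))
        f <- file.path(cams[[v]], sprintf("%s_%s_%06d.bmp", ts, cams[[v]], id))
        write_bmp(rend$image, file.path(out_dir, f))
        files[v] <- f
        if (v == "shape") truth_area <- rend$truth$area_px2
      }
      sspec <- sensor_spec(item$vital, separation = sensor_separation,
                           seed = derive_seed(s, 13))
      frames[[id]] <- render_sensor_frames(sspec, 1, start_id = id,
                                           timestamp = ts)[[1]]
      min_px2 <- round(81900 * scale^2); max_px2 <- round(124500 * scale^2)
      rows[[id]] <- data.frame(
        id = as.integer(id), category = as.integer(ci),
        shape_file = files["shape"], top_file = files["top"],
        bottom_file = files["bottom"],
        true_area_px2 = truth_area,
        true_size_class = if (truth_area <= min_px2) "undersized"
                          else if (truth_area >= max_px2) "oversized" else "ok",
        true_shape_class = item$shape_class,
        true_stain = item$stained,
        true_stain_top = item$stained && item$stain_side %in% c("top", "both"),
        true_stain_bottom = item$stained && item$stain_side %in% c("bottom", "both"),
        true_vital_state = item$vital,
        stringsAsFactors = FALSE)
    }
  }
  write_sensor_csv(frames, file.path(out_dir, "sensor", "frames.csv"))
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- default_config()
  cfg$size$min_px2 <- round(81900 * scale^2)
  cfg$size$max_px2 <- round(124500 * scale^2)
  cfg$size$px2_per_mm2 <- px2_per_mm2
  cfg$stain$min_area_px2 <- max(round(144 * scale^2), 2)
  cfg$generator <- list(seed = seed, scale = scale, noise_sd = noise_sd,
                        n_per_category = n_per_category)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}
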