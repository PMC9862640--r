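#' Raster containers
#'
#' Images are stored as plain arrays with a light S3 class for validation:
#' an `rgb_image` is an integer height x width x 3 array with channels R, G, B
#' on the 0-255 scale; an `hsb_image` is the analogous numeric array holding
#' hue, saturation and brightness, each linearly rescaled to 0-255 (the scale
#' on which all stain thresholds are expressed); a `binary_mask` is a logical
#' height x width matrix with foreground = TRUE. Pixel coordinates are 0-based
#' with the origin at the top-left corner and rasters stored row-major
#' (row = y, column = x).
#'
#' @param pixels array of dimension height x width x 3 (images) or a logical
#'   matrix (masks).
#' @return the validated classed object.
#' @name rasters
NULL

#' @rdname rasters
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop_cocoon("rgb_image: pixels must be a height x width x 3 array",
                class = "invalid_image")
  if (any(is.na(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop_cocoon("rgb_image: channel values must lie in [0, 255]",
                class = "invalid_image")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' @rdname rasters
#' @export
hsb_image <- function(pixels) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop_cocoon("hsb_image: pixels must be a height x width x 3 array",
                class = "invalid_image")
  if (any(is.na(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop_cocoon("hsb_image: channel values must lie in [0, 255]",
                class = "invalid_image")
  structure(pixels, class = "hsb_image")
}

#' @rdname rasters
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels))
    stop_cocoon("binary_mask: pixels must be a matrix", class = "invalid_image")
  storage.mode(pixels) <- "logical"
  pixels[is.na(pixels)] <- FALSE
  structure(pixels, class = "binary_mask")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.hsb_image <- function(x, ...) {
  cat(sprintf("<hsb_image %d x %d>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Convert an RGB image to HSB
#'
#' Standard hexcone hue/saturation/brightness conversion with every channel
#' linearly rescaled to 0-255, so that fixed thresholds for hue, saturation
#' and brightness all live on the same 8-bit scale.
#'
#' @param img an [rgb_image].
#' @return an [hsb_image] of the same dimensions.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_hsb(rgb_image(px))  # H = 0, S = 255, B = 255
#' @export
rgb_to_hsb <- function(img) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  d <- dim(img)
  r <- as.numeric(img[, , 1]); g <- as.numeric(img[, , 2]); b <- as.numeric(img[, , 3])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  s <- ifelse(mx > 0, delta / mx, 0)
  h <- numeric(length(r))
  nz <- delta > 0
  hr <- nz & mx == r
  hg <- nz & mx == g & !hr
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / delta[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / delta[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / delta[hb] + 4
  h <- h / 6
  out <- array(0, dim = d)
  out[, , 1] <- h * 255
  out[, , 2] <- s * 255
  out[, , 3] <- mx
  structure(out, class = "hsb_image")  # in [0,255] by construction
}

#' Convert an HSB image back to RGB
#'
#' Inverse hexcone conversion; round-trips with [rgb_to_hsb()] to within one
#' quantization step. Used by the synthetic renderer, whose colors are
#' specified in HSB because all stain thresholds are.
#'
#' @param hsb an [hsb_image], or a numeric vector of length 3 (one color).
#' @return an [rgb_image] (or integer vector of length 3 for one color).
#' @export
hsb_to_rgb <- function(hsb) {
  one <- is.numeric(hsb) && is.null(dim(hsb)) && length(hsb) == 3
  if (one) hsb <- hsb_image(array(hsb, dim = c(1, 1, 3)))
  if (!inherits(hsb, "hsb_image")) hsb <- hsb_image(hsb)
  cols <- grDevices::hsv(pmin(as.vector(hsb[, , 1]) / 255, 1),
                         as.vector(hsb[, , 2]) / 255,
                         as.vector(hsb[, , 3]) / 255)
  m <- grDevices::col2rgb(cols)
  out <- array(0L, dim = dim(hsb))
  out[, , 1] <- m[1, ]
  out[, , 2] <- m[2, ]
  out[, , 3] <- m[3, ]
  img <- rgb_image(out)
  if (one) return(as.integer(img[1, 1, ]))
  img
}

#' Edge-emphasis map of an HSB image
#'
#' Computes the per-pixel map \eqn{M = \log(|0.2989 H + 0.5870 S + 0.1140 B| +
#' \epsilon)}: the BT.601 luminance weights applied to the HSB channels. The
#' brightness channel tracks the change in illumination across an object edge
#' while hue and saturation separate the inner side of the border from the
#' background, so the weighted sum emphasizes silhouette edges; the log
#' compresses the dynamic range. The map is then normalized to its maximum and
#' quantized to 8 bits for histogram thresholding.
#'
#' The epsilon guard keeps the log finite on zero pixels; the weighted sum is
#' otherwise used exactly as written.
#'
#' @param hsb an [hsb_image].
#' @param eps small positive constant added inside the log (default 1e-6).
#' @return an object of class `edge_map`: list with `values` (the real matrix
#'   M), `normalized8` (integer matrix on 0-255 after max-normalization) and
#'   `degenerate` (TRUE when the quantized map is constant, in which case
#'   binarization must reject it).
#' @export
edge_map <- function(hsb, eps = 1e-6) {
  if (!inherits(hsb, "hsb_image")) hsb <- hsb_image(hsb)
  stopifnot(eps > 0)
  lin <- 0.2989 * hsb[, , 1] + 0.5870 * hsb[, , 2] + 0.1140 * hsb[, , 3]
  m <- log(abs(lin) + eps)
  mx <- max(m)
  if (mx == 0) {
    norm <- m + 1  # max is exactly 0: shift so the maximum maps to full scale
  } else {
    norm <- m / mx
  }
  n8 <- matrix(as.integer(round_half_up(255 * pmin(pmax(norm, 0), 1))),
               nrow(m), ncol(m))
  structure(list(values = m, normalized8 = n8,
                 degenerate = length(unique(as.vector(n8))) < 2),
            class = "edge_map")
}

#' Otsu threshold of an 8-bit image
#'
#' Exact integer Otsu: over the 256-bin histogram, picks the threshold t in
#' 0..254 maximizing the between-class variance of the split into pixels <= t
#' and pixels > t (ties resolved to the smallest t).
#'
#' @param x integer vector/matrix of values in 0..255.
#' @return the integer threshold.
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  if (any(v < 0 | v > 255)) stop_cocoon("otsu_threshold: values outside 0..255",
                                        class = "invalid_image")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w <- cumsum(h) / n          # P(value <= t)
  mu <- cumsum(h * lev) / n   # partial mean mass
  mu_t <- mu[256]
  t <- 0:254
  w0 <- w[t + 1]
  num <- (mu_t * w0 - mu[t + 1])^2
  den <- w0 * (1 - w0)
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  if (all(!is.finite(sigma_b)))
    stop_cocoon("otsu_threshold: constant image has no threshold",
                class = "degenerate_image")
  t[which.max(sigma_b)]
}

#' Binarize an edge map with the Otsu threshold
#'
#' Thresholds the 8-bit normalized edge map at the between-class-variance
#' maximizer. The cocoon sits at the image center in its cradle, so by default
#' the class containing the center pixel is taken as foreground; this polarity
#' can be forced instead.
#'
#' @param edge an [edge_map].
#' @param polarity `"auto"` (class of the center pixel is foreground),
#'   `"above"` (pixels above threshold) or `"below"`.
#' @return a [binary_mask].
#' @export
otsu_binarize <- function(edge, polarity = c("auto", "above", "below")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(edge, "edge_map"))
  if (edge$degenerate)
    stop_cocoon("otsu_binarize: degenerate (constant) edge map",
                class = "degenerate_image")
  n8 <- edge$normalized8
  t <- otsu_threshold(n8)
  mask <- n8 > t
  if (polarity == "below") mask <- !mask
  if (polarity == "auto") {
    ctr <- mask[ceiling(nrow(mask) / 2), ceiling(ncol(mask) / 2)]
    if (!ctr) mask <- !mask
  }
  m <- binary_mask(mask)
  attr(m, "threshold") <- t
  m
}

#' 8-connected component labeling
#'
#' Labels connected foreground regions using 8-connectivity (diagonal
#' neighbours join). Built on 4-connected labeling with a union-find merge of
#' labels that touch diagonally.
#'
#' @param mask a [binary_mask].
#' @return integer matrix of labels (0 = background), with attribute `n`.
#' @export
label_components <- function(mask) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  nl <- max(lab)
  if (nl > 1L) {
    # union-find over 4-connected labels touching along either diagonal
    parent <- seq_len(nl)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-nr, -1]),  as.vector(lab[-1, -nc]))   # down-left
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nl), find, integer(1))
      remap <- match(root, sort(unique(root)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      nl <- max(lab)
    }
  }
  attr(lab, "n") <- nl
  lab
}

#' Keep the dominant cocoon region
#'
#' One cocoon per cradle: the mask is reduced to its largest 8-connected
#' component and interior holes are filled.
#'
#' @param mask a [binary_mask] with at least one foreground component.
#' @return a [binary_mask] containing one filled region.
#' @export
select_cocoon_region <- function(mask) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  lab <- label_components(mask)
  if (attr(lab, "n") == 0L)
    stop_cocoon("select_cocoon_region: no foreground object in mask",
                class = "no_object")
  areas <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  keep <- which.max(areas)
  m <- lab == keep
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  binary_mask(filled)
}

#' Size thresholds
#'
#' Pixel-area acceptance band for the size station. Defaults are the
#' machine's operating thresholds at full camera resolution: cocoons are
#' accepted when 81,900 px^2 < area < 124,500 px^2, which at the optics
#' calibration of 273 px^2 per mm^2 corresponds to the 300-450 mm^2 band of
#' normal cocoons. The calibration factor is exposed because it is purely a
#' property of the optics.
#'
#' @param min_px2,max_px2 integer pixel-area bounds (strict).
#' @param px2_per_mm2 optional calibration factor.
#' @return object of class `size_thresholds`.
#' @export
size_thresholds <- function(min_px2 = 81900, max_px2 = 124500,
                            px2_per_mm2 = 273) {
  stopifnot(min_px2 > 0, min_px2 < max_px2)
  structure(list(min_px2 = min_px2, max_px2 = max_px2,
                 px2_per_mm2 = px2_per_mm2),
            class = "size_thresholds")
}

#' Measure cocoon area and gate on size
#'
#' Counts foreground pixels of the selected region and applies the strict
#' acceptance band: area <= min is undersized, area >= max is oversized
#' (boundary values are rejected), anything between is ok.
#'
#' @param mask a [binary_mask] holding the single selected region.
#' @param thresholds a [size_thresholds].
#' @return list with `area_px2` (integer), `verdict` (one of `"undersized"`,
#'   `"ok"`, `"oversized"`) and `area_mm2` when a calibration is available.
#' @export
measure_and_gate_size <- function(mask, thresholds = size_thresholds()) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  stopifnot(inherits(thresholds, "size_thresholds"))
  area <- sum(mask)
  if (area == 0L)
    stop_cocoon("measure_and_gate_size: empty mask", class = "no_object")
  verdict <- if (area <= thresholds$min_px2) "undersized"
             else if (area >= thresholds$max_px2) "oversized"
             else "ok"
  out <- list(area_px2 = as.integer(area), verdict = verdict)
  if (!is.null(thresholds$px2_per_mm2))
    out$area_mm2 <- area / thresholds$px2_per_mm2
  out
}

#' Segment one cocoon image
#'
#' Convenience wrapper running the full segmentation chain: HSB conversion,
#' edge-emphasis map, Otsu binarization, dominant-region selection.
#'
#' @param img an [rgb_image].
#' @param eps epsilon of [edge_map()].
#' @param polarity see [otsu_binarize()].
#' @return a [binary_mask] with the filled cocoon silhouette.
#' @export
segment_cocoon <- function(img, eps = 1e-6, polarity = "auto") {
  hsb <- if (inherits(img, "hsb_image")) img else rgb_to_hsb(img)
  em <- edge_map(hsb, eps = eps)
  mask <- otsu_binarize(em, polarity = polarity)
  select_cocoon_region(mask)
}
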