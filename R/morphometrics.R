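#' Outline objects
#'
#' An `outline` is an ordered closed polygon of (x, y) points in pixel units,
#' by convention digitized counterclockwise in image coordinates starting at
#' angle 0, with the closing edge running from the last point back to the
#' first. The radial digitizer places point i on the ray at angle
#' (i - 1) * 2 * pi / n from the centroid.
#'
#' @param points numeric n x 2 matrix of (x, y) coordinates.
#' @param centroid optional (x, y); defaults to the polygon vertex mean.
#' @return object of class `outline`.
#' @export
outline <- function(points, centroid = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3 || any(!is.finite(points)))
    stop_cocoon("outline: points must be a finite n x 2 matrix, n >= 3",
                class = "invalid_outline")
  colnames(points) <- c("x", "y")
  structure(list(points = points,
                 centroid = centroid %||% colMeans(points)),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline: %d points, centroid (%.1f, %.1f)>\n",
              nrow(x$points), x$centroid[1], x$centroid[2]))
  invisible(x)
}

# Bilinear interpolation of a matrix at 0-based (x, y) positions; outside -> 0.
bilinear_at <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(r, c) {
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok] + 1, c[ok] + 1)]
    out
  }
  v00 <- val(y0, x0);     v01 <- val(y0, x0 + 1)
  v10 <- val(y0 + 1, x0); v11 <- val(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Digitize a silhouette outline by radial sampling
#'
#' Casts `n_points` rays from the region centroid, one every
#' 2 * pi / n_points radians (pi/90 for the default 180 points), and records
#' for each ray the outermost crossing of the region boundary, located to
#' sub-pixel precision by linear interpolation of the bilinearly sampled mask.
#' Taking the outermost crossing keeps deeply waisted silhouettes
#' representable even where a ray crosses the boundary more than once.
#'
#' @param mask a [binary_mask] holding one filled region whose centroid lies
#'   inside the region.
#' @param n_points number of rays (default 180).
#' @param step radial sampling step in pixels (default 0.5).
#' @return an [outline] with `n_points` points in 0-based pixel coordinates.
#' @export
digitize_outline <- function(mask, n_points = 180, step = 0.5) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop_cocoon("digitize_outline: empty mask", class = "no_object")
  cy <- mean(idx[, 1]) - 1  # 0-based
  cx <- mean(idx[, 2]) - 1
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (bilinear_at(m, cx, cy) < 0.5)
    stop_cocoon("digitize_outline: centroid falls outside the region",
                class = "digitization_error")
  rmax <- sqrt(max((idx[, 2] - 1 - cx)^2 + (idx[, 1] - 1 - cy)^2)) + 1.5
  r <- seq(0, rmax, by = step)
  theta <- (seq_len(n_points) - 1) * 2 * pi / n_points
  # sample all rays at once: (length(r) x n_points) grids
  px <- cx + outer(r, cos(theta))
  py <- cy + outer(r, sin(theta))
  v <- matrix(bilinear_at(m, as.vector(px), as.vector(py)),
              length(r), n_points)
  inside <- v >= 0.5
  radial <- numeric(n_points)
  for (j in seq_len(n_points)) {
    k <- max(which(inside[, j]))
    if (k == length(r)) { radial[j] <- r[k]; next }
    v0 <- v[k, j]; v1 <- v[k + 1, j]
    frac <- if (v0 > v1) (v0 - 0.5) / (v0 - v1) else 0
    radial[j] <- r[k] + step * frac
  }
  pts <- cbind(x = cx + radial * cos(theta), y = cy + radial * sin(theta))
  outline(pts, centroid = c(cx, cy))
}

# Optimal rotation (no reflection) aligning centered config X onto mu.
opa_rotation <- function(x, mu) {
  s <- svd(crossprod(x, mu))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment of outlines
#'
#' Full superimposition of a set of equally sampled outlines: each
#' configuration is centered, scaled to unit centroid size (size is gated by a
#' separate station, so shape features are size-free), and then iteratively
#' rotated onto the evolving mean shape until the summed squared residual
#' changes by less than `tol` relatively, or `max_iter` passes.
#'
#' @param outlines list of [outline] objects (or n x 2 matrices) with equal
#'   point counts.
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return object of class `aligned_outlines`: list with `outlines` (aligned
#'   n x 2 matrices), `mean_shape` (its centroid at the origin),
#'   `residual_ss`, and `iterations`.
#' @export
procrustes_align <- function(outlines, tol = 1e-8, max_iter = 200) {
  mats <- lapply(outlines, function(o) if (inherits(o, "outline")) o$points else as.matrix(o))
  if (length(mats) < 2)
    stop_cocoon("procrustes_align: need at least two outlines",
                class = "alignment_error")
  np <- vapply(mats, nrow, integer(1))
  if (length(unique(np)) != 1)
    stop_cocoon("procrustes_align: outlines must share the point count",
                class = "alignment_error")
  mats <- lapply(mats, function(x) {
    x <- sweep(x, 2, colMeans(x))
    s <- sqrt(sum(x^2))
    if (s == 0) stop_cocoon("procrustes_align: degenerate outline (zero spread)",
                            class = "alignment_error")
    x / s
  })
  mu <- mats[[1]]
  res_old <- Inf
  it <- 0
  repeat {
    it <- it + 1
    mats <- lapply(mats, function(x) x %*% opa_rotation(x, mu))
    mu <- Reduce(`+`, mats) / length(mats)
    res <- sum(vapply(mats, function(x) sum((x - mu)^2), numeric(1)))
    if (it >= max_iter) break
    if (is.finite(res_old) &&
        abs(res_old - res) <= tol * max(res_old, .Machine$double.eps)) break
    res_old <- res
  }
  structure(list(outlines = mats, mean_shape = mu,
                 residual_ss = res, iterations = it),
            class = "aligned_outlines")
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size and
#' optimally rotated; the distance is the root summed squared difference.
#'
#' @param a,b n x 2 matrices or [outline] objects with equal point counts.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- if (inherits(a, "outline")) a$points else as.matrix(a)
  b <- if (inherits(b, "outline")) b$points else as.matrix(b)
  a <- sweep(a, 2, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2, colMeans(b)); b <- b / sqrt(sum(b^2))
  a <- a %*% opa_rotation(a, b)
  sqrt(sum((a - b)^2))
}

#' Align one outline onto a reference shape
#'
#' Ordinary Procrustes superimposition of a single (new) outline onto a stored
#' mean shape, used when predicting with a fitted shape model.
#'
#' @param o an [outline] or n x 2 matrix.
#' @param reference n x 2 matrix (e.g. `mean_shape` of [procrustes_align()]).
#' @return n x 2 matrix.
#' @export
align_to_reference <- function(o, reference) {
  x <- if (inherits(o, "outline")) o$points else as.matrix(o)
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(sum(x^2))
  if (s == 0) stop_cocoon("align_to_reference: degenerate outline",
                          class = "alignment_error")
  x <- x / s
  x %*% opa_rotation(x, as.matrix(reference))
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Decomposes the x and y coordinates of a closed outline polygon into
#' separate Fourier series, four coefficients (a_i, b_i, c_i, d_i) per
#' harmonic; the harmonic power is (a_i^2 + b_i^2 + c_i^2 + d_i^2) / 2 and
#' the maximum computable harmonic is the Nyquist limit, half the number of
#' outline points.
#'
#' Two parameterizations are provided. The default, `"uniform"`, places the
#' points at equal parameter steps and computes the coefficients by the
#' discrete Fourier transform of the coordinate series. For outlines
#' digitized at equal angular spacing the chord lengths are nearly uniform,
#' so this matches the chordal convention closely while making the
#' decomposition an exactly invertible transform: reconstruction from all
#' Nyquist harmonics reproduces the input points to machine precision, and
#' the harmonic powers satisfy Parseval's identity against the signal power
#' of the coordinate series. `"chord"` computes the classical coefficients by
#' the exact closed-form integrals of the piecewise-linear coordinate
#' functions of cumulative chordal length; it is retained for comparison with
#' the classical morphometrics literature (its reconstruction incurs the
#' O(1/N^2) piecewise-linear truncation bias instead of being exact).
#'
#' @param o an [outline] (or n x 2 matrix) of distinct consecutive points.
#' @param n number of harmonics, 1 <= n <= n_points / 2.
#' @param method `"uniform"` (default) or `"chord"`, see Details.
#' @param t optional explicit parameter values for `method = "chord"`
#'   (length n_points, strictly increasing from 0; attribute `"period"` may
#'   carry the full period).
#' @return object of class `efa`: list with `n_harmonics`, `coefficients`
#'   (n x 4 matrix, columns a, b, c, d), `dc` (A0, C0), `harmonic_power`,
#'   `t_norm` (parameter of each input point, normalized to [0, 1)), and
#'   `n_points`.
#' @export
efa_decompose <- function(o, n, method = c("uniform", "chord"), t = NULL) {
  method <- match.arg(method)
  x <- if (inherits(o, "outline")) o$points else as.matrix(o)
  np <- nrow(x)
  if (n < 1 || n > np / 2)
    stop_cocoon("efa_decompose: n must be between 1 and the Nyquist limit ",
                floor(np / 2), class = "parameter_error")
  xs <- x[, 1]; ys <- x[, 2]
  if (method == "uniform") {
    fx <- stats::fft(xs) / np
    fy <- stats::fft(ys) / np
    harm <- seq_len(n)
    a <- 2 * Re(fx[harm + 1]); b <- -2 * Im(fx[harm + 1])
    cc <- 2 * Re(fy[harm + 1]); d <- -2 * Im(fy[harm + 1])
    if (np %% 2 == 0 && n == np / 2) {
      # Nyquist harmonic: pure cosine, not double-counted
      a[n] <- a[n] / 2; b[n] <- 0
      cc[n] <- cc[n] / 2; d[n] <- 0
    }
    a0 <- Re(fx[1]); c0 <- Re(fy[1])
    t0 <- (seq_len(np) - 1) / np
    bigT <- 1
  } else {
    dx <- diff(c(xs, xs[1]))
    dy <- diff(c(ys, ys[1]))
    if (is.null(t)) {
      dt <- sqrt(dx^2 + dy^2)
      if (any(dt == 0))
        stop_cocoon("efa_decompose: repeated consecutive points (zero chord)",
                    class = "invalid_outline")
      tc <- cumsum(dt)               # t at points 2..np, then closure
      bigT <- tc[np]
      t0 <- c(0, tc[-np])            # parameter of each input point
    } else {
      if (length(t) != np || t[1] != 0 || any(diff(t) <= 0))
        stop_cocoon("efa_decompose: t must have length n_points, start at 0 and increase",
                    class = "parameter_error")
      bigT <- attr(t, "period") %||% (t[np] + (t[np] - t[np - 1]))
      t0 <- as.vector(t)
      tc <- c(t0[-1], bigT)
      dt <- tc - t0
    }
    phi1 <- 2 * pi * t0 / bigT       # phase at segment start
    phi2 <- 2 * pi * tc / bigT       # phase at segment end
    harm <- seq_len(n)
    cos2 <- cos(outer(phi2, harm)); cos1 <- cos(outer(phi1, harm))
    sin2 <- sin(outer(phi2, harm)); sin1 <- sin(outer(phi1, harm))
    fac <- bigT / (2 * pi^2 * harm^2)
    sx <- dx / dt; sy <- dy / dt
    a <- fac * colSums(sx * (cos2 - cos1))
    b <- fac * colSums(sx * (sin2 - sin1))
    cc <- fac * colSums(sy * (cos2 - cos1))
    d <- fac * colSums(sy * (sin2 - sin1))
    # DC terms: the mean of the piecewise-linear x(t), y(t)
    a0 <- sum((xs + dx / 2) * dt) / bigT
    c0 <- sum((ys + dy / 2) * dt) / bigT
    t0 <- t0 / bigT
  }
  coefs <- cbind(a = a, b = b, c = cc, d = d)
  structure(list(n_harmonics = as.integer(n),
                 coefficients = coefs,
                 dc = c(A0 = a0, C0 = c0),
                 harmonic_power = rowSums(coefs^2) / 2,
                 t_norm = t0,
                 method = method,
                 n_points = np),
            class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("<efa: %d harmonics (%d coefficients), %d outline points>\n",
              x$n_harmonics, 4 * x$n_harmonics, x$n_points))
  invisible(x)
}

#' @export
coef.efa <- function(object, k = object$n_harmonics, ...) {
  m <- object$coefficients[seq_len(k), , drop = FALSE]
  v <- as.vector(t(m))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), k), rep(seq_len(k), each = 4))
  v
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series from the first `k` harmonics. By
#' default the series is evaluated at the parameter values stored during
#' decomposition, so that with k equal to the full harmonic count the original
#' points are recovered up to Fourier truncation at the Nyquist limit;
#' alternatively a uniform resampling with `n_points` positions is produced.
#'
#' @param desc an `efa` descriptor.
#' @param k number of harmonics to use, 1 <= k <= `desc$n_harmonics`.
#' @param n_points if given, evaluate at `n_points` uniformly spaced parameter
#'   values instead of the stored ones.
#' @return an [outline].
#' @export
efa_reconstruct <- function(desc, k = desc$n_harmonics, n_points = NULL) {
  stopifnot(inherits(desc, "efa"))
  if (k < 1 || k > desc$n_harmonics)
    stop_cocoon("efa_reconstruct: k out of range 1..", desc$n_harmonics,
                class = "parameter_error")
  tn <- if (is.null(n_points)) desc$t_norm else (seq_len(n_points) - 1) / n_points
  harm <- seq_len(k)
  ph <- 2 * pi * outer(tn, harm)
  co <- cos(ph); si <- sin(ph)
  cf <- desc$coefficients
  x <- desc$dc["A0"] + co %*% cf[harm, "a"] + si %*% cf[harm, "b"]
  y <- desc$dc["C0"] + co %*% cf[harm, "c"] + si %*% cf[harm, "d"]
  out <- outline(cbind(x, y))
  attr(out, "t_norm") <- tn
  out
}

#' Harmonic truncation order at a cumulative power fraction
#'
#' Returns the smallest k such that the mean (over descriptors) cumulative
#' power through harmonic k reaches `fraction` of the mean total power. The
#' default keeps 99.999% of the average total power, the operating rule of
#' the shape station.
#'
#' @param descriptors list of `efa` descriptors sharing the same harmonic
#'   count.
#' @param fraction cumulative power fraction (default 0.99999).
#' @return integer k.
#' @export
truncation_order <- function(descriptors, fraction = 0.99999) {
  if (length(descriptors) == 0)
    stop_cocoon("truncation_order: empty descriptor list",
                class = "parameter_error")
  ns <- vapply(descriptors, function(d) d$n_harmonics, numeric(1))
  if (length(unique(ns)) != 1)
    stop_cocoon("truncation_order: descriptors must share n_harmonics",
                class = "parameter_error")
  pw <- vapply(descriptors, function(d) d$harmonic_power, numeric(ns[1]))
  pw <- matrix(pw, nrow = ns[1])
  mean_power <- rowMeans(pw)
  total <- sum(mean_power)
  cum <- cumsum(mean_power)
  k <- which(cum >= fraction * total * (1 - 1e-12))[1]
  if (is.na(k)) k <- as.integer(ns[1])
  as.integer(k)
}

#' Export elliptic Fourier coefficients to CSV
#'
#' One row per cocoon: id followed by the 4n coefficients (a1, b1, c1, d1,
#' a2, ...), the interchange format feeding the shape classifier.
#'
#' @param descriptors named list of `efa` descriptors.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_efa_csv <- function(descriptors, path) {
  rows <- lapply(descriptors, function(d) coef(d))
  df <- data.frame(id = names(descriptors) %||% seq_along(descriptors),
                   do.call(rbind, rows), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
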