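# Shared fixtures, all generated in code.

# Filled disc mask of given radius centered in a square mask.
fixture_disc_mask <- function(radius = 50, size = 2 * radius + 101) {
  ctr <- (size + 1) / 2
  rr <- matrix(rep(seq_len(size), size), size)
  cc <- matrix(rep(seq_len(size), each = size), size)
  binary_mask((rr - ctr)^2 + (cc - ctr)^2 <= radius^2)
}

# Axis-aligned filled ellipse mask (semi-axes a along x, b along y).
fixture_ellipse_mask <- function(a = 70, b = 40, size = 2 * max(a, b) + 61) {
  ctr <- (size + 1) / 2
  rr <- matrix(rep(seq_len(size), size), size)
  cc <- matrix(rep(seq_len(size), each = size), size)
  binary_mask(((cc - ctr) / a)^2 + ((rr - ctr) / b)^2 <= 1)
}

# Band-limited outline (180 points) drawn from random low harmonics around
# an ovoid, returned with the generating descriptor.
fixture_bandlimited <- function(seed, n_harm = 8, n_points = 180) {
  set.seed(seed)
  cf <- matrix(0, n_harm, 4)
  cf[1, ] <- c(stats::runif(1, 45, 60), 0, 0, stats::runif(1, 32, 42))
  for (h in 2:n_harm) cf[h, ] <- stats::rnorm(4, 0, 3 / h^2)
  d <- efa_from_coefficients(cf, dc = c(100, 90), n_points = n_points)
  list(desc = d, outline = efa_reconstruct(d, n_points = n_points))
}

# Independent exhaustive Otsu oracle: naive loop over all 255 cuts.
brute_otsu <- function(v) {
  best <- -1; bt <- NA
  for (t in 0:254) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    s <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (s > best) { best <- s; bt <- t }
  }
  bt
}

rotate_pts <- function(p, ang) {
  p %*% matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
}

# Simple two-class Gaussian features for classifier tests.
fixture_gaussian_classes <- function(n_per_class, p, shift, seed) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = shift), ncol = p))
  list(x = x, labels = factor(rep(c("neg", "pos"), each = n_per_class),
                              levels = c("neg", "pos")))
}
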