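test_that("radial digitizer recovers disc and ellipse geometry", {
  dd <- digitize_outline(fixture_disc_mask(50))
  expect_equal(nrow(dd$points), 180)
  radii <- sqrt(rowSums(sweep(dd$points, 2, dd$centroid)^2))
  expect_true(all(abs(radii - 50) <= 0.5))
  a <- 70; b <- 40
  de <- digitize_outline(fixture_ellipse_mask(a, b))
  th <- (0:179) * 2 * pi / 180
  truth <- a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
  rad <- sqrt(rowSums(sweep(de$points, 2, de$centroid)^2))
  expect_true(all(abs(rad - truth) <= 1))
  expect_equal(nrow(digitize_outline(fixture_disc_mask(30), n_points = 90)$points), 90)
  expect_error(digitize_outline(binary_mask(matrix(FALSE, 5, 5))),
               class = "no_object")
})

test_that("digitizer rejects a centroid outside the region", {
  # thin crescent-like ring: centroid of the foreground falls in the hole
  m <- fixture_disc_mask(40)
  inner <- fixture_disc_mask(34, size = nrow(m))
  ring <- binary_mask(unclass(m) & !unclass(inner))
  expect_error(digitize_outline(ring), class = "digitization_error")
})

test_that("generalized Procrustes alignment removes similarity transforms", {
  o <- fixture_bandlimited(1)$outline$points
  moved <- sweep(rotate_pts(o, pi / 6), 2, c(30, -10), "+")
  scaled <- rotate_pts(o, -0.4) * 2
  al <- procrustes_align(list(o, moved, scaled))
  expect_lt(procrustes_distance(al$outlines[[1]], al$outlines[[2]]), 1e-6)
  expect_lt(procrustes_distance(al$outlines[[1]], al$outlines[[3]]), 1e-6)
  expect_lt(max(abs(colMeans(al$mean_shape))), 1e-9)
  expect_lt(al$residual_ss, 1e-12)
})

test_that("GPA is idempotent and rejects degenerate outlines", {
  set.seed(4)
  outls <- lapply(1:6, function(i) fixture_bandlimited(i)$outline)
  al <- procrustes_align(outls)
  al2 <- procrustes_align(al$outlines)
  expect_lt(abs(al2$residual_ss - al$residual_ss), 1e-8 * max(al$residual_ss, 1e-12))
  degenerate <- matrix(5, 180, 2)  # zero spread
  expect_error(procrustes_align(list(outls[[1]], degenerate)),
               class = "alignment_error")
  expect_error(procrustes_align(list(outls[[1]])), class = "alignment_error")
})

test_that("elliptic Fourier decomposition satisfies its spectral contracts", {
  fx <- fixture_bandlimited(2)
  d <- efa_decompose(fx$outline, 90)
  expect_equal(length(coef(d)), 4 * 90)        # 4n coefficients
  expect_true(all(d$harmonic_power >= 0))
  # full-Nyquist reconstruction reproduces the points
  r <- efa_reconstruct(d, 90)
  expect_lt(sqrt(mean((r$points - fx$outline$points)^2)), 1e-3)
  # a pure ellipse concentrates all power in harmonic 1
  ell <- efa_reconstruct(efa_from_coefficients(
    matrix(c(55, 0, 0, 40), 1, 4, byrow = TRUE)), n_points = 180)
  dell <- efa_decompose(ell, 90)
  expect_gt(dell$harmonic_power[1] / sum(dell$harmonic_power), 0.9999)
  expect_error(efa_decompose(fx$outline, 91), class = "parameter_error")
})

test_that("harmonic power is conserved and rotation-equivariant", {
  for (seed in 1:5) {
    fx <- fixture_bandlimited(seed)
    pts <- fx$outline$points
    d <- efa_decompose(pts, 90)
    sigpow <- mean((pts[, 1] - mean(pts[, 1]))^2 + (pts[, 2] - mean(pts[, 2]))^2)
    expect_lt(abs(sum(d$harmonic_power) - sigpow) / sigpow, 1e-9)
    drot <- efa_decompose(rotate_pts(pts, 0.7), 90)
    expect_lt(max(abs(drot$harmonic_power - d$harmonic_power)) /
                max(d$harmonic_power), 1e-9)
    expect_gt(max(abs(drot$coefficients - d$coefficients)), 1e-3)  # coefs move
  }
})

test_that("decompose and reconstruct are mutually inverse on band-limited shapes", {
  for (seed in 1:5) {
    fx <- fixture_bandlimited(seed)
    d8 <- efa_decompose(fx$outline, 8)
    expect_lt(max(abs(d8$coefficients - fx$desc$coefficients)), 1e-6)
    expect_lt(max(abs(d8$dc - fx$desc$dc)), 1e-6)
  }
})

test_that("efa_reconstruct handles truncation and degenerate descriptors", {
  fx <- fixture_bandlimited(3)
  d <- efa_decompose(fx$outline, 90)
  # one harmonic reconstructs an ellipse: the 5 d.o.f. conic through it fits
  r1 <- efa_reconstruct(d, 1, n_points = 120)
  P <- r1$points
  X <- cbind(P[, 1]^2, P[, 1] * P[, 2], P[, 2]^2, P[, 1], P[, 2], 1)
  sv <- svd(X)
  expect_lt(tail(sv$d, 1) / sv$d[1], 1e-6)
  expect_error(efa_reconstruct(d, 0), class = "parameter_error")
  expect_error(efa_reconstruct(d, 91), class = "parameter_error")
  # all-zero harmonics: constant point at the DC offset
  dz <- efa_from_coefficients(matrix(0, 2, 4), dc = c(12, -7))
  rz <- efa_reconstruct(dz, 2, n_points = 16)
  expect_true(all(abs(rz$points[, 1] - 12) < 1e-12))
  expect_true(all(abs(rz$points[, 2] + 7) < 1e-12))
})

test_that("truncation order implements the cumulative-power rule", {
  ells <- lapply(1:4, function(i) {
    e <- efa_reconstruct(efa_from_coefficients(
      matrix(c(40 + i, 2, -3, 30 + i), 1, 4, byrow = TRUE)), n_points = 180)
    efa_decompose(e, 90)
  })
  expect_identical(truncation_order(ells), 1L)  # pure ellipses
  noisy <- lapply(1:4, function(i) efa_decompose(fixture_bandlimited(i)$outline, 8))
  expect_identical(truncation_order(noisy, fraction = 1.0), 8L)
  k <- truncation_order(noisy)
  expect_true(k >= 1 && k <= 8)
  expect_error(truncation_order(list()), class = "parameter_error")
})

test_that("chord-parameterized decomposition remains available and consistent", {
  fx <- fixture_bandlimited(6)
  du <- efa_decompose(fx$outline, 8)
  dc <- efa_decompose(fx$outline, 8, method = "chord")
  # the two conventions agree to a few percent for near-uniform chords
  expect_lt(max(abs(du$coefficients - dc$coefficients)) /
              max(abs(du$coefficients)), 0.05)
  expect_equal(dc$method, "chord")
  expect_error(efa_decompose(rbind(fx$outline$points, fx$outline$points[180, ]),
                             8, method = "chord"),
               class = "invalid_outline")
})

test_that("coefficient export writes one row of 4n coefficients per cocoon", {
  descs <- list(c1 = efa_decompose(fixture_bandlimited(1)$outline, 6),
                c2 = efa_decompose(fixture_bandlimited(2)$outline, 6))
  p <- file.path(tempdir(), "efa.csv")
  write_efa_csv(descs, p)
  df <- utils::read.csv(p, check.names = FALSE)
  expect_equal(dim(df), c(2, 1 + 24))
  expect_equal(df$id, c("c1", "c2"))
  expect_equal(as.numeric(df[1, -1]), unname(coef(descs$c1)))
})
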