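test_that("rgb_to_hsb handles primary, achromatic and black pixels", {
  px <- function(r, g, b) rgb_image(array(c(r, g, b), dim = c(1, 1, 3)))
  red <- rgb_to_hsb(px(255, 0, 0))
  expect_equal(as.numeric(red[1, 1, ]), c(0, 255, 255))
  gray <- rgb_to_hsb(px(128, 128, 128))
  expect_equal(as.numeric(gray[1, 1, 2:3]), c(0, 128))
  black <- rgb_to_hsb(px(0, 0, 0))
  expect_equal(as.numeric(black[1, 1, 3]), 0)
})

test_that("rgb_to_hsb matches the hexcone reference and round-trips", {
  set.seed(11)
  n <- 2000
  rgbm <- matrix(sample(0:255, 3 * n, replace = TRUE), nrow = 3)
  img <- rgb_image(array(t(rgbm), dim = c(n, 1, 3)))
  hsb <- rgb_to_hsb(img)
  ref <- grDevices::rgb2hsv(rgbm, maxColorValue = 255) * 255
  expect_lt(max(abs(hsb[, , 1] - ref[1, ])), 1e-9)
  expect_lt(max(abs(hsb[, , 2] - ref[2, ])), 1e-9)
  expect_lt(max(abs(hsb[, , 3] - ref[3, ])), 1e-9)
  # inverse conversion within one quantization step per channel
  back <- hsb_to_rgb(hsb)
  expect_lte(max(abs(as.integer(back) - as.integer(img))), 1)
})

test_that("edge_map applies the weighted log map and normalizes to 255", {
  mk <- function(h, s, b, nr = 3, nc = 3) {
    a <- array(0, dim = c(nr, nc, 3))
    a[, , 1] <- h; a[, , 2] <- s; a[, , 3] <- b
    hsb_image(a)
  }
  em <- edge_map(mk(100, 100, 100), eps = 1e-6)
  expect_equal(em$values[1, 1], log(0.2989 * 100 + 0.587 * 100 + 0.114 * 100 + 1e-6))
  expect_equal(em$values[1, 1], log(99.99 + 1e-6))
  # constant non-zero image: normalized map saturates and is degenerate
  expect_true(all(em$normalized8 == 255L))
  expect_true(em$degenerate)
  # zero image: epsilon floors the log at its minimum
  em0 <- edge_map(mk(0, 0, 0), eps = 1e-6)
  expect_equal(min(em0$values), log(1e-6))
  expect_true(em0$degenerate)
  expect_error(otsu_binarize(em0), class = "degenerate_image")
  # a two-region map keeps its layout through normalization
  a <- array(0, dim = c(4, 4, 3)); a[1:2, , 3] <- 200; a[3:4, , 3] <- 20
  em2 <- edge_map(hsb_image(a))
  expect_equal(max(em2$normalized8), 255L)
  expect_false(em2$degenerate)
})

test_that("otsu threshold maximizes between-class variance and binarizes", {
  # perfectly bimodal image reproduces the two-level layout
  n8 <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  em <- structure(list(values = matrix(0, 4, 4), normalized8 = n8,
                       degenerate = FALSE), class = "edge_map")
  mask <- otsu_binarize(em, polarity = "above")
  expect_equal(unclass(mask), n8 > 0, ignore_attr = TRUE)
  # random images agree with the exhaustive-search oracle
  set.seed(7)
  for (i in 1:25) {
    v <- sample(0:255, 256, replace = TRUE)
    expect_identical(otsu_threshold(v), brute_otsu(v))
  }
  expect_error(otsu_threshold(rep(7L, 100)), class = "degenerate_image")
})

test_that("edge-map scale shifts are additive and do not change the verdict", {
  a <- array(0, dim = c(20, 20, 3))
  a[, , 3] <- 20; a[6:15, 6:15, 3] <- 200  # bright square on dark field
  h1 <- hsb_image(a)
  h2 <- hsb_image(a * 1.2)  # c > 1, still within range
  e1 <- edge_map(h1); e2 <- edge_map(h2)
  # pre-normalization difference is a constant (log c), up to the eps guard
  d <- e2$values - e1$values
  expect_lt(diff(range(d)), 1e-6)
  m1 <- otsu_binarize(e1, polarity = "auto")
  m2 <- otsu_binarize(e2, polarity = "auto")
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
})

test_that("select_cocoon_region keeps the dominant object and fills holes", {
  m <- matrix(FALSE, 40, 60)
  m[5:29, 5:24] <- TRUE      # 500 px blob
  m[35:39, 50:53] <- TRUE    # 20 px blob
  m[15, 15] <- FALSE         # interior hole
  sel <- select_cocoon_region(binary_mask(m))
  expect_equal(sum(sel), 25 * 20)          # big blob, hole filled
  expect_true(sel[15, 15])
  expect_false(any(sel[35:39, 50:53]))
  expect_error(select_cocoon_region(binary_mask(matrix(FALSE, 5, 5))),
               class = "no_object")
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal chain
  m[6, 6] <- TRUE                                    # separate
  lab <- label_components(binary_mask(m))
  expect_equal(attr(lab, "n"), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[6, 6] != lab[1, 1])
})

test_that("size gate counts pixels and applies strict bounds", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  thr <- size_thresholds()  # 81,900 / 124,500
  g <- measure_and_gate_size(binary_mask(sq), thr)
  expect_equal(g$area_px2, 100L)
  expect_equal(g$verdict, "undersized")
  big <- binary_mask(matrix(TRUE, 400, 325))      # 130,000 px2
  expect_equal(measure_and_gate_size(big, thr)$verdict, "oversized")
  ok <- binary_mask(matrix(TRUE, 400, 250))       # 100,000 px2
  expect_equal(measure_and_gate_size(ok, thr)$verdict, "ok")
  # boundary values are rejected (strict inequalities)
  at_min <- binary_mask(matrix(TRUE, 300, 273))   # 81,900 px2
  expect_equal(measure_and_gate_size(at_min, thr)$verdict, "undersized")
  at_max <- binary_mask(matrix(TRUE, 300, 415))   # 124,500 px2
  expect_equal(measure_and_gate_size(at_max, thr)$verdict, "oversized")
  expect_error(measure_and_gate_size(binary_mask(matrix(FALSE, 3, 3)), thr),
               class = "no_object")
  expect_error(size_thresholds(100, 100), "min_px2 < max_px2")
})

test_that("size verdict is monotone under mask dilation", {
  thr <- size_thresholds(min_px2 = 50, max_px2 = 200, px2_per_mm2 = NULL)
  rank_of <- c(undersized = 1, ok = 2, oversized = 3)
  m <- matrix(FALSE, 40, 40); m[15:20, 15:20] <- TRUE
  prev <- 0
  for (grow in 0:6) {
    mm <- matrix(FALSE, 40, 40)
    mm[(15 - grow):(20 + grow), (15 - grow):(20 + grow)] <- TRUE
    v <- measure_and_gate_size(binary_mask(mm), thr)$verdict
    expect_gte(rank_of[[v]], prev)
    prev <- rank_of[[v]]
  }
})

test_that("BMP writer and reader round-trip and PNG fixtures load", {
  set.seed(3)
  img <- rgb_image(array(sample(0:255, 31 * 17 * 3, replace = TRUE),
                         dim = c(17, 31, 3)))  # odd width exercises padding
  p <- file.path(tempdir(), "rt.bmp")
  write_bmp(img, p)
  back <- read_bmp(p)
  expect_identical(unclass(back), unclass(img))
  pp <- file.path(tempdir(), "rt.png")
  png::writePNG(array(as.numeric(img) / 255, dim = dim(img)), pp)
  frompng <- read_image(pp)
  expect_identical(unclass(frompng), unclass(img))
  expect_error(read_image(file.path(tempdir(), "nope.tif")),
               class = "format_error")
})
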