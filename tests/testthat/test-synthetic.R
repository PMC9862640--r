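test_that("rendered silhouettes match their analytic specification", {
  for (seed in c(2, 5)) {
    cls <- if (seed %% 2 == 0) "well" else "bad"
    cf <- random_cocoon_coefficients(cls, seed = seed)
    r <- render_cocoon(cocoon_spec(cf, scale_px = 50, seed = seed,
                                   pose = list(rotation = 0.2,
                                               translation = c(4, -3))))
    expect_lt(abs(r$truth$area_px2 - r$truth$analytic_area_px2) /
                r$truth$analytic_area_px2, 0.02)
  }
  # a pure harmonic-1 silhouette is an ellipse: the rendered, segmented and
  # digitized outline reproduces the polar ellipse geometry to sub-pixel
  # accuracy, and its spectrum is dominated by harmonic 1 (the remainder is
  # the equal-angle re-parameterization of an eccentric ellipse, not noise)
  cf1 <- matrix(c(48, 0, 0, 31), 1, 4, byrow = TRUE)
  r <- render_cocoon(cocoon_spec(cf1, scale_px = 1, seed = 1,
                                 width = 140, height = 100))
  seg <- segment_cocoon(r$image)
  o <- digitize_outline(seg)
  rad <- sqrt(rowSums(sweep(o$points, 2, o$centroid)^2))
  th <- (0:179) * 2 * pi / 180
  polar <- 48 * 31 / sqrt(31^2 * cos(th)^2 + 48^2 * sin(th)^2)
  expect_lt(max(abs(rad - polar)), 1)
  d <- efa_decompose(o, 90)
  expect_gt(d$harmonic_power[1] / sum(d$harmonic_power), 0.97)
})

test_that("planted stains render at the requested area and drive the verdict", {
  cf <- random_cocoon_coefficients("well", seed = 12)
  mk <- function(area) render_cocoon(cocoon_spec(
    cf, scale_px = 52,
    stains = list(list(center = c(3, 2), area_px2 = area, hsb = c(20, 180, 200))),
    seed = 3))
  r150 <- mk(150)
  expect_lt(abs(r150$truth$stains$rendered_area_px2 - 150) / 150, 0.05)
  v <- check_stains(r150$image, stain_profile("top"))
  expect_equal(v$stained, r150$truth$stains$rendered_area_px2 > 144)
  r400 <- mk(400)
  expect_lt(abs(r400$truth$stains$rendered_area_px2 - 400) / 400, 0.05)
  expect_true(check_stains(r400$image, stain_profile("top"))$stained)
  # stain centered off the silhouette is a specification error
  expect_error(render_cocoon(cocoon_spec(
    cf, scale_px = 52,
    stains = list(list(center = c(150, 0), area_px2 = 100, hsb = c(20, 180, 200))),
    seed = 3)), class = "spec_error")
})

test_that("rendering is deterministic under a fixed seed", {
  cf <- random_cocoon_coefficients("bad", seed = 4)
  spec <- cocoon_spec(cf, scale_px = 48, noise_sd = 6, seed = 77)
  r1 <- render_cocoon(spec)
  r2 <- render_cocoon(spec)
  expect_identical(unclass(r1$image), unclass(r2$image))
  r3 <- render_cocoon(cocoon_spec(cf, scale_px = 48, noise_sd = 6, seed = 78))
  expect_false(identical(unclass(r1$image), unclass(r3$image)))
})

test_that("synthetic sensor frames respect the ADC range and the planted shift", {
  fr <- render_sensor_frames(sensor_spec("dead", means = 1000, sd = 80,
                                         separation = 3, seed = 9), 50)
  counts <- unlist(lapply(fr, function(f) as.vector(f$values)))
  expect_true(all(counts >= 0 & counts <= 1023))       # clipping contract
  # class-mean difference recovers the separation parameter
  n <- 4000
  a <- render_sensor_frames(sensor_spec("alive", means = 480, sd = 60,
                                        separation = 2, seed = 10), n)
  d <- render_sensor_frames(sensor_spec("dead", means = 480, sd = 60,
                                        separation = 2, seed = 11), n)
  shift <- mean(vapply(d, function(f) mean(f$values), numeric(1))) -
           mean(vapply(a, function(f) mean(f$values), numeric(1)))
  expect_lt(abs(shift / 60 - 2) / 2, 0.1)
  # separation 0: equal distributions
  d0 <- render_sensor_frames(sensor_spec("dead", separation = 0, seed = 12), n)
  a0 <- render_sensor_frames(sensor_spec("alive", separation = 0, seed = 13), n)
  shift0 <- mean(vapply(d0, function(f) mean(f$values), numeric(1))) -
            mean(vapply(a0, function(f) mean(f$values), numeric(1)))
  expect_lt(abs(shift0), 3)
})

test_that("benchmark sets have a complete, self-consistent layout", {
  dir <- file.path(tempdir(), "bench_small")
  unlink(dir, recursive = TRUE)
  mani <- make_benchmark_set(dir, n_per_category = 2, seed = 19)
  expect_equal(nrow(mani), 12)                        # 6 categories x 2
  expect_equal(sort(unique(mani$category)), 1:6)
  cams <- c("camera1-shape", "camera2-top", "camera3-bottom")
  for (cam in cams) {
    files <- list.files(file.path(dir, cam))
    expect_length(files, 12)
    expect_true(all(grepl(sprintf("^[0-9]{14}_%s_[0-9]{6}\\.bmp$", cam), files)))
  }
  # every generator output passes the corresponding reader's validation
  img <- read_image(file.path(dir, mani$shape_file[1]))
  expect_s3_class(img, "rgb_image")
  frames <- read_sensor_csv(file.path(dir, "sensor", "frames.csv"))
  expect_length(frames, 12)
  expect_identical(vapply(frames, function(f) f$cocoon_id, integer(1)), mani$id)
  cfg <- load_config(file.path(dir, "config.yaml"))
  expect_equal(cfg$size$min_px2, round(81900 * 0.25^2))
  # manifest truth agrees with what was rendered: re-measure one stained top
  # view with the dataset's own scaled stain profile
  st <- which(mani$true_stain_top)[1]
  if (!is.na(st)) {
    prof <- stain_profile("top", min_object_area_px2 = cfg$stain$min_area_px2)
    v <- check_stains(read_image(file.path(dir, mani$top_file[st])), prof)
    expect_true(v$stained)
  }
  # regenerating with the same seed reproduces the manifest exactly
  dir2 <- file.path(tempdir(), "bench_small2")
  unlink(dir2, recursive = TRUE)
  mani2 <- make_benchmark_set(dir2, n_per_category = 2, seed = 19)
  expect_identical(mani, mani2)
})
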