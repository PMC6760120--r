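test_that("the drop circle fit is subpixel-accurate and fails cleanly", {
  d <- morpho_droplet()
  spec <- morpho_spec(noise_sd = 0)
  pitch <- spec$pixel_pitch
  img <- render_morphology_frame(d, spec)
  geom <- fit_drop(img, pitch = pitch)
  expect_lt(abs(geom$center_px[1] - 180 / pitch), 0.2)
  expect_lt(abs(geom$center_px[2] - 180 / pitch), 0.2)
  expect_lt(abs(geom$radius_px - 75 / pitch), 0.2)

  # SNR ~ 10 on the drop contrast: radius still within 1 px
  noisy <- render_morphology_frame(d, morpho_spec(noise_sd = 8.4))
  geom_n <- fit_drop(noisy, pitch = pitch)
  expect_lt(abs(geom_n$radius_px - 75 / pitch), 1)
  expect_gt(geom_n$residual_px, 0)     # residual reported, not discarded

  # blank frame: detection error
  set.seed(2)
  blank <- matrix(120 + rnorm(256^2, sd = 5), 256, 256)
  expect_error(fit_drop(blank), "no circular structure")
})

test_that("a uniform annulus is measured at its true thickness in every bin", {
  d <- morpho_droplet()
  spec <- morpho_spec(noise_sd = 0)
  pitch <- spec$pixel_pitch
  img <- render_morphology_frame(d, spec, film = list(kind = "annulus",
                                                      thickness = 4))
  geom <- fit_drop(img, pitch = pitch)
  fp <- film_profile(img, geom, bins = 72, pitch = pitch)
  expect_equal(nrow(fp), 72)
  expect_true(all(abs(fp$thickness_um - 4) <= pitch))

  # clean drop, no aggregate: all bins zero
  img0 <- render_morphology_frame(d, spec)
  fp0 <- film_profile(img0, fit_drop(img0, pitch = pitch), pitch = pitch)
  expect_true(all(fp0$thickness_um == 0))
})

test_that("crescent films peak at +/-45 degrees from the stagnation point", {
  d <- morpho_droplet()
  spec <- morpho_spec(noise_sd = 0)
  pitch <- spec$pixel_pitch
  img <- render_morphology_frame(
    d, spec, film = list(kind = "crescent", centers_deg = c(-45, 45),
                         peak_um = 50, width_deg = 15))
  geom <- fit_drop(img, pitch = pitch)
  fp <- film_profile(img, geom, bins = 72, pitch = pitch)
  binw <- 360 / 72
  pos <- fp[fp$angle_deg > 0, ]; neg <- fp[fp$angle_deg < 0, ]
  expect_lte(abs(pos$angle_deg[which.max(pos$thickness_um)] - 45), binw)
  expect_lte(abs(neg$angle_deg[which.max(neg$thickness_um)] + 45), binw)
  expect_equal(max(fp$thickness_um), 50, tolerance = 0.1)
})

test_that("film measurement co-rotates with the declared flow axis", {
  d <- morpho_droplet()
  spec <- morpho_spec(noise_sd = 0)
  pitch <- spec$pixel_pitch
  ang <- 30 * pi / 180
  dir <- c(cos(ang), sin(ang))
  img <- render_morphology_frame(
    d, spec, film = list(kind = "crescent", centers_deg = c(-45, 45),
                         peak_um = 30, width_deg = 15), flow_dir = dir)
  geom <- fit_drop(img, pitch = pitch)
  fp <- film_profile(img, geom, bins = 72, pitch = pitch, flow_dir = dir)
  binw <- 360 / 72
  pos <- fp[fp$angle_deg > 0, ]
  expect_lte(abs(pos$angle_deg[which.max(pos$thickness_um)] - 45), binw)
})

test_that("streamer tails are measured in drop diameters and classified", {
  # small drop so a 12-diameter tail fits in the field of view
  d <- droplet_spec(40, c(80, 180))
  spec <- render_spec(fov = c(720, 360), sensor = c(1024, 512), noise_sd = 0)
  pitch <- spec$pixel_pitch
  img <- render_morphology_frame(d, spec, tail = list(length_dd = 12,
                                                      width_um = 10))
  geom <- fit_drop(img, pitch = pitch)
  tm <- tail_metric(img, geom, pitch = pitch)
  expect_equal(tm$length_dd, 12, tolerance = 0.05)
  expect_equal(tm$classification, "> 10 drop diameters")

  # no tail: zero length
  img0 <- render_morphology_frame(d, spec)
  tm0 <- tail_metric(img0, fit_drop(img0, pitch = pitch), pitch = pitch)
  expect_equal(tm0$length_um, 0)

  # rotation covariance with the declared axis
  dd <- droplet_spec(40, c(120, 120))
  spec2 <- render_spec(fov = c(720, 720), sensor = c(1024, 1024), noise_sd = 0)
  angd <- 35 * pi / 180
  dird <- c(cos(angd), sin(angd))
  img_r <- render_morphology_frame(dd, spec2, tail = list(length_dd = 12,
                                                          width_um = 10),
                                   flow_dir = dird)
  geom_r <- fit_drop(img_r, pitch = spec2$pixel_pitch)
  tm_r <- tail_metric(img_r, geom_r, flow_dir = dird, pitch = spec2$pixel_pitch)
  expect_equal(tm_r$length_dd, 12, tolerance = 0.05)
})

test_that("metrics are invariant to affine intensity transforms", {
  d <- morpho_droplet()
  spec <- morpho_spec(noise_sd = 3, seed = 5)
  pitch <- spec$pixel_pitch
  img <- render_morphology_frame(d, spec, film = list(kind = "annulus",
                                                      thickness = 6))
  geom <- fit_drop(img, pitch = pitch)
  m1 <- aggregate_mask(img, geom)
  m2 <- aggregate_mask(1.7 * img + 40, geom)
  expect_identical(m1, m2)
})

test_that("time-lapse processing is per-frame robust and trend-sensitive", {
  d <- morpho_droplet()
  spec <- morpho_spec(noise_sd = 0)
  frames <- lapply(c(4, 8, 12), function(t)
    render_morphology_frame(d, spec, film = list(kind = "annulus",
                                                 thickness = t)))
  seq1 <- image_sequence(frames, spec$pixel_pitch, 30, "timelapse")
  ts <- drop_timeseries(seq1)
  expect_true(all(ts$ok))
  expect_true(all(diff(ts$film_mean_um) > 0))    # growing film detected
  expect_lt(max(abs(ts$radius_um - 75)), 1)

  # constant sequence: constant metrics
  seq2 <- image_sequence(rep(frames[1], 3), spec$pixel_pitch, 30, "timelapse")
  ts2 <- drop_timeseries(seq2)
  expect_equal(ts2$film_mean_um, rep(ts2$film_mean_um[1], 3))

  # one corrupt frame: flagged, the rest intact
  set.seed(4)
  bad <- matrix(120 + rnorm(512^2, sd = 5), 512, 512)
  seq3 <- image_sequence(list(frames[[1]], bad, frames[[3]]),
                         spec$pixel_pitch, 30, "timelapse")
  ts3 <- drop_timeseries(seq3)
  expect_equal(ts3$ok, c(TRUE, FALSE, TRUE))
  expect_match(ts3$note[2], "no circular structure")
})
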