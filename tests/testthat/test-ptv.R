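test_that("detection recovers rendered blobs to 0.1 px and respects thresholds", {
  set.seed(21)
  n <- 256
  x <- runif(10, 20, n - 20); y <- runif(10, 20, n - 20)
  img <- 100 + microptv:::stamp_blobs_cpp(n, n, x, y, rep(1, 10), rep(800, 10))

  ps <- detect_particles(img, detect_config())
  expect_equal(nrow(ps), 10)
  d <- sqrt(outer(ps$x_px, x, `-`)^2 + outer(ps$y_px, y, `-`)^2)
  expect_lt(max(apply(d, 2, min)), 0.1)

  # blank frame: empty set, not an error
  expect_equal(nrow(detect_particles(matrix(100, 64, 64), detect_config())), 0)
  # threshold above the peak response: empty set
  hi <- detect_config(threshold = 1e6)
  expect_equal(nrow(detect_particles(img, hi)), 0)
})

test_that("predictor-assisted matching is exact, one-to-one, and unswapped", {
  pred <- uniform_predictor(256, dx = 8, dy = 0)
  pa <- structure(data.frame(x_px = 50, y_px = 50, intensity = 1, size = 1),
                  class = c("particle_set", "data.frame"))
  pb <- structure(data.frame(x_px = 58, y_px = 50, intensity = 1, size = 1),
                  class = c("particle_set", "data.frame"))
  m <- match_particles(pa, pb, pred, radius = 3)
  expect_equal(nrow(m), 1)
  expect_equal(m$residual_px, 0)
  expect_equal(m$dx_px, 8)

  # empty first set: empty result
  empty <- pa[0, ]
  expect_equal(nrow(match_particles(empty, pb, pred, 3)), 0)

  # two particles that nearest-neighbor linking would cross-match:
  # A1 (50,50)->B1 (58,50), A2 (53,50)->B2 (61,50); plain distance pairs
  # A2 with B1 (5 px) before A1 with B1 (8 px)
  pa2 <- structure(data.frame(x_px = c(50, 53), y_px = c(50, 50),
                              intensity = 1, size = 1),
                   class = c("particle_set", "data.frame"))
  pb2 <- structure(data.frame(x_px = c(58, 61), y_px = c(50, 50),
                              intensity = 1, size = 1),
                   class = c("particle_set", "data.frame"))
  naive <- match_particles(pa2, pb2, uniform_predictor(256, 0, 0), radius = 6)
  m2 <- match_particles(pa2, pb2, pred, radius = 3)
  expect_equal(m2$ia, c(1, 2))
  expect_equal(m2$ib, c(1, 2))
  expect_equal(m2$dx_px, c(8, 8))
  # and the unassisted pairing is indeed the crossed one
  expect_true(any(naive$ia != naive$ib))
  # one-to-one: no index reused
  expect_false(any(duplicated(m2$ia)) || any(duplicated(m2$ib)))
})

test_that("a noiseless uniform burst is recovered almost completely", {
  un <- flow_scene(small_droplet(), 2000, "uniform")
  spec <- small_spec(noise_sd = 0, seed = 31)
  # distinctly resolvable tracers: rejection-seeded minimum separation of
  # 4 um (tracers at contact distance merge into a single detection and are
  # exercised by the density/accuracy tests instead)
  set.seed(31)
  pos <- matrix(numeric(0), 0, 2)
  while (nrow(pos) < 40) {
    cand <- c(runif(1, -5, 180), runif(1, 0, 180))
    if (sqrt(sum((cand - c(90, 90))^2)) < 31) next
    if (nrow(pos) == 0 || min(sqrt(colSums((t(pos) - cand)^2))) > 4)
      pos <- rbind(pos, cand)
  }
  b <- make_burst(un, spec, n_frames = 2, ensemble0 = tracer_ensemble(pos))
  vs <- vectors_from_burst(b)
  pitch <- spec$pixel_pitch
  expected_dx <- 2000 / 1000 / pitch

  # count tracers in view, clear of the drop exclusion and of the frame
  # border (truncated spots are discarded by detection), in both frames
  tr <- b$truth
  clear <- function(f) {
    t <- subset(tr, frame == f & in_view)
    r <- sqrt((t$x_um - 90)^2 + (t$y_um - 90)^2)
    inner <- t$x_um > 4 & t$x_um < 176 & t$y_um > 4 & t$y_um < 176
    t$id[r > 30 + 5 & inner]
  }
  N <- length(intersect(clear(1), clear(2)))
  expect_gte(nrow(vs), 0.95 * N)
  expect_lt(max(abs(vs$dx_px - expected_dx)), 0.1)
  expect_lt(max(abs(vs$dy_px)), 0.1)
})

test_that("pooled vector bookkeeping and time-reversal symmetry hold", {
  sc <- small_scene()
  spec <- small_spec(seed = 33)
  b <- make_burst(sc, spec, n_frames = 6, n_per_frame = 80)
  vs <- vectors_from_burst(b)
  n_det <- attr(vs, "n_detected")
  pairs <- length(b$frames) - 1
  expect_lt(abs(nrow(vs) - mean(n_det) * pairs), 0.2 * mean(n_det) * pairs)

  rev_b <- image_sequence(rev(b$frames), b$pixel_pitch, b$frame_interval,
                          "burst", scene = b$scene)
  vr <- vectors_from_burst(rev_b)
  expect_equal(nrow(vr), nrow(vs), tolerance = 0.05)
  expect_equal(mean(vr$u_um_s), -mean(vs$u_um_s), tolerance = 0.02 * 2000)
})

test_that("per-pair recovery and velocity accuracy meet the tracking budget", {
  # desk-scale version of the potential-flow burst (same optics and density)
  sc <- small_scene()
  spec <- small_spec(seed = 35)
  b <- make_burst(sc, spec, n_frames = 8, n_per_frame = 80)
  vs <- vectors_from_burst(b)

  vel <- evaluate_flow(sc, as.matrix(vs[, c("x_um", "y_um")]))
  errpx <- sqrt((vs$u_um_s - vel[, 1])^2 + (vs$v_um_s - vel[, 2])^2) /
    (spec$pixel_pitch * 1000)
  r <- sqrt((vs$x_um - 90)^2 + (vs$y_um - 90)^2)
  annulus <- r <= 30 + 30        # one drop radius beyond the perimeter
  expect_lt(sqrt(mean(errpx[!annulus]^2)), 0.15)
  expect_lt(sqrt(mean(errpx[annulus]^2)), 0.3)
  # wrong matches (link to a different true particle) are rare
  expect_lt(mean(errpx > 1.5), 0.01)
  # one-to-one within every pair
  for (p in unique(vs$pair)) {
    sub <- vs[vs$pair == p, ]
    expect_false(any(duplicated(sub$ia)) || any(duplicated(sub$ib)))
  }
})
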