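test_that("potential flow past the drop has the classical doublet structure", {
  sc <- default_scene()
  a <- 75; cc <- c(360, 360); U <- 2000

  # uniform model is constant everywhere
  un <- default_scene("uniform")
  pts <- rbind(c(10, 10), c(700, 300), c(360, 700))
  expect_equal(evaluate_flow(un, pts),
               cbind(rep(2000, 3), rep(0, 3)), ignore_attr = TRUE)

  # leading stagnation point (r = a, theta = pi)
  expect_lt(sqrt(sum(evaluate_flow(sc, cc + c(-a, 0))^2)), 1e-9 * U)
  # top of the perimeter: doublet maximum, speed 2 U_f
  expect_equal(sqrt(sum(evaluate_flow(sc, cc + c(0, a))^2)), 2 * U,
               tolerance = 1e-12)
  # inside the drop is a domain error naming the point
  expect_error(evaluate_flow(sc, cc + c(10, 0)), "inside the drop")
})

test_that("potential field is divergence-free and satisfies no-penetration", {
  sc <- default_scene()
  a <- 75; U <- 2000; D <- 150
  h <- 0.5
  xs <- seq(100, 620, by = 4); ys <- seq(100, 620, by = 4)
  pts <- expand.grid(x = xs, y = ys)
  r <- sqrt((pts$x - 360)^2 + (pts$y - 360)^2)
  pts <- pts[r > a + 5, ]
  ux1 <- evaluate_flow(sc, cbind(pts$x + h, pts$y))[, 1]
  ux0 <- evaluate_flow(sc, cbind(pts$x - h, pts$y))[, 1]
  vy1 <- evaluate_flow(sc, cbind(pts$x, pts$y + h))[, 2]
  vy0 <- evaluate_flow(sc, cbind(pts$x, pts$y - h))[, 2]
  div <- (ux1 - ux0) / (2 * h) + (vy1 - vy0) / (2 * h)
  expect_lt(max(abs(div)) * D / U, 1e-3)

  th <- seq(0, 2 * pi, length.out = 361)[-361]
  per <- cbind(360 + a * cos(th), 360 + a * sin(th))
  vel <- evaluate_flow(sc, per)
  u_r <- vel[, 1] * cos(th) + vel[, 2] * sin(th)
  expect_lt(max(abs(u_r)), 1e-9 * U)
})

test_that("advection is exact in uniform flow and deterministic without noise", {
  un <- default_scene("uniform")
  e <- tracer_ensemble(rbind(c(10, 10), c(20, 650), c(500, 100)))
  e2 <- advect_tracers(e, un, 1e-3)
  expect_equal(e2$positions - e$positions,
               matrix(rep(c(2, 0), each = 3), 3, 2), ignore_attr = TRUE)

  sc <- default_scene()
  set.seed(1); e3 <- tracer_ensemble(matrix(runif(40, 0, 200), 20, 2))
  a1 <- advect_tracers(e3, sc, 1e-3)
  a2 <- advect_tracers(e3, sc, 1e-3)
  expect_identical(a1$positions, a2$positions)
})

test_that("diffusion reproduces the 2 D t mean-squared displacement", {
  # independent oracle: for pure Brownian steps the per-axis MSD after time t
  # is 2 D t, with standard error sqrt(2/n) * 2 D t for n tracers
  still <- flow_scene(default_droplet(), u_free = 0, model = "uniform")
  D <- 0.5; dt <- 0.01; nsteps <- 20; n <- 2000
  set.seed(7)
  e <- tracer_ensemble(matrix(rep(c(2000, 2000), each = n), n, 2),
                       diffusivity = D)
  p0 <- e$positions
  for (k in seq_len(nsteps)) e <- advect_tracers(e, still, dt)
  t <- nsteps * dt
  msd <- colMeans((e$positions - p0)^2)
  se <- sqrt(2 / n) * 2 * D * t
  expect_lt(abs(msd[1] - 2 * D * t), 3 * se)
  expect_lt(abs(msd[2] - 2 * D * t), 3 * se)
})

test_that("reflection at the perimeter conserves tracer count", {
  sc <- small_scene()
  set.seed(3)
  th <- runif(200, 0, 2 * pi)
  pos <- cbind(90 + (30.2 + runif(200, 0, 1)) * cos(th),
               90 + (30.2 + runif(200, 0, 1)) * sin(th))
  e <- tracer_ensemble(pos)
  e2 <- advect_tracers(e, sc, 2e-3)
  expect_equal(nrow(e2$positions), 200)
  r <- sqrt((e2$positions[, 1] - 90)^2 + (e2$positions[, 2] - 90)^2)
  expect_true(all(r >= 30 - 1e-9))
})

test_that("rendered spots are photometrically faithful", {
  spec <- render_spec(fov = c(90, 90), sensor = c(128, 128), noise_sd = 0)
  # empty ensemble: background plus drop footprint only
  d <- droplet_spec(30, c(45, 45))
  img0 <- render_frame(NULL, spec, d)
  expect_equal(sort(unique(as.vector(img0))),
               c(round(0.05 * 120), round(0.3 * 120), 120))

  # single blob: intensity-weighted centroid within 0.05 px of truth
  e1 <- tracer_ensemble(rbind(c(33.4, 61.7)))
  img1 <- render_frame(e1, spec, droplet = NULL, quantize = FALSE)
  w <- img1 - 120
  xs <- (seq_len(128) - 0.5); tot <- sum(w)
  cx <- sum(colSums(w) * xs) / tot; cy <- sum(rowSums(w) * xs) / tot
  pitch <- spec$pixel_pitch
  expect_lt(abs(cx - 33.4 / pitch), 0.05)
  expect_lt(abs(cy - 61.7 / pitch), 0.05)

  # two disjoint tracers: linear superposition of integrated intensity
  e2 <- tracer_ensemble(rbind(c(20, 20), c(70, 70)))
  img2 <- render_frame(e2, spec, droplet = NULL, quantize = FALSE)
  expect_equal(sum(img2 - 120), 2 * sum(img1 - 120), tolerance = 1e-6)
})

test_that("bursts are seeded deterministically with consistent ground truth", {
  sc <- small_scene()
  spec <- small_spec(seed = 17)
  b1 <- make_burst(sc, spec, n_frames = 3, n_per_frame = 60)
  b2 <- make_burst(sc, spec, n_frames = 3, n_per_frame = 60)
  expect_identical(b1$frames, b2$frames)
  expect_identical(b1$truth, b2$truth)

  # exported truth velocities match the analytic field
  vel <- evaluate_flow(sc, as.matrix(b1$truth[, c("x_um", "y_um")]))
  expect_equal(b1$truth$u_um_s, vel[, 1], tolerance = 1e-9)
  expect_equal(b1$truth$v_um_s, vel[, 2], tolerance = 1e-9)

  # uniform 2-frame burst: constant truth displacement U_f / frame_rate
  un <- flow_scene(small_droplet(), 2000, "uniform")
  bu <- make_burst(un, small_spec(seed = 4), n_frames = 2, frame_rate = 1000,
                   n_per_frame = 40)
  t1 <- subset(bu$truth, frame == 1); t2 <- subset(bu$truth, frame == 2)
  expect_equal(t2$x_um - t1$x_um, rep(2, nrow(t1)), tolerance = 1e-12)
  expect_equal(t2$y_um - t1$y_um, rep(0, nrow(t1)), tolerance = 1e-12)
})
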