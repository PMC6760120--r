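test_that("normalization scales and round trips behave", {
  sc <- normalization_scales(150, 2000, 1e-3, 1000)
  expect_equal(sc$Re, 0.3)
  expect_equal(sc$tau_scale, 1e-3 * 2e-3 / 150e-6)

  scene <- default_scene()
  g <- grid_spec(c(1024, 1024), c(512, 512), 8, 720 / 1024)
  f <- sample_scene_to_grid(scene, g)
  fs <- normalize_field(f, sc)
  # far-upstream column: u* -> 1, v* -> 0
  up <- which(fs$x_star < -2)   # doublet perturbation decays as 1/r*^2
  expect_lt(max(abs(fs$u[, up][fs$valid[, up]] - 1)), 0.07)
  expect_lt(max(abs(fs$v[, up][fs$valid[, up]])), 0.07)
  # round trip
  back <- denormalize_field(fs)
  expect_equal(back$u, f$u, tolerance = 1e-12)
  expect_equal(back$v, f$v, tolerance = 1e-12)
  expect_identical(back$valid, f$valid)
  expect_error(normalization_scales(150, 0), "U_f")
})

test_that("stress maps implement the printed second-derivative formulas", {
  # u* = x*^2 -> tau*_xx = 2 everywhere, tau*_xy = 0
  f1 <- analytic_star_field(\(x, y) x^2, \(x, y) 0 * x)
  s1 <- stress_maps(f1)
  expect_lt(max(abs(s1$tau_xx[s1$valid] - 2)), 1e-10)
  expect_lt(max(abs(s1$tau_xy[s1$valid])), 1e-10)

  # u* = y*^2, v* = x*^2 -> tau*_xy = (2 + 2)/2 = 2
  f2 <- analytic_star_field(\(x, y) y^2, \(x, y) x^2)
  s2 <- stress_maps(f2)
  expect_lt(max(abs(s2$tau_xy[s2$valid] - 2)), 1e-10)
  expect_lt(max(abs(s2$tau_xx[s2$valid])), 1e-10)

  # uniform field: both maps identically zero
  f0 <- analytic_star_field(\(x, y) 1 + 0 * x, \(x, y) 0 * x)
  s0 <- stress_maps(f0)
  expect_lt(max(abs(s0$tau_xx[s0$valid])), 1e-12)
  expect_lt(max(abs(s0$tau_xy[s0$valid])), 1e-12)

  # linearity of the operator
  f3 <- analytic_star_field(\(x, y) x^2 + x * y, \(x, y) y^2)
  f3b <- f3; f3b$u <- 3.5 * f3$u; f3b$v <- 3.5 * f3$v
  s3 <- stress_maps(f3); s3b <- stress_maps(f3b)
  expect_lt(max(abs(s3b$tau_xx - 3.5 * s3$tau_xx), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(s3b$tau_xy - 3.5 * s3$tau_xy), na.rm = TRUE), 1e-10)
})

test_that("stress maps inherit the mirror symmetry of the analytic flow", {
  scene <- default_scene()
  g <- grid_spec(c(1024, 1024), c(512, 512), 8, 720 / 1024)
  fs <- normalize_field(sample_scene_to_grid(scene, g),
                        normalization_scales(150, 2000))
  s <- stress_maps(fs)
  # the grid is anchored at the drop center: rows mirror in y. u* is even and
  # v* odd in y*, so tau*_xx is even; of the cross-term pieces, v*_xx is odd
  # and u*_yy even (second y-derivatives preserve parity).
  ny <- length(fs$y_star)
  flip <- rev(seq_len(ny))
  both <- s$valid & s$valid[flip, ]
  expect_gt(sum(both), 1000)
  expect_lt(max(abs(s$tau_xx - s$tau_xx[flip, ])[both]), 1e-9)
  vxx <- microptv:::grid_deriv(fs$v, fs$valid, fs$h_star, 1, 2)
  uyy <- microptv:::grid_deriv(fs$u, fs$valid, fs$h_star, 2, 2)
  expect_lt(max(abs(vxx + vxx[flip, ])[both], na.rm = TRUE), 1e-9)
  expect_lt(max(abs(uyy - uyy[flip, ])[both], na.rm = TRUE), 1e-9)
})

test_that("the momentum budget closes and matches the Bernoulli oracle", {
  # uniform field: every term vanishes
  f0 <- analytic_star_field(\(x, y) 1 + 0 * x, \(x, y) 0 * x)
  b0 <- momentum_budget(f0, normalization_scales(150, 2000))
  expect_lt(max(abs(b0$inertial[b0$valid])), 1e-12)
  expect_lt(max(abs(b0$viscous[b0$valid])), 1e-12)
  expect_lt(max(abs(b0$dp_dx[b0$valid])), 1e-12)

  scene <- default_scene()
  scales <- normalization_scales(150, 2000)
  g <- grid_spec(c(1024, 1024), c(512, 512), 4, 720 / 1024)
  fs <- normalize_field(sample_scene_to_grid(scene, g), scales)

  # Stokes limit: with Re = 0 the pressure gradient equals the viscous term
  s0 <- normalization_scales(150, 2000, rho_f = 1e-12)
  bs <- momentum_budget(fs, s0)
  expect_lt(max(abs(bs$dp_dx - bs$viscous), na.rm = TRUE), 1e-12)

  # budget identity at every valid node, by construction
  b <- momentum_budget(fs, scales)
  expect_lt(max(abs(b$inertial + b$dp_dx - b$viscous)[b$valid]), 1e-12)

  # closed-form oracle on the upstream stagnation line: for the doublet
  # field u*(x*) = 1 - (1/2)^2 / x*^2 on y* = 0, the Bernoulli pressure
  # gradient is -Re u* du*/dx* with du*/dx* = 0.5 / x*^3 (viscous term of a
  # harmonic field ~ 0)
  iy <- which.min(abs(fs$y_star))
  xs <- fs$x_star
  line <- which(xs <= -0.75 & b$valid[iy, ])
  expect_gt(length(line), 20)
  u_line <- 1 - 0.25 / xs[line]^2
  bern <- -scales$Re * u_line * (0.5 / xs[line]^3)
  expect_lt(max(abs(b$dp_dx[iy, line] - bern) / abs(bern)), 0.10)
})

test_that("Stokes law and optics calibration give the published figures", {
  # closed form: U = d rho g d^2 / (18 mu), reported in mm/s
  expect_equal(stokes_rise_velocity(150, 150, 1e-3, 9.81),
               150 * 9.81 * (150e-6)^2 / (18 * 1e-3) * 1000)
  expect_equal(stokes_rise_velocity(150, 150), 1.84, tolerance = 0.005)
  expect_equal(signif(stokes_rise_velocity(150, 150), 1), 2)
  # d^2 scaling and the small-drop limit
  expect_equal(stokes_rise_velocity(300, 150) / stokes_rise_velocity(150, 150), 4)
  expect_lt(stokes_rise_velocity(0.01, 150), 1e-7)

  expect_equal(pixel_pitch(720, 1024), 0.703125)
  expect_equal(round(pixel_pitch(720, 1024), 1), 0.7)
  expect_equal(pixel_pitch(1024, 1024), 1)
  expect_equal(pixel_pitch(720, 1024) * 1024, 720)
})

test_that("the free-stream estimate is robust to downstream structure", {
  scene <- flow_scene(default_droplet(), 2000, "potential_plus_wake")
  g <- grid_spec(c(1024, 1024), c(512, 512), 8, 720 / 1024)
  f <- sample_scene_to_grid(scene, g)
  expect_equal(estimate_u_free(f), 2000, tolerance = 0.03)
})
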