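# Shared fixture builders. Everything is generated in code at test time; the
# "desk-scale" scene keeps the experiment's areal tracer density and optics
# (0.703 um/px) on a smaller sensor so unit tests stay fast.

default_droplet <- function(center = c(360, 360))
  droplet_spec(150, center)

default_scene <- function(model = "potential_past_circle", u_free = 2000)
  flow_scene(default_droplet(), u_free, model)

# 256 px / 180 um window with a 60 um drop: same pitch as the experiment.
small_droplet <- function() droplet_spec(60, c(90, 90))

small_scene <- function(model = "potential_past_circle", u_free = 2000)
  flow_scene(small_droplet(), u_free, model)

small_spec <- function(noise_sd = 8, seed = 42)
  render_spec(fov = c(180, 180), sensor = c(256, 256), noise_sd = noise_sd,
              seed = seed)

# Plain textured frames (smoothed noise) for PIV kernel tests.
textured_frame <- function(n = 128, seed = 5) {
  set.seed(seed)
  microptv:::gauss_blur_cpp(matrix(rnorm(n * n, 500, 100), n, n), 1.2)
}

# Well-seeded particle-image frame (sharp spots; ~25 per 32 px window at the
# default count) for PIV estimator tests.
blob_frame <- function(n = 256, n_blobs = 1600, seed = 11, shift = c(0, 0),
                       sigma = 0.7) {
  set.seed(seed)
  x <- runif(n_blobs, 5, n - 5); y <- runif(n_blobs, 5, n - 5)
  100 + microptv:::stamp_blobs_cpp(n, n, x + shift[1], y + shift[2],
                                   rep(sigma, n_blobs), rep(800, n_blobs))
}

circ_shift <- function(m, di, dj) {
  n <- nrow(m)
  m[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(ncol(m)) - 1 - dj) %% ncol(m)) + 1]
}

# A hand-built uniform predictor lattice covering an n x n frame.
uniform_predictor <- function(n, dx, dy, step = 16) {
  xs <- seq(step, n - step, by = step)
  nx <- length(xs)
  structure(list(x = xs, y = xs,
                 dx = matrix(dx, nx, nx), dy = matrix(dy, nx, nx),
                 peak_ratio = matrix(10, nx, nx),
                 valid = matrix(TRUE, nx, nx),
                 masked = matrix(FALSE, nx, nx),
                 interpolated = matrix(FALSE, nx, nx),
                 window = 2 * step, step = step),
            class = "piv_field")
}

# Scattered vectors sampling a pair of polynomial component fields.
polynomial_vectors <- function(n, fu, fv, extent = 200, seed = 3) {
  set.seed(seed)
  x <- runif(n, 0, extent); y <- runif(n, 0, extent)
  data.frame(x_px = x, y_px = y, dx_px = fu(x, y), dy_px = fv(x, y))
}

# Dimensionless gridded field built directly from analytic u*(x*,y*), v*.
analytic_star_field <- function(fu, fv, h = 0.05, half = 1) {
  xs <- seq(-half, half, by = h)
  U <- outer(xs, xs, function(yy, xx) fu(xx, yy))
  V <- outer(xs, xs, function(yy, xx) fv(xx, yy))
  structure(list(x_px = xs, y_px = xs, x_um = xs, y_um = xs,
                 u = U, v = V, n = matrix(100L, length(xs), length(xs)),
                 residual = matrix(0, length(xs), length(xs)),
                 valid = matrix(TRUE, length(xs), length(xs)),
                 spacing_px = h, pitch = 1, center_px = c(0, 0),
                 units = "dimensionless", dimensionless = TRUE,
                 x_star = xs, y_star = xs, h_star = h,
                 scales = normalization_scales(150, 2000),
                 n_rank_deficient = 0L, min_count = 1L),
            class = "gridded_field")
}

# Morphology fixture geometry reused across tests.
morpho_droplet <- function() droplet_spec(150, c(180, 180))

morpho_spec <- function(noise_sd = 0, seed = 9)
  render_spec(fov = c(360, 360), sensor = c(512, 512), noise_sd = noise_sd,
              seed = seed)
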