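#' Normalization scales for nondimensional hydrodynamics
#'
#' Lengths are scaled by the drop diameter \eqn{D_d}, velocities by the
#' incoming free-stream speed \eqn{U_f}, and stresses by
#' \eqn{\mu_f U_f / D_d}. The drop-diameter Reynolds number
#' \eqn{Re_{D_d} = \rho_f U_f D_d / \mu_f} weights the inertial term of the
#' normalized momentum balance.
#'
#' @param D_d Drop diameter, um.
#' @param U_f Free-stream speed, um/s.
#' @param mu_f Dynamic viscosity, Pa s.
#' @param rho_f Fluid density, kg/m^3.
#' @return An object of class `normalization_scales` with `Re` and the
#'   stress scale `tau_scale` (Pa).
#' @export
normalization_scales <- function(D_d, U_f, mu_f = 1e-3, rho_f = 1000) {
  stopifnot(D_d > 0, U_f > 0, mu_f > 0, rho_f > 0)
  structure(list(D_d = D_d, U_f = U_f, mu_f = mu_f, rho_f = rho_f,
                 Re = rho_f * (U_f * 1e-6) * (D_d * 1e-6) / mu_f,
                 tau_scale = mu_f * (U_f * 1e-6) / (D_d * 1e-6)),
            class = "normalization_scales")
}

#' Estimate the free-stream speed from a gridded field
#'
#' Median streamwise velocity over the upstream 10% of valid columns; robust
#' to streamers and wake structure downstream.
#'
#' @param field A `gridded_field` in um/s.
#' @return Estimated \eqn{U_f} in um/s.
#' @export
estimate_u_free <- function(field) {
  has <- colSums(field$valid) > 0
  cols <- which(has)
  k <- max(1, ceiling(length(cols) * 0.1))
  sel <- cols[seq_len(k)]
  median(field$u[, sel][field$valid[, sel]], na.rm = TRUE)
}

#' Nondimensionalize a gridded velocity field
#'
#' Coordinates become \eqn{(x - x_c)/D_d} with origin at the drop center;
#' velocities are divided by \eqn{U_f}. The validity mask is preserved.
#'
#' @param field A `gridded_field` with velocities in um/s.
#' @param scales A [normalization_scales()].
#' @return A dimensionless `gridded_field` (adds `x_star`, `y_star`,
#'   `h_star`, and a `scales` element).
#' @export
normalize_field <- function(field, scales) {
  stopifnot(inherits(field, "gridded_field"),
            inherits(scales, "normalization_scales"))
  if (scales$U_f == 0) stop("U_f must be nonzero")
  if (field$dimensionless) stop("field is already dimensionless")
  out <- field
  out$x_star <- (field$x_um - field$center_px[1] * field$pitch) / scales$D_d
  out$y_star <- (field$y_um - field$center_px[2] * field$pitch) / scales$D_d
  out$h_star <- field$spacing_px * field$pitch / scales$D_d
  out$u <- field$u / scales$U_f
  out$v <- field$v / scales$U_f
  out$units <- "dimensionless"
  out$dimensionless <- TRUE
  out$scales <- scales
  out
}

#' @rdname normalize_field
#' @export
denormalize_field <- function(field) {
  stopifnot(field$dimensionless)
  out <- field
  out$u <- field$u * field$scales$U_f
  out$v <- field$v * field$scales$U_f
  out$units <- "um/s"
  out$dimensionless <- FALSE
  out$x_star <- out$y_star <- out$h_star <- out$scales <- NULL
  out
}

# Mask-aware finite differences on a regular grid.
# axis 1: x (columns), axis 2: y (rows). Central 2nd-order stencils where both
# neighbors are valid; 2nd-order one-sided at mask edges; NA elsewhere.
grid_deriv <- function(m, valid, h, axis, order = 1) {
  m[!valid] <- NA
  sh <- function(k) {                  # value at node + k along axis
    if (axis == 1) shift_mat(m, 0, -k) else shift_mat(m, -k, 0)
  }
  fp <- sh(1); fm <- sh(-1)
  if (order == 1) {
    d <- (fp - fm) / (2 * h)
    fpp <- sh(2); fmm <- sh(-2)
    fwd <- (-3 * m + 4 * fp - fpp) / (2 * h)
    bwd <- (3 * m - 4 * fm + fmm) / (2 * h)
  } else {
    d <- (fp - 2 * m + fm) / h^2
    fpp <- sh(2); fmm <- sh(-2); fp3 <- sh(3); fm3 <- sh(-3)
    fwd <- (2 * m - 5 * fp + 4 * fpp - fp3) / h^2
    bwd <- (2 * m - 5 * fm + 4 * fmm - fm3) / h^2
  }
  d[is.na(d)] <- fwd[is.na(d)]
  d[is.na(d)] <- bwd[is.na(d)]
  d[!valid] <- NA
  d
}

#' Normalized viscous-stress maps
#'
#' Computes, from a dimensionless gridded field, the two second-derivative
#' maps of the streamwise viscous force density:
#' \deqn{\tau^*_{xx} = \partial^{*2} u^* / (\partial^* x^*)^2, \qquad
#'       \tau^*_{xy} = [\partial^{*2} u^* / (\partial^* y^*)^2 +
#'                      \partial^{*2} v^* / (\partial^* x^*)^2] / 2.}
#' (These quantities are labeled normal and shear "stresses" in the
#' measurement convention this package follows; dimensionally they are the
#' components of \eqn{\nabla^* \cdot \nabla^* u^*}, i.e. viscous force
#' densities, not the stress tensor itself.) Second derivatives use central
#' differences with 2nd-order one-sided stencils at mask edges; nodes lacking
#' a full stencil are masked.
#'
#' @param field A dimensionless `gridded_field` (see [normalize_field()]).
#' @return An object of class `stress_maps` with matrices `tau_xx`, `tau_xy`,
#'   a joint `valid` mask, and the node coordinates.
#' @export
stress_maps <- function(field) {
  stopifnot(field$dimensionless)
  h <- field$h_star
  txx <- grid_deriv(field$u, field$valid, h, axis = 1, order = 2)
  uyy <- grid_deriv(field$u, field$valid, h, axis = 2, order = 2)
  vxx <- grid_deriv(field$v, field$valid, h, axis = 1, order = 2)
  txy <- (uyy + vxx) / 2
  structure(list(tau_xx = txx, tau_xy = txy,
                 valid = is.finite(txx) & is.finite(txy),
                 x_star = field$x_star, y_star = field$y_star),
            class = "stress_maps")
}

#' Streamwise momentum budget with inferred pressure gradient
#'
#' Evaluates, node-wise on a dimensionless field, the x-component terms of
#' the normalized momentum balance
#' \deqn{Re_{D_d} (u^* \cdot \nabla^*) u^* + \nabla^* p^* -
#'       \nabla^* \cdot \nabla^* u^* = 0:}
#' the inertial term \eqn{Re_{D_d}(u^* \partial u^*/\partial x^* +
#' v^* \partial u^*/\partial y^*)}, the viscous term
#' \eqn{\partial^2 u^*/\partial x^{*2} + \partial^2 u^*/\partial y^{*2}}, and
#' the pressure gradient inferred as their difference,
#' \eqn{\partial p^*/\partial x^* = \mathrm{viscous} - \mathrm{inertial}}.
#' The balance closes by construction, so the stored diagnostics are the term
#' magnitudes, not a closure residual.
#'
#' @param field A dimensionless `gridded_field`.
#' @param scales A [normalization_scales()] (defaults to the field's own).
#' @return An object of class `momentum_budget` with matrices `inertial`,
#'   `viscous`, `dp_dx`, a `valid` mask, `Re`, and term-magnitude
#'   `diagnostics`.
#' @export
momentum_budget <- function(field, scales = field$scales) {
  stopifnot(field$dimensionless, inherits(scales, "normalization_scales"))
  h <- field$h_star
  du_dx <- grid_deriv(field$u, field$valid, h, 1, 1)
  du_dy <- grid_deriv(field$u, field$valid, h, 2, 1)
  inertial <- scales$Re * (field$u * du_dx + field$v * du_dy)
  viscous <- grid_deriv(field$u, field$valid, h, 1, 2) +
             grid_deriv(field$u, field$valid, h, 2, 2)
  dp_dx <- viscous - inertial
  valid <- is.finite(inertial) & is.finite(viscous)
  structure(list(inertial = inertial, viscous = viscous, dp_dx = dp_dx,
                 valid = valid, Re = scales$Re,
                 x_star = field$x_star, y_star = field$y_star,
                 diagnostics = c(
                   max_abs_inertial = max(abs(inertial[valid]), na.rm = TRUE),
                   max_abs_viscous = max(abs(viscous[valid]), na.rm = TRUE),
                   max_abs_dp_dx = max(abs(dp_dx[valid]), na.rm = TRUE))),
            class = "momentum_budget")
}

#' Sample an analytic scene onto a grid
#'
#' Evaluates the scene's ground-truth field at the grid nodes (in um/s),
#' masking nodes inside the drop perimeter. Used as the oracle against
#' measured gridded fields and for closed-form budget checks.
#'
#' @param scene A [flow_scene()].
#' @param grid A [grid_spec()].
#' @param standoff_um Extra masked annulus width beyond the perimeter, um.
#' @return A `gridded_field` in um/s.
#' @export
sample_scene_to_grid <- function(scene, grid, standoff_um = 0) {
  x_um <- grid$x_px * grid$pitch
  y_um <- grid$y_px * grid$pitch
  pts <- cbind(rep(x_um, each = length(y_um)), rep(y_um, length(x_um)))
  a <- scene$droplet$diameter / 2
  r <- sqrt((pts[, 1] - scene$droplet$center[1])^2 +
            (pts[, 2] - scene$droplet$center[2])^2)
  vel <- eval_flow_clamped(scene, pts)
  ny <- length(y_um); nx <- length(x_um)
  valid <- matrix(r >= a + standoff_um, ny, nx)
  u <- matrix(vel[, 1], ny, nx); u[!valid] <- NA
  v <- matrix(vel[, 2], ny, nx); v[!valid] <- NA
  structure(list(x_px = grid$x_px, y_px = grid$y_px, x_um = x_um, y_um = y_um,
                 u = u, v = v, n = matrix(1L, ny, nx),
                 residual = matrix(0, ny, nx), valid = valid,
                 spacing_px = grid$spacing_px, pitch = grid$pitch,
                 center_px = grid$center_px, units = "um/s",
                 dimensionless = FALSE, n_rank_deficient = 0L, min_count = 1L),
            class = "gridded_field")
}

#' Stokes rising velocity of a buoyant droplet
#'
#' Rigid-sphere Stokes law \eqn{U = \Delta\rho\, g\, d^2 / (18 \mu)}. The
#' rigid form (rather than the Hadamard-Rybczynski mobile-interface
#' correction) is appropriate for crude-oil drops, whose viscosity far
#' exceeds that of water.
#'
#' @param diameter Drop diameter, um.
#' @param density_contrast \eqn{\Delta\rho} (fluid minus oil), kg/m^3.
#' @param mu_f Fluid viscosity, Pa s.
#' @param g Gravitational acceleration, m/s^2.
#' @return Rise velocity in mm/s.
#' @examples
#' stokes_rise_velocity(150, 150)  # ~1.84 mm/s, i.e. ~2 mm/s
#' @export
stokes_rise_velocity <- function(diameter, density_contrast, mu_f = 1e-3,
                                 g = 9.81) {
  stopifnot(diameter > 0, density_contrast > 0, mu_f > 0, g > 0)
  d <- diameter * 1e-6
  1000 * density_contrast * g * d^2 / (18 * mu_f)
}

#' Optical pixel pitch from calibration
#'
#' @param fov_um Field-of-view extent, um.
#' @param sensor_px Sensor extent, px.
#' @return um per pixel.
#' @examples
#' pixel_pitch(720, 1024)  # 0.703 um/px, i.e. ~0.7 um optical resolution
#' @export
pixel_pitch <- function(fov_um, sensor_px) {
  stopifnot(fov_um > 0, sensor_px > 0)
  fov_um / sensor_px
}
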