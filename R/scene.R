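#' Specify a pinned oil micro-droplet
#'
#' Geometric and material description of the droplet cross-section at the
#' channel mid-plane. The droplet must be buoyant (fluid denser than oil) so
#' that the imposed channel flow emulates the flow around a rising drop.
#'
#' @param diameter Drop diameter \eqn{D_d} in micrometres.
#' @param center Drop center as `c(x, y)` in micrometres (field-of-view frame,
#'   x streamwise, y transverse).
#' @param oil_density Oil density in kg/m^3 (crude oil, default 850).
#' @param fluid_density Aqueous-phase density in kg/m^3 (default 1000).
#' @param fluid_viscosity Dynamic viscosity \eqn{\mu_f} of the aqueous phase
#'   in Pa s (default 1e-3).
#' @return An object of class `droplet_spec`.
#' @export
droplet_spec <- function(diameter, center = c(0, 0), oil_density = 850,
                         fluid_density = 1000, fluid_viscosity = 1e-3) {
  stopifnot(is.numeric(diameter), length(diameter) == 1, diameter > 0,
            length(center) == 2, is.numeric(center),
            fluid_viscosity > 0, oil_density > 0)
  if (fluid_density <= oil_density)
    stop("fluid_density must exceed oil_density (the drop must be buoyant)")
  structure(list(diameter = diameter, center = as.numeric(center),
                 oil_density = oil_density, fluid_density = fluid_density,
                 fluid_viscosity = fluid_viscosity),
            class = "droplet_spec")
}

#' Define an analytic flow scene around the droplet
#'
#' The ground-truth velocity field used by the synthetic-scene generator and
#' as the oracle for pipeline validation. The `potential_past_circle` model is
#' the depth-averaged (Hele-Shaw) potential flow past a circular obstacle: in
#' drop-centered polar coordinates with \eqn{a = D_d/2},
#' \deqn{u_r = U_f (1 - a^2/r^2)\cos\theta, \quad
#'       u_\theta = -U_f (1 + a^2/r^2)\sin\theta.}
#' It is divergence-free and satisfies no-penetration on the perimeter (though
#' not no-slip). `uniform` is the constant free stream; `potential_plus_wake`
#' subtracts a Gaussian streamwise velocity deficit downstream of the drop to
#' mimic a momentum defect behind trailing aggregates.
#'
#' @param droplet A [droplet_spec()].
#' @param u_free Free-stream speed \eqn{U_f} in um/s, directed along +x.
#' @param model One of `"potential_past_circle"`, `"uniform"`,
#'   `"potential_plus_wake"`.
#' @param wake For the wake model: `list(amplitude=, width=, length=)` with
#'   amplitude a fraction of `u_free` and width/length in micrometres.
#' @return An object of class `flow_scene`.
#' @export
flow_scene <- function(droplet, u_free = 2000,
                       model = c("potential_past_circle", "uniform",
                                 "potential_plus_wake"),
                       wake = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(droplet, "droplet_spec"), is.numeric(u_free))
  if (model == "potential_plus_wake") {
    if (is.null(wake)) wake <- list(amplitude = 0.5, width = droplet$diameter / 4,
                                    length = 3 * droplet$diameter)
    stopifnot(all(c("amplitude", "width", "length") %in% names(wake)))
  }
  structure(list(droplet = droplet, u_free = u_free, model = model, wake = wake),
            class = "flow_scene")
}

# Field evaluation without the inside-drop guard; points inside the drop are
# evaluated at their radial projection onto the perimeter. Used internally by
# the advection integrator, whose midpoint stage may transiently probe inside.
eval_flow_clamped <- function(scene, pts) {
  pts <- rbind(pts)
  a <- scene$droplet$diameter / 2
  xc <- pts[, 1] - scene$droplet$center[1]
  yc <- pts[, 2] - scene$droplet$center[2]
  U <- scene$u_free
  if (scene$model == "uniform")
    return(cbind(rep(U, nrow(pts)), rep(0, nrow(pts))))
  r2 <- xc^2 + yc^2
  inside <- r2 < a^2
  if (any(inside)) {                 # project onto the perimeter
    r <- sqrt(pmax(r2[inside], 1e-300))
    xc[inside] <- xc[inside] * a / r
    yc[inside] <- yc[inside] * a / r
    r2[inside] <- a^2
  }
  th <- atan2(yc, xc)
  u <- U * (1 - (a^2 / r2) * cos(2 * th))
  v <- -U * (a^2 / r2) * sin(2 * th)
  if (scene$model == "potential_plus_wake") {
    w <- scene$wake
    s <- xc - a                      # streamwise distance past the rear pole
    deficit <- w$amplitude * U * exp(-0.5 * (yc / w$width)^2) *
      ifelse(s > 0, exp(-s / w$length), 0)
    u <- u - deficit
  }
  cbind(u, v)
}

#' Evaluate the scene velocity field
#'
#' @param scene A [flow_scene()].
#' @param points Numeric `c(x, y)` or an n x 2 matrix of positions in um.
#' @return An n x 2 matrix of velocities (u, v) in um/s.
#' @details Points strictly inside the drop perimeter are a domain error.
#' @export
evaluate_flow <- function(scene, points) {
  stopifnot(inherits(scene, "flow_scene"))
  pts <- rbind(points)
  if (ncol(pts) != 2) stop("points must be c(x, y) or an n x 2 matrix")
  a <- scene$droplet$diameter / 2
  r <- sqrt((pts[, 1] - scene$droplet$center[1])^2 +
            (pts[, 2] - scene$droplet$center[2])^2)
  bad <- which(r < a * (1 - 1e-9))
  if (length(bad))
    stop(sprintf("point (%.3f, %.3f) lies inside the drop (r = %.3f < a = %.3f)",
                 pts[bad[1], 1], pts[bad[1], 2], r[bad[1]], a))
  eval_flow_clamped(scene, pts)
}

#' Create a tracer ensemble
#'
#' @param positions n x 2 matrix of tracer positions in um.
#' @param diffusivity Translational diffusivity in um^2/s (Brownian motion of
#'   ~1 um cells in water is ~0.2 um^2/s; default 0 for a purely advected
#'   ensemble).
#' @param body Render shape: `list(shape = "blob", sigma = 0.7)` (Gaussian
#'   blob, sigma in um) or `list(shape = "rod", length =, width =)` with
#'   per-tracer orientations drawn at render time.
#' @param droplet Optional [droplet_spec()]; positions inside its perimeter
#'   are rejected.
#' @return An object of class `tracer_ensemble` with an `id` per tracer.
#' @export
tracer_ensemble <- function(positions, diffusivity = 0,
                            body = list(shape = "blob", sigma = 0.7),
                            droplet = NULL) {
  positions <- rbind(positions)
  stopifnot(ncol(positions) == 2, diffusivity >= 0)
  if (!is.null(droplet)) {
    a <- droplet$diameter / 2
    r <- sqrt((positions[, 1] - droplet$center[1])^2 +
              (positions[, 2] - droplet$center[2])^2)
    if (any(r < a)) stop("tracer positions must lie outside the drop perimeter")
  }
  structure(list(positions = unname(positions), diffusivity = diffusivity,
                 body = body, id = seq_len(nrow(positions)),
                 n_reflected = 0L, n_exited = 0L),
            class = "tracer_ensemble")
}

#' Seed tracers uniformly over a box, excluding the drop footprint
#'
#' @param n Number of tracers.
#' @param bbox `c(xmin, xmax, ymin, ymax)` in um.
#' @param droplet Optional [droplet_spec()] whose footprint is excluded.
#' @param diffusivity,body Passed to [tracer_ensemble()].
#' @return A `tracer_ensemble`. Uses the current RNG state.
#' @export
seed_tracers <- function(n, bbox, droplet = NULL, diffusivity = 0,
                         body = list(shape = "blob", sigma = 0.7)) {
  stopifnot(n >= 1, length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3])
  pos <- matrix(NA_real_, 0, 2)
  while (nrow(pos) < n) {
    k <- n - nrow(pos)
    cand <- cbind(runif(k, bbox[1], bbox[2]), runif(k, bbox[3], bbox[4]))
    if (!is.null(droplet)) {
      a <- droplet$diameter / 2
      r <- sqrt((cand[, 1] - droplet$center[1])^2 +
                (cand[, 2] - droplet$center[2])^2)
      cand <- cand[r >= a + 0.5, , drop = FALSE]   # 0.5 um standoff
    }
    pos <- rbind(pos, cand)
  }
  tracer_ensemble(pos[seq_len(n), , drop = FALSE], diffusivity, body, droplet)
}

#' Advect tracers through one time step
#'
#' Positions are advanced by midpoint (second-order Runge-Kutta) integration
#' of the scene field; when `diffusivity > 0` an independent Gaussian step of
#' per-axis variance `2 * diffusivity * dt` is added. Tracers that would end
#' inside the drop are reflected specularly off the perimeter
#' (\eqn{r \to 2a - r}) and counted in `n_reflected`. Tracers outside
#' `domain` (if given) are retained but counted in `n_exited`.
#'
#' @param ensemble A [tracer_ensemble()].
#' @param scene A [flow_scene()].
#' @param dt Time step in seconds (> 0).
#' @param domain Optional `c(xmin, xmax, ymin, ymax)` used only for exit
#'   bookkeeping.
#' @return The advanced `tracer_ensemble` (same tracer count and ids).
#' @export
advect_tracers <- function(ensemble, scene, dt, domain = NULL) {
  stopifnot(inherits(ensemble, "tracer_ensemble"), dt > 0)
  p0 <- ensemble$positions
  k1 <- eval_flow_clamped(scene, p0)
  pm <- p0 + 0.5 * dt * k1
  k2 <- eval_flow_clamped(scene, pm)
  p1 <- p0 + dt * k2
  if (ensemble$diffusivity > 0) {
    sdv <- sqrt(2 * ensemble$diffusivity * dt)
    p1 <- p1 + matrix(rnorm(length(p1), sd = sdv), ncol = 2)
  }
  n_refl <- 0L
  if (scene$model != "uniform") {
    a <- scene$droplet$diameter / 2
    xc <- p1[, 1] - scene$droplet$center[1]
    yc <- p1[, 2] - scene$droplet$center[2]
    r <- sqrt(xc^2 + yc^2)
    inside <- r < a
    if (any(inside)) {
      n_refl <- sum(inside)
      rr <- pmax(r[inside], 1e-6)
      scale <- (2 * a - rr) / rr     # specular reflection about the perimeter
      p1[inside, 1] <- scene$droplet$center[1] + xc[inside] * scale
      p1[inside, 2] <- scene$droplet$center[2] + yc[inside] * scale
    }
  }
  out <- ensemble
  out$positions <- p1
  out$n_reflected <- ensemble$n_reflected + n_refl
  if (!is.null(domain)) {
    exited <- p1[, 1] < domain[1] | p1[, 1] > domain[2] |
              p1[, 2] < domain[3] | p1[, 2] > domain[4]
    out$n_exited <- sum(exited)
  }
  out
}
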