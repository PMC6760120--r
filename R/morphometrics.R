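#' Fit the droplet cross-section as a circle
#'
#' Locates the dominant dark disk (the drop footprint), then refines its
#' geometry: 360 radial intensity profiles are cast from the coarse centroid,
#' the perimeter is located per ray as the sub-pixel mid-level crossing, and a
#' circle is fit to the edge points (Kasa algebraic fit refined by
#' Gauss-Newton on the geometric distance). The RMS radial deviation of edge
#' points is reported, never silently discarded.
#'
#' @param image Numeric matrix (counts) containing one dominant dark disk.
#' @param pitch um per px (for `radius_um`); `NA` if unknown.
#' @param min_radius_px Smallest acceptable drop radius, px.
#' @return An object of class `drop_geometry`: `center_px` (x, y),
#'   `radius_px`, `radius_um`, `residual_px`, `interior_level`, `bg_level`.
#' @export
fit_drop <- function(image, pitch = NA, min_radius_px = 10) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  bg <- median(image)
  spread <- mad(image)
  dark <- image < bg - max(6 * spread, 0.25 * bg)
  fail <- function(why)
    stop(sprintf("no circular structure found: %s (bg=%.1f, mad=%.1f)",
                 why, bg, spread))
  if (!any(dark)) fail("no pixels below the dark threshold")
  lab <- EBImage::bwlabel(dark * 1L)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < pi * min_radius_px^2)
    fail("largest dark component is below the minimum drop area")
  comp <- lab == which.max(sizes)
  ij <- which(comp, arr.ind = TRUE)
  cx <- mean(ij[, 2] - 0.5); cy <- mean(ij[, 1] - 0.5)
  r0 <- sqrt(sum(comp) / pi)
  interior <- median(image[comp])
  level <- (bg + interior) / 2

  sample_img <- function(x, y) {       # bilinear, pixel centers at (j-.5, i-.5)
    gx <- pmin(pmax(x + 0.5, 1), nc); gy <- pmin(pmax(y + 0.5, 1), nr)
    j0 <- pmin(floor(gx), nc - 1); i0 <- pmin(floor(gy), nr - 1)
    fx <- gx - j0; fy <- gy - i0
    image[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      image[cbind(i0, j0 + 1)] * fx * (1 - fy) +
      image[cbind(i0 + 1, j0)] * (1 - fx) * fy +
      image[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  edge_points <- function(cx, cy, r0) {
    th <- seq(0, 2 * pi, length.out = 361)[-361]
    rs <- seq(max(1, 0.5 * r0), 1.6 * r0, by = 0.5)
    pts <- matrix(NA_real_, length(th), 2)
    for (k in seq_along(th)) {
      x <- cx + rs * cos(th[k]); y <- cy + rs * sin(th[k])
      prof <- sample_img(x, y)
      if (length(prof) >= 3)           # light smoothing against read noise
        prof <- stats::filter(prof, rep(1 / 3, 3), sides = 2) |>
          (\(p) { p[is.na(p)] <- prof[is.na(p)]; p })()
      ins <- prof < level              # inside the dark disk
      cross <- which(ins[-length(ins)] & !ins[-1])
      if (!length(cross)) next
      i <- cross[length(cross)]        # outermost dark-to-bright crossing
      f <- (level - prof[i]) / (prof[i + 1] - prof[i])
      re <- rs[i] + f * (rs[i + 1] - rs[i])
      pts[k, ] <- c(cx + re * cos(th[k]), cy + re * sin(th[k]))
    }
    pts[is.finite(pts[, 1]), , drop = FALSE]
  }
  fit_circle <- function(p) {          # Kasa then Gauss-Newton
    A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
    sol <- qr.solve(A, p[, 1]^2 + p[, 2]^2)
    cx <- sol[1]; cy <- sol[2]; R <- sqrt(sol[3] + cx^2 + cy^2)
    for (it in 1:10) {
      dx <- p[, 1] - cx; dy <- p[, 2] - cy
      r <- sqrt(dx^2 + dy^2)
      J <- cbind(-dx / r, -dy / r, -1)
      step <- tryCatch(qr.solve(J, -(r - R)), error = function(e) c(0, 0, 0))
      cx <- cx + step[1]; cy <- cy + step[2]; R <- R + step[3]
      if (sqrt(sum(step^2)) < 1e-10) break
    }
    r <- sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)
    list(cx = cx, cy = cy, R = R, resid = sqrt(mean((r - R)^2)))
  }

  fit <- NULL
  for (pass in 1:2) {
    p <- edge_points(cx, cy, r0)
    if (nrow(p) < 30) fail("too few perimeter edge points")
    fit <- fit_circle(p)
    cx <- fit$cx; cy <- fit$cy; r0 <- fit$R
  }
  if (fit$R < min_radius_px || fit$resid > 0.2 * fit$R)
    fail("edge points are not consistent with a circle")
  structure(list(center_px = c(cx, cy), radius_px = fit$R,
                 radius_um = fit$R * pitch, residual_px = fit$resid,
                 interior_level = interior, bg_level = bg, time = NA_real_),
            class = "drop_geometry")
}

#' Segment droplet-bound aggregates
#'
#' Local-background-relative thresholding: background level and spread are
#' estimated robustly (median/MAD) outside the drop, and aggregate pixels are
#' those outside the perimeter whose robust z-score exceeds `z_thresh` in
#' either direction. Relative thresholds make the mask invariant to affine
#' intensity transforms.
#'
#' @param image Numeric matrix.
#' @param geometry A [fit_drop()] result.
#' @param z_thresh Robust z-score threshold (default 2).
#' @return Logical matrix (TRUE = aggregate).
#' @export
aggregate_mask <- function(image, geometry, z_thresh = 2) {
  nr <- nrow(image); nc <- ncol(image)
  xc <- (seq_len(nc) - 0.5) - geometry$center_px[1]
  yc <- (seq_len(nr) - 0.5) - geometry$center_px[2]
  r <- sqrt(outer(yc^2, xc^2, `+`))
  out_drop <- r > geometry$radius_px + 2
  bg <- median(image[out_drop])
  s <- mad(image[out_drop])
  if (s <= 0) s <- 1e-12
  abs(image - bg) > z_thresh * s & out_drop
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Film-thickness-versus-angle profile
#'
#' Measures the radial extent of the aggregate film along 360 rays at 1
#' degree resolution, then bins the ray thicknesses. Angles are measured from
#' the leading (upstream) stagnation point, positive counterclockwise; bin
#' centers are multiples of the bin width so that e.g. +/-45 degrees are
#' exact centers. Along each ray the thickness is the outermost extent of the
#' mask run connected to the perimeter, bridging holes up to `gap_tol_px`.
#'
#' @param image Numeric matrix.
#' @param geometry A [fit_drop()] result from the same frame.
#' @param bins Number of angular bins covering 360 degrees (default 72).
#' @param pitch um per px.
#' @param flow_dir Unit flow direction in the image frame (default +x).
#' @param z_thresh Segmentation threshold, see [aggregate_mask()].
#' @param gap_tol_px Largest hole bridged along a ray, px.
#' @return A `film_profile` data.frame with `angle_deg` (bin centers),
#'   `thickness_um`; attributes carry the per-ray profile and mask provenance.
#' @export
film_profile <- function(image, geometry, bins = 72, pitch = 1,
                         flow_dir = c(1, 0), z_thresh = 2, gap_tol_px = 2) {
  mask <- aggregate_mask(image, geometry, z_thresh)
  nr <- nrow(image); nc <- ncol(image)
  cx <- geometry$center_px[1]; cy <- geometry$center_px[2]
  R <- geometry$radius_px
  flow_dir <- flow_dir / sqrt(sum(flow_dir^2))
  phi0 <- atan2(-flow_dir[2], -flow_dir[1])   # image angle of the upstream pole

  theta <- seq(0, 359)                        # degrees from stagnation point
  rmax <- min(cx, nc - cx, cy, nr - cy) - 1
  step <- 0.5
  rs <- seq(R + step, rmax, by = step)
  thick <- numeric(length(theta))
  for (k in seq_along(theta)) {
    ang <- phi0 + theta[k] * pi / 180
    x <- cx + rs * cos(ang); y <- cy + rs * sin(ang)
    i <- pmin(pmax(ceiling(y), 1), nr); j <- pmin(pmax(ceiling(x), 1), nc)
    m <- mask[cbind(i, j)]
    t <- 0; gap <- 0
    for (s in seq_along(m)) {
      if (m[s]) { t <- rs[s] - R; gap <- 0 }
      else { gap <- gap + step; if (gap > gap_tol_px) break }
    }
    thick[k] <- t
  }
  width <- 360 / bins
  centers <- wrap180(seq(0, bins - 1) * width)
  bin_of <- (round(wrap180(theta) / width) %% bins) + 1
  binned <- vapply(seq_len(bins), function(b)
    mean(thick[bin_of == b]) * pitch, numeric(1))
  ord <- order(centers)
  structure(data.frame(angle_deg = centers[ord], thickness_um = binned[ord]),
            class = c("film_profile", "data.frame"),
            ray_angle_deg = wrap180(theta), ray_thickness_um = thick * pitch,
            z_thresh = z_thresh, pitch = pitch)
}

#' Streamer-tail extent downstream of the drop
#'
#' Segments aggregates, keeps the connected components touching the drop
#' perimeter, and projects them onto the flow direction; the tail length is
#' the farthest connected extent beyond the drop's rear perimeter, in um and
#' in drop diameters. An absent tail yields zero length, not an error.
#'
#' @param image Numeric matrix.
#' @param geometry A [fit_drop()] result.
#' @param flow_dir Unit flow direction (default +x).
#' @param pitch um per px.
#' @param z_thresh Segmentation threshold.
#' @param n_width_bins Number of bins of the downstream width profile.
#' @return A `tail_metric`: `length_um`, `length_dd`, `classification`,
#'   `width_profile` (data.frame `s_um`, `width_um`), `hollow_fraction`.
#' @export
tail_metric <- function(image, geometry, flow_dir = c(1, 0), pitch = 1,
                        z_thresh = 2, n_width_bins = 20) {
  mask <- aggregate_mask(image, geometry, z_thresh)
  zero <- structure(list(length_um = 0, length_dd = 0,
                         classification = "no tail",
                         width_profile = data.frame(s_um = numeric(0),
                                                    width_um = numeric(0)),
                         hollow_fraction = NA_real_),
                    class = "tail_metric")
  if (!any(mask)) return(zero)
  lab <- EBImage::bwlabel(mask * 1L)
  ij <- which(mask, arr.ind = TRUE)
  x <- ij[, 2] - 0.5; y <- ij[, 1] - 0.5
  cx <- geometry$center_px[1]; cy <- geometry$center_px[2]
  R <- geometry$radius_px
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  touching <- unique(lab[ij][r < R + 3])
  touching <- touching[touching > 0]
  if (!length(touching)) return(zero)
  keep <- lab[ij] %in% touching
  x <- x[keep]; y <- y[keep]
  flow_dir <- flow_dir / sqrt(sum(flow_dir^2))
  s <- (x - cx) * flow_dir[1] + (y - cy) * flow_dir[2]
  t <- -(x - cx) * flow_dir[2] + (y - cy) * flow_dir[1]
  len_px <- max(0, max(s) - R)
  D_d_um <- 2 * R * pitch
  if (len_px <= 0) return(zero)

  beyond <- s > R
  wp <- data.frame(s_um = numeric(0), width_um = numeric(0))
  hollow <- NA_real_
  if (any(beyond)) {
    sb <- s[beyond]; tb <- t[beyond]
    brk <- seq(R, R + len_px, length.out = n_width_bins + 1)
    bin <- pmin(findInterval(sb, brk, rightmost.closed = TRUE), n_width_bins)
    wp <- data.frame(
      s_um = ((brk[-1] + brk[-length(brk)]) / 2 - R) * pitch,
      width_um = vapply(seq_len(n_width_bins), function(b) {
        tt <- tb[bin == b]
        if (!length(tt)) 0 else (max(tt) - min(tt) + 1) * pitch
      }, numeric(1)))
    tail_mask <- matrix(FALSE, nrow(image), ncol(image))
    tail_mask[cbind(round(y[beyond] + 0.5), round(x[beyond] + 0.5))] <- TRUE
    filled <- EBImage::fillHull(tail_mask * 1L) > 0
    hollow <- 1 - sum(tail_mask) / max(1, sum(filled))
  }
  dd <- len_px * pitch / D_d_um
  structure(list(length_um = len_px * pitch, length_dd = dd,
                 classification = if (dd > 10) "> 10 drop diameters"
                                  else "<= 10 drop diameters",
                 width_profile = wp, hollow_fraction = hollow),
            class = "tail_metric")
}

#' Per-frame morphometrics over a time-lapse sequence
#'
#' Fits the drop, measures the film profile and tail metric on every frame,
#' with per-frame failures flagged (the run continues).
#'
#' @param sequence An [image_sequence()] of kind `"timelapse"` (any kind is
#'   accepted).
#' @param flow_dir Unit flow direction.
#' @param bins Angular bins for the film profile.
#' @param z_thresh Segmentation threshold.
#' @return A data.frame with one row per frame: `frame, time_s, ok, note,
#'   center_x_px, center_y_px, radius_um, residual_px, film_mean_um,
#'   film_max_um, film_peak_angle_deg, tail_um, tail_dd`.
#' @export
drop_timeseries <- function(sequence, flow_dir = c(1, 0), bins = 72,
                            z_thresh = 2) {
  stopifnot(inherits(sequence, "image_sequence"))
  pitch <- sequence$pixel_pitch
  rows <- lapply(seq_along(sequence$frames), function(f) {
    base <- data.frame(frame = f, time_s = (f - 1) * sequence$frame_interval,
                       ok = FALSE, note = "", center_x_px = NA, center_y_px = NA,
                       radius_um = NA, residual_px = NA, film_mean_um = NA,
                       film_max_um = NA, film_peak_angle_deg = NA,
                       tail_um = NA, tail_dd = NA)
    tryCatch({
      geom <- fit_drop(sequence$frames[[f]], pitch = pitch)
      fp <- film_profile(sequence$frames[[f]], geom, bins = bins,
                         pitch = pitch, flow_dir = flow_dir,
                         z_thresh = z_thresh)
      tm <- tail_metric(sequence$frames[[f]], geom, flow_dir = flow_dir,
                        pitch = pitch, z_thresh = z_thresh)
      base$ok <- TRUE
      base$center_x_px <- geom$center_px[1]; base$center_y_px <- geom$center_px[2]
      base$radius_um <- geom$radius_um; base$residual_px <- geom$residual_px
      base$film_mean_um <- mean(fp$thickness_um)
      base$film_max_um <- max(fp$thickness_um)
      base$film_peak_angle_deg <- fp$angle_deg[which.max(fp$thickness_um)]
      base$tail_um <- tm$length_um; base$tail_dd <- tm$length_dd
      base
    }, error = function(e) { base$note <- conditionMessage(e); base })
  })
  do.call(rbind, rows)
}

#' Render a synthetic morphology frame
#'
#' Generates a time-lapse-style frame for morphometrics validation: dark drop
#' footprint on a uniform background, plus optional bright film (uniform
#' annulus or Gaussian crescents at given angles from the leading stagnation
#' point) and an optional straight streamer tail downstream.
#'
#' @param droplet A [droplet_spec()].
#' @param spec A [render_spec()] (noise and background reused).
#' @param film `NULL`, `list(kind = "annulus", thickness = <um>)`, or
#'   `list(kind = "crescent", centers_deg =, peak_um =, width_deg =)`.
#' @param tail `NULL` or `list(length_dd =, width_um =)`.
#' @param flow_dir Unit flow direction.
#' @param seed Noise seed (default `spec$seed`).
#' @return A numeric image matrix.
#' @export
render_morphology_frame <- function(droplet, spec, film = NULL, tail = NULL,
                                    flow_dir = c(1, 0), seed = spec$seed) {
  nr <- spec$sensor[2]; nc <- spec$sensor[1]
  pitch <- spec$pixel_pitch
  xg <- (seq_len(nc) - 0.5) * pitch - droplet$center[1]
  yg <- (seq_len(nr) - 0.5) * pitch - droplet$center[2]
  X <- matrix(xg, nr, nc, byrow = TRUE)
  Y <- matrix(yg, nr, nc)
  r <- sqrt(X^2 + Y^2)
  a <- droplet$diameter / 2
  flow_dir <- flow_dir / sqrt(sum(flow_dir^2))
  img <- matrix(spec$background, nr, nc)
  bright <- spec$background + 0.5 * spec$peak

  if (!is.null(film)) {
    phi0 <- atan2(-flow_dir[2], -flow_dir[1])
    theta <- wrap180((atan2(Y, X) - phi0) * 180 / pi)
    tfun <- if (film$kind == "annulus") {
      matrix(film$thickness, nr, nc)
    } else {
      acc <- matrix(0, nr, nc)
      for (cdeg in film$centers_deg)
        acc <- acc + film$peak_um *
          exp(-0.5 * (wrap180(theta - cdeg) / film$width_deg)^2)
      acc
    }
    img[r >= a & r < a + tfun] <- bright
  }
  if (!is.null(tail)) {
    s <- X * flow_dir[1] + Y * flow_dir[2]
    t <- -X * flow_dir[2] + Y * flow_dir[1]
    L <- tail$length_dd * droplet$diameter
    img[s > 0 & s <= a + L & abs(t) <= tail$width_um / 2 & r >= a] <- bright
  }
  img[r < a] <- 0.3 * spec$background
  if (spec$noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(nr * nc, sd = spec$noise_sd),
                                        nr, nc))
  img[img < 0] <- 0
  img[img > 2^spec$bit_depth - 1] <- 2^spec$bit_depth - 1
  round(img)
}
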