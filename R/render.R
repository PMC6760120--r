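#' Rendering specification for synthetic micrographs
#'
#' Emulates the acquisition geometry of the experiment: a 720 x 720 um field
#' of view on a 1K x 1K sensor (0.70 um/px), tracers imaged as
#' diffraction-limited spots, and additive Gaussian read noise. Depth-of-field
#' averaging over the ~5 um optical slab is modeled as purely 2-D: tracers
#' live at the focal mid-plane.
#'
#' @param fov Field of view `c(width, height)` in um.
#' @param sensor Sensor size `c(cols, rows)` in pixels.
#' @param background Uniform background level in counts.
#' @param noise_sd Gaussian read-noise standard deviation in counts (0 = none).
#' @param peak Peak (center-pixel) intensity of a tracer spot in counts.
#' @param psf_sigma Gaussian point-spread sigma in um.
#' @param bit_depth Sensor bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed Integer seed that fully determines rendered stacks (noise and
#'   any render-time randomness); `NULL` uses the current RNG state.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(fov = c(720, 720), sensor = c(1024, 1024),
                        background = 120, noise_sd = 8, peak = 2000,
                        psf_sigma = 0.7, bit_depth = 16, seed = NULL) {
  stopifnot(all(fov > 0), all(sensor >= 1), background >= 0, noise_sd >= 0,
            peak > 0, psf_sigma > 0)
  pitch <- fov / sensor
  if (any(pitch <= 0)) stop("pixel pitch must be positive")
  structure(list(fov = fov, sensor = as.integer(sensor), background = background,
                 noise_sd = noise_sd, peak = peak, psf_sigma = psf_sigma,
                 bit_depth = as.integer(bit_depth), seed = seed,
                 pixel_pitch = pitch[1]),
            class = "render_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(expr))
}

# Expand an ensemble into per-spot stamping parameters (rods become a short
# chain of sub-blobs along their axis).
spot_params <- function(ensemble, pitch, peak) {
  pos <- ensemble$positions
  body <- ensemble$body
  if (identical(body$shape, "rod")) {
    n <- nrow(pos)
    ang <- if (!is.null(body$orientations)) body$orientations else
      (seq_len(n) * 2.399963)          # deterministic golden-angle spread
    nsub <- 5
    s <- seq(-0.5, 0.5, length.out = nsub) * body$length / pitch
    x <- rep(pos[, 1] / pitch, each = nsub) + rep(s, n) * rep(cos(ang), each = nsub)
    y <- rep(pos[, 2] / pitch, each = nsub) + rep(s, n) * rep(sin(ang), each = nsub)
    list(x = x, y = y, sigma = rep((body$width / 2) / pitch, n * nsub),
         amp = rep(peak / nsub, n * nsub))
  } else {
    list(x = pos[, 1] / pitch, y = pos[, 2] / pitch,
         sigma = rep(body$sigma / pitch, nrow(pos)),
         amp = rep(peak, nrow(pos)))
  }
}

#' Render one synthetic micrograph
#'
#' Produces background + per-tracer point-spread profiles (Gaussian,
#' integrated over pixel areas) + a dark drop footprint (attenuated interior
#' with a darker rim at the perimeter) + seeded Gaussian read noise, clipped
#' to the sensor range. Pixel `(row i, col j)` is centered at
#' `x = (j - 0.5) * pitch`, `y = (i - 0.5) * pitch`; rows index the transverse
#' (y) axis.
#'
#' @param ensemble A [tracer_ensemble()] (positions in um).
#' @param spec A [render_spec()].
#' @param droplet Optional [droplet_spec()] rendered as a dark disk.
#' @param seed Overrides `spec$seed` for this frame.
#' @param quantize Round to integer counts (the sensor model); set `FALSE`
#'   for unquantized photometric analysis.
#' @return A numeric matrix (`sensor[2]` rows x `sensor[1]` cols) of counts.
#' @export
render_frame <- function(ensemble, spec, droplet = NULL,
                         seed = spec$seed, quantize = TRUE) {
  stopifnot(inherits(spec, "render_spec"))
  nr <- spec$sensor[2]; nc <- spec$sensor[1]
  pitch <- spec$pixel_pitch
  img <- matrix(spec$background, nr, nc)

  if (!is.null(droplet)) {
    xc <- (seq_len(nc) - 0.5) * pitch - droplet$center[1]
    yc <- (seq_len(nr) - 0.5) * pitch - droplet$center[2]
    r <- sqrt(outer(yc^2, xc^2, `+`))
    a <- droplet$diameter / 2
    img[r < a] <- 0.3 * spec$background
    img[abs(r - a) <= pitch] <- 0.05 * spec$background
  }

  if (!is.null(ensemble) && nrow(ensemble$positions) > 0) {
    sp <- spot_params(ensemble, pitch, spec$peak)
    img <- img + stamp_blobs_cpp(nr, nc, sp$x, sp$y, sp$sigma, sp$amp)
  }

  if (spec$noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc))
  img[img < 0] <- 0
  vmax <- 2^spec$bit_depth - 1
  img[img > vmax] <- vmax
  if (quantize) round(img) else img
}

#' Calibrated image sequence
#'
#' Container for a stack of frames with its calibration: pixel pitch, frame
#' interval, and stream kind (`"burst"` for high-speed velocimetry,
#' `"timelapse"` for morphometrics).
#'
#' @param frames List of numeric matrices (identical dimensions).
#' @param pixel_pitch um per pixel.
#' @param frame_interval Seconds between frames.
#' @param kind `"burst"` or `"timelapse"`.
#' @param truth Optional ground-truth trajectory table (see [make_burst()]).
#' @param scene,spec Optional provenance ([flow_scene()], [render_spec()]).
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_pitch, frame_interval,
                           kind = c("burst", "timelapse"),
                           truth = NULL, scene = NULL, spec = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(frames), length(frames) >= 1, pixel_pitch > 0,
            frame_interval > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all frames must share dimensions")
  structure(list(frames = frames, pixel_pitch = pixel_pitch,
                 frame_interval = frame_interval, kind = kind,
                 truth = truth, scene = scene, spec = spec),
            class = "image_sequence")
}

#' @export
length.image_sequence <- function(x) length(x$frames)

#' Simulate a high-speed burst with paired ground truth
#'
#' Renders `n_frames` frames at `1/frame_rate` intervals while advecting the
#' tracer ensemble through the scene field. When no initial ensemble is given,
#' tracers are seeded uniformly over the field of view extended upstream by
#' the free-stream drift over the burst duration, so the in-view tracer count
#' stays near `n_per_frame` throughout (as it does under continuous seeding in
#' the experiment). The exported truth table carries every tracer every frame.
#'
#' @param scene A [flow_scene()].
#' @param spec A [render_spec()]; its `seed` determines the whole stack.
#' @param n_frames Number of frames (>= 2).
#' @param frame_rate Frames per second (default 1000).
#' @param n_per_frame Target in-view tracer count (default 600).
#' @param ensemble0 Optional initial [tracer_ensemble()] overriding seeding.
#' @param diffusivity Tracer diffusivity um^2/s for auto-seeded ensembles.
#' @return An [image_sequence()] of kind `"burst"` whose `truth` is a
#'   data.frame with columns `frame, id, x_um, y_um, u_um_s, v_um_s, in_view`.
#' @export
make_burst <- function(scene, spec, n_frames, frame_rate = 1000,
                       n_per_frame = 600, ensemble0 = NULL, diffusivity = 0) {
  stopifnot(inherits(scene, "flow_scene"), inherits(spec, "render_spec"),
            n_frames >= 2, frame_rate > 0)
  dt <- 1 / frame_rate
  fov <- spec$fov
  if (is.null(ensemble0)) {
    drift <- abs(scene$u_free) * n_frames * dt + 20
    bbox <- c(-drift, fov[1], 0, fov[2])
    density <- n_per_frame / (fov[1] * fov[2])
    n_tot <- max(n_per_frame, round(density * (fov[1] + drift) * fov[2]))
    ensemble0 <- with_seed(
      if (is.null(spec$seed)) NULL else child_seed(spec$seed, 1),
      seed_tracers(n_tot, bbox, scene$droplet, diffusivity = diffusivity))
  }
  ens <- ensemble0
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    vel <- eval_flow_clamped(scene, ens$positions)
    in_view <- ens$positions[, 1] >= 0 & ens$positions[, 1] <= fov[1] &
               ens$positions[, 2] >= 0 & ens$positions[, 2] <= fov[2]
    truth[[f]] <- data.frame(frame = f, id = ens$id,
                             x_um = ens$positions[, 1], y_um = ens$positions[, 2],
                             u_um_s = vel[, 1], v_um_s = vel[, 2],
                             in_view = in_view)
    vis <- ens
    vis$positions <- ens$positions[in_view, , drop = FALSE]
    frames[[f]] <- render_frame(vis, spec, scene$droplet,
                                seed = if (is.null(spec$seed)) NULL else
                                  child_seed(spec$seed, 100 + f))
    if (f < n_frames)
      ens <- with_seed(if (is.null(spec$seed) || diffusivity == 0) NULL else
                         child_seed(spec$seed, 200 + f),
                       advect_tracers(ens, scene, dt))
  }
  image_sequence(frames, spec$pixel_pitch, dt, "burst",
                 truth = do.call(rbind, truth), scene = scene, spec = spec)
}
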