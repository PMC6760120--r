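#' Particle-detection configuration
#'
#' Band-pass (difference-of-Gaussians) detection tuned to ~1-2 um cell images:
#' the narrow scale matches the point-spread sigma, the wide scale suppresses
#' background structure, and candidates are local maxima above a threshold,
#' refined to sub-pixel precision by an intensity-weighted centroid over a
#' fixed window.
#'
#' @param sigma_narrow,sigma_wide DoG scales in px (`sigma_wide > sigma_narrow`).
#' @param threshold Absolute DoG threshold in counts, or `NULL` for automatic
#'   `5 * mad(DoG)` above its median.
#' @param min_sep Minimum separation between detections in px.
#' @param centroid_radius Half-width of the centroid-refinement window in px.
#' @return An object of class `detect_config`.
#' @export
detect_config <- function(sigma_narrow = 1, sigma_wide = 2.5, threshold = NULL,
                          min_sep = 3, centroid_radius = 3) {
  stopifnot(sigma_wide > sigma_narrow, sigma_narrow > 0, min_sep >= 1,
            centroid_radius >= 1)
  structure(list(sigma_narrow = sigma_narrow, sigma_wide = sigma_wide,
                 threshold = threshold, min_sep = min_sep,
                 centroid_radius = as.integer(centroid_radius)),
            class = "detect_config")
}

#' Detect tracer cells in one frame
#'
#' @param image Calibrated numeric matrix (counts).
#' @param config A [detect_config()].
#' @param mask Optional logical matrix (TRUE = excluded, e.g. drop footprint);
#'   detections inside it are dropped.
#' @return An object of class `particle_set`: a data.frame with sub-pixel
#'   columns `x_px, y_px` plus `intensity` (DoG peak) and `size` (RMS spot
#'   radius, px). A blank frame yields an empty set, not an error.
#' @export
detect_particles <- function(image, config = detect_config(), mask = NULL) {
  stopifnot(is.matrix(image))
  dog <- gauss_blur_cpp(image, config$sigma_narrow) -
         gauss_blur_cpp(image, config$sigma_wide)
  thr <- config$threshold
  if (is.null(thr)) thr <- median(dog) + 5 * mad(dog)
  # floor against floating-point ripple on flat or noiseless frames
  thr <- max(thr, 1e-8 * max(abs(image)))

  # strict local maxima over the 8-neighborhood
  is_max <- dog > thr
  for (k in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    if (!any(is_max)) break
    is_max <- is_max & (dog >= shift_mat(dog, k[1], k[2], fill = -Inf))
  }
  idx <- which(is_max, arr.ind = TRUE)
  empty <- structure(data.frame(x_px = numeric(0), y_px = numeric(0),
                                intensity = numeric(0), size = numeric(0)),
                     class = c("particle_set", "data.frame"))
  if (nrow(idx) == 0) return(empty)

  peaks <- data.frame(i = idx[, 1], j = idx[, 2], val = dog[idx])
  peaks <- peaks[order(-peaks$val), ]
  # enforce minimum separation, brightest first
  if (nrow(peaks) > 1) {
    keep <- rep(TRUE, nrow(peaks))
    for (k in seq_len(nrow(peaks))[-1]) {
      prev <- which(keep[seq_len(k - 1)])
      near <- prev[abs(peaks$i[prev] - peaks$i[k]) < config$min_sep &
                   abs(peaks$j[prev] - peaks$j[k]) < config$min_sep]
      if (length(near)) keep[k] <- FALSE
    }
    peaks <- peaks[keep, ]
  }

  # sub-pixel refinement: intensity-weighted centroid on the (non-negative)
  # DoG response in a fixed window
  r <- config$centroid_radius
  nr <- nrow(image); nc <- ncol(image)
  out <- lapply(seq_len(nrow(peaks)), function(k) {
    i <- peaks$i[k]; j <- peaks$j[k]
    ii <- max(1, i - r):min(nr, i + r)
    jj <- max(1, j - r):min(nc, j + r)
    w <- pmax(dog[ii, jj, drop = FALSE], 0)
    sw <- sum(w)
    if (sw <= 0) return(NULL)
    # pixel (i,j) spans [i-1,i] so its center is i - 0.5
    yc <- sum((ii - 0.5) * rowSums(w)) / sw
    xc <- sum((jj - 0.5) * colSums(w)) / sw
    size <- sqrt(sum(w * (outer(ii - 0.5 - yc, jj - 0.5 - xc,
                                function(a, b) a^2 + b^2))) / sw)
    c(xc, yc, peaks$val[k], size)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  df <- data.frame(x_px = out[, 1], y_px = out[, 2],
                   intensity = out[, 3], size = out[, 4])

  # neighbor-aware refinement: spots with a close neighbor have their
  # centroid recomputed after subtracting the neighbors' modeled band-pass
  # response, which removes the mutual pull of partially-overlapping spots
  if (nrow(df) > 1) {
    dmat <- as.matrix(stats::dist(df[, c("x_px", "y_px")]))
    diag(dmat) <- Inf
    reach <- 2 * (2 * r + 1)
    near <- which(apply(dmat, 1, min) < reach)
    if (length(near)) {
      sigma_eff <- max(median(df$size), 0.8)
      for (iter in 1:2) {
        upd <- df
        for (k in near) {
          i <- min(max(round(df$y_px[k] + 0.5), 1), nr)
          j <- min(max(round(df$x_px[k] + 0.5), 1), nc)
          ii <- max(1, i - r):min(nr, i + r)
          jj <- max(1, j - r):min(nc, j + r)
          w <- pmax(dog[ii, jj, drop = FALSE], 0)
          for (q in which(dmat[k, ] < reach + 3 * sigma_eff)) {
            gy <- exp(-((ii - 0.5) - df$y_px[q])^2 / (2 * sigma_eff^2))
            gx <- exp(-((jj - 0.5) - df$x_px[q])^2 / (2 * sigma_eff^2))
            w <- w - df$intensity[q] * (gy %o% gx)
          }
          w <- pmax(w, 0)
          sw <- sum(w)
          if (sw <= 0) next
          upd$y_px[k] <- sum((ii - 0.5) * rowSums(w)) / sw
          upd$x_px[k] <- sum((jj - 0.5) * colSums(w)) / sw
        }
        df <- upd
      }
    }
  }

  if (!is.null(mask)) {
    ij <- cbind(pmin(pmax(ceiling(df$y_px), 1), nr),
                pmin(pmax(ceiling(df$x_px), 1), nc))
    df <- df[!mask[ij], , drop = FALSE]
  }
  # spots whose refinement window is clipped by the frame border carry a
  # truncation-biased centroid; discard them
  b <- r + 1
  df <- df[df$x_px >= b & df$x_px <= nc - b & df$y_px >= b & df$y_px <= nr - b, ]
  structure(df, class = c("particle_set", "data.frame"))
}

#' Match particles across a frame pair with a PIV predictor
#'
#' Each particle of the first frame is projected forward by the bilinearly
#' interpolated PIV displacement; candidates in the second frame within
#' `radius` of the projection are ranked by residual and resolved greedily
#' under a one-to-one constraint. Particles at which the predictor is
#' undefined (masked lattice region) are skipped and counted.
#'
#' @param set_a,set_b [detect_particles()] results from consecutive frames.
#' @param predictor A validated [correlate_pair()] field.
#' @param radius Search radius around the projection, px (default 3).
#' @return A `vector_set` data.frame with columns
#'   `x_px, y_px` (pair midpoint), `dx_px, dy_px`, `residual_px`, `ia, ib`
#'   (row indices into the input sets). Attributes `n_unmatched_a`,
#'   `n_unmatched_b`, `n_skipped` report the bookkeeping.
#' @export
match_particles <- function(set_a, set_b, predictor, radius = 3) {
  empty <- structure(data.frame(x_px = numeric(0), y_px = numeric(0),
                                dx_px = numeric(0), dy_px = numeric(0),
                                residual_px = numeric(0),
                                ia = integer(0), ib = integer(0)),
                     class = c("vector_set", "data.frame"))
  attr(empty, "n_unmatched_a") <- nrow(set_a)
  attr(empty, "n_unmatched_b") <- nrow(set_b)
  attr(empty, "n_skipped") <- 0L
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)

  pred <- interp_field(predictor, set_a$x_px, set_a$y_px)
  skipped <- !is.finite(pred[, 1]) | !is.finite(pred[, 2])
  proj_x <- set_a$x_px + pred[, 1]
  proj_y <- set_a$y_px + pred[, 2]

  cand <- NULL
  usable <- which(!skipped)
  if (length(usable)) {
    dx <- outer(proj_x[usable], set_b$x_px, `-`)
    dy <- outer(proj_y[usable], set_b$y_px, `-`)
    d <- sqrt(dx^2 + dy^2)
    hit <- which(d <= radius, arr.ind = TRUE)
    if (nrow(hit))
      cand <- data.frame(ia = usable[hit[, 1]], ib = hit[, 2],
                         resid = d[hit])
  }
  if (is.null(cand) || nrow(cand) == 0) {
    attr(empty, "n_skipped") <- sum(skipped)
    return(empty)
  }
  cand <- cand[order(cand$resid), ]
  used_a <- logical(nrow(set_a)); used_b <- logical(nrow(set_b))
  take <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ia <- cand$ia[k]; ib <- cand$ib[k]
    if (!used_a[ia] && !used_b[ib]) {
      take[k] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
    }
  }
  m <- cand[take, ]
  df <- data.frame(
    x_px = (set_a$x_px[m$ia] + set_b$x_px[m$ib]) / 2,
    y_px = (set_a$y_px[m$ia] + set_b$y_px[m$ib]) / 2,
    dx_px = set_b$x_px[m$ib] - set_a$x_px[m$ia],
    dy_px = set_b$y_px[m$ib] - set_a$y_px[m$ia],
    residual_px = m$resid, ia = m$ia, ib = m$ib)
  structure(df, class = c("vector_set", "data.frame"),
            n_unmatched_a = sum(!used_a & !skipped),
            n_unmatched_b = sum(!used_b),
            n_skipped = sum(skipped))
}

#' PIV-assisted PTV over a whole burst
#'
#' Runs, for every consecutive frame pair, cross-correlation PIV (validated by
#' the normalized median test), particle detection, and predictor-assisted
#' matching, pooling the per-pair vectors with their frame-pair provenance.
#' Displacements are converted to velocities with the sequence calibration
#' (pixel pitch x frame rate).
#'
#' @param sequence An [image_sequence()] with >= 2 frames.
#' @param piv A [piv_config()].
#' @param detect A [detect_config()].
#' @param radius PTV search radius around the projection, px.
#' @param droplet Optional [droplet_spec()] (defaults to the sequence scene's
#'   drop) used to mask the drop footprint for PIV and detection.
#' @param validate_threshold Normalized-median threshold for PIV validation.
#' @return A `vector_set` data.frame with columns `pair, x_px, y_px,
#'   x_um, y_um, dx_px, dy_px, u_um_s, v_um_s, residual_px`. Attributes:
#'   `pixel_pitch`, `frame_rate`, `n_detected` (per frame), `pair_log`.
#' @export
vectors_from_burst <- function(sequence, piv = piv_config(),
                               detect = detect_config(), radius = 3,
                               droplet = NULL, validate_threshold = 2) {
  stopifnot(inherits(sequence, "image_sequence"))
  n <- length(sequence$frames)
  if (n < 2) stop("a burst needs at least 2 frames")
  if (is.null(droplet) && !is.null(sequence$scene))
    droplet <- sequence$scene$droplet
  pitch <- sequence$pixel_pitch
  rate <- 1 / sequence$frame_interval
  mask <- mask_det <- NULL
  if (!is.null(droplet)) {
    # PIV exclusion is dilated well past the drop edge: the static dark rim
    # otherwise anchors overlapping windows at zero displacement
    mask <- drop_pixel_mask(dim(sequence$frames[[1]]), droplet, pitch,
                            dilate_um = 6)
    # detection exclusion extends past the rendered rim and the band-pass
    # support so rim gradients are not picked up as particles
    mask_det <- drop_pixel_mask(dim(sequence$frames[[1]]), droplet, pitch,
                                dilate_um = (detect$sigma_wide + 2) * pitch)
  }

  sets <- lapply(sequence$frames, detect_particles, config = detect,
                 mask = mask_det)
  pair_out <- vector("list", n - 1)
  pair_log <- data.frame(pair = seq_len(n - 1), n_vectors = 0L,
                         n_skipped = 0L, note = "")
  for (p in seq_len(n - 1)) {
    res <- tryCatch({
      fld <- correlate_pair(sequence$frames[[p]], sequence$frames[[p + 1]],
                            piv, mask = mask)
      fld <- validate_field(fld, validate_threshold)
      match_particles(sets[[p]], sets[[p + 1]], fld, radius)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      pair_log$note[p] <- conditionMessage(res)
      next
    }
    pair_log$n_vectors[p] <- nrow(res)
    pair_log$n_skipped[p] <- attr(res, "n_skipped")
    if (nrow(res)) {
      res$pair <- p
      pair_out[[p]] <- res
    }
  }
  pooled <- do.call(rbind, pair_out[!vapply(pair_out, is.null, TRUE)])
  if (is.null(pooled))
    pooled <- data.frame(x_px = numeric(0), y_px = numeric(0),
                         dx_px = numeric(0), dy_px = numeric(0),
                         residual_px = numeric(0), ia = integer(0),
                         ib = integer(0), pair = integer(0))
  pooled$x_um <- pooled$x_px * pitch
  pooled$y_um <- pooled$y_px * pitch
  pooled$u_um_s <- pooled$dx_px * pitch * rate
  pooled$v_um_s <- pooled$dy_px * pitch * rate
  cols <- c("pair", "x_px", "y_px", "x_um", "y_um", "dx_px", "dy_px",
            "u_um_s", "v_um_s", "residual_px", "ia", "ib")
  structure(pooled[, cols], class = c("vector_set", "data.frame"),
            pixel_pitch = pitch, frame_rate = rate,
            n_detected = vapply(sets, nrow, integer(1)), pair_log = pair_log)
}

#' Write / read pooled PTV vectors as delimited text
#' @param vectors A `vector_set`.
#' @param path Output TSV path.
#' @export
write_vectors <- function(vectors, path) {
  write.table(as.data.frame(vectors), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vectors
#' @export
read_vectors <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(df, class = c("vector_set", "data.frame"))
}
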