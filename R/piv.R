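#' PIV configuration
#'
#' Parameters for window-based cross-correlation PIV. Defaults follow standard
#' micro-PIV practice at this seeding density: 32 px windows with 50% overlap
#' and a +/- 8 px search range (free-stream displacement here is ~3 px/frame).
#'
#' @param window Square interrogation window side in px (power of two >= 16).
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @param search Search margin in px around zero displacement.
#' @param subpixel `"gaussian3pt"` (with parabolic fallback when a neighbor
#'   correlation value is non-positive) or `"parabolic"`.
#' @param min_peak_ratio Minimum primary/secondary correlation peak ratio for
#'   a node to be accepted (> 1).
#' @return An object of class `piv_config`.
#' @export
piv_config <- function(window = 32, overlap = 0.5, search = 8,
                       subpixel = c("gaussian3pt", "parabolic"),
                       min_peak_ratio = 1.2) {
  subpixel <- match.arg(subpixel)
  if (window < 16 || bitwAnd(window, window - 1L) != 0)
    stop("window must be a power of two >= 16")
  stopifnot(overlap >= 0, overlap < 1, search >= 2, min_peak_ratio > 1)
  structure(list(window = as.integer(window), overlap = overlap,
                 search = as.integer(search), subpixel = subpixel,
                 min_peak_ratio = min_peak_ratio),
            class = "piv_config")
}

# Logical drop-footprint mask (TRUE inside) on the pixel lattice of an image.
drop_pixel_mask <- function(dim_img, droplet, pitch, dilate_um = 0) {
  xc <- (seq_len(dim_img[2]) - 0.5) * pitch - droplet$center[1]
  yc <- (seq_len(dim_img[1]) - 0.5) * pitch - droplet$center[2]
  outer(yc^2, xc^2, `+`) < (droplet$diameter / 2 + dilate_um)^2
}

#' Cross-correlate a frame pair into a coarse PIV field
#'
#' Each interrogation window is mean-subtracted and cross-correlated against
#' the matching (margin-extended) window of the second frame by direct spatial
#' correlation over the search range; the displacement is the correlation-peak
#' location plus a 3-point subpixel fit, and the peak ratio is
#' primary/secondary peak with a 3x3 exclusion zone. All-constant windows
#' yield a masked node (degenerate correlation), not an error. Windows with
#' more than half their pixels inside `mask` (e.g. the drop footprint) are
#' masked a priori.
#'
#' @param frame_a,frame_b Numeric matrices of equal dimensions, larger than
#'   one window.
#' @param config A [piv_config()].
#' @param mask Optional logical matrix (TRUE = excluded pixels).
#' @return An object of class `piv_field`: node coordinate vectors `x`, `y`
#'   (px, window centers), matrices `dx`, `dy` (px/frame, `NA` at masked
#'   nodes), `peak_ratio`, logical `valid` and `masked`, plus `window`/`step`.
#' @export
correlate_pair <- function(frame_a, frame_b, config = piv_config(),
                           mask = NULL) {
  stopifnot(is.matrix(frame_a), identical(dim(frame_a), dim(frame_b)))
  win <- config$window
  if (any(dim(frame_a) < win)) stop("frames must exceed one window")
  step <- max(1L, as.integer(round(win * (1 - config$overlap))))
  use_mask <- !is.null(mask)
  if (!use_mask) mask <- matrix(FALSE, 1, 1)
  res <- piv_correlate_cpp(frame_a, frame_b, win, step, config$search,
                           config$min_peak_ratio,
                           if (config$subpixel == "gaussian3pt") 0L else 1L,
                           mask, use_mask, 0.5)
  nwx <- ncol(res$dx); nwy <- nrow(res$dx)
  structure(list(
    x = (seq_len(nwx) - 1) * step + win / 2,
    y = (seq_len(nwy) - 1) * step + win / 2,
    dx = res$dx, dy = res$dy, peak_ratio = res$peak_ratio,
    valid = res$valid, masked = res$masked,
    interpolated = matrix(FALSE, nwy, nwx),
    window = win, step = step), class = "piv_field")
}

shift_mat <- function(m, di, dj, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

#' Validate a PIV field by the normalized median test
#'
#' Applies the universal outlier (normalized median) test over each node's
#' 8-neighborhood: the residual of a node's displacement from the neighborhood
#' median, normalized by the median neighbor residual plus a noise floor of
#' 0.1 px, must not exceed `threshold`. Outliers are masked; masked interior
#' nodes with at least 3 valid neighbors are refilled with the neighborhood
#' median and flagged `interpolated`.
#'
#' @param field A [correlate_pair()] result.
#' @param threshold Normalized residual threshold (default 2).
#' @return The validated `piv_field`.
#' @export
validate_field <- function(field, threshold = 2) {
  stopifnot(inherits(field, "piv_field"))
  if (length(field$dx) == 0) stop("empty PIV field")
  eps0 <- 0.1
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  get_neigh <- function(m) {
    arr <- array(NA_real_, c(dim(m), nrow(offs)))
    for (k in seq_len(nrow(offs)))
      arr[, , k] <- shift_mat(m, offs$di[k], offs$dj[k])
    arr
  }
  dxv <- field$dx; dxv[!field$valid] <- NA
  dyv <- field$dy; dyv[!field$valid] <- NA
  nx <- get_neigh(dxv); ny <- get_neigh(dyv)
  med_dx <- apply(nx, c(1, 2), median, na.rm = TRUE)
  med_dy <- apply(ny, c(1, 2), median, na.rm = TRUE)
  rx <- abs(sweep(nx, c(1, 2), med_dx)); ry <- abs(sweep(ny, c(1, 2), med_dy))
  rmed <- apply(sqrt(rx^2 + ry^2), c(1, 2), median, na.rm = TRUE)
  resid <- sqrt((dxv - med_dx)^2 + (dyv - med_dy)^2) / (rmed + eps0)
  bad <- field$valid & !is.na(resid) & resid > threshold
  out <- field
  out$valid[bad] <- FALSE
  out$dx[bad] <- NA; out$dy[bad] <- NA

  # refill interior holes (outlier-masked or correlation-failed, not a priori
  # masked) with the neighborhood median of surviving vectors
  dxv <- out$dx; dxv[!out$valid] <- NA
  dyv <- out$dy; dyv[!out$valid] <- NA
  nx <- get_neigh(dxv); ny <- get_neigh(dyv)
  nvalid <- apply(!is.na(nx), c(1, 2), sum)
  fill <- !out$valid & !out$masked & nvalid >= 3
  if (any(fill)) {
    med_dx <- apply(nx, c(1, 2), median, na.rm = TRUE)
    med_dy <- apply(ny, c(1, 2), median, na.rm = TRUE)
    out$dx[fill] <- med_dx[fill]
    out$dy[fill] <- med_dy[fill]
    out$valid[fill] <- TRUE
    out$interpolated[fill] <- TRUE
  }
  out
}

#' Bilinearly interpolate a PIV field at pixel positions
#'
#' @param field A `piv_field` (ideally validated).
#' @param x_px,y_px Pixel coordinates.
#' @return A 2-column matrix of predicted displacements (px/frame).
#'   Coordinates beyond the node lattice are clamped to its hull (constant
#'   extrapolation); where a supporting node is invalid the nearest valid
#'   node within two lattice steps is used instead; rows where no valid node
#'   is that close are `NA` (predictor undefined, e.g. deep inside the drop
#'   mask).
#' @export
interp_field <- function(field, x_px, y_px) {
  stopifnot(inherits(field, "piv_field"))
  step <- field$step
  nx <- length(field$x); ny <- length(field$y)
  gx <- pmin(pmax((x_px - field$x[1]) / step + 1, 1), nx)
  gy <- pmin(pmax((y_px - field$y[1]) / step + 1, 1), ny)
  j0 <- pmin(floor(gx), nx - 1); i0 <- pmin(floor(gy), ny - 1)
  fx <- gx - j0; fy <- gy - i0
  out <- matrix(NA_real_, length(x_px), 2)
  idx <- function(i, j) (j - 1) * ny + i
  for (comp in 1:2) {
    m <- if (comp == 1) field$dx else field$dy
    m[!field$valid] <- NA
    v00 <- m[idx(i0, j0)];     v01 <- m[idx(i0, j0 + 1)]
    v10 <- m[idx(i0 + 1, j0)]; v11 <- m[idx(i0 + 1, j0 + 1)]
    out[, comp] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                   fy * ((1 - fx) * v10 + fx * v11)
  }
  holes <- which(!is.finite(out[, 1]) | !is.finite(out[, 2]))
  if (length(holes)) {
    vi <- which(field$valid, arr.ind = TRUE)
    if (nrow(vi)) {
      for (k in holes) {
        d2 <- (vi[, 2] - gx[k])^2 + (vi[, 1] - gy[k])^2
        b <- which.min(d2)
        if (d2[b] <= 4) {                  # within two lattice steps
          out[k, 1] <- field$dx[vi[b, 1], vi[b, 2]]
          out[k, 2] <- field$dy[vi[b, 1], vi[b, 2]]
        }
      }
    }
  }
  out
}

#' Write / read a PIV field as delimited text
#'
#' Columns: `x_px, y_px, dx_px, dy_px, valid, peak_ratio, interpolated`.
#' @param field A `piv_field`.
#' @param path Output path (TSV).
#' @export
write_piv_field <- function(field, path) {
  g <- expand.grid(y = seq_along(field$y), x = seq_along(field$x))
  df <- data.frame(x_px = field$x[g$x], y_px = field$y[g$y],
                   dx_px = field$dx[cbind(g$y, g$x)],
                   dy_px = field$dy[cbind(g$y, g$x)],
                   valid = field$valid[cbind(g$y, g$x)],
                   peak_ratio = field$peak_ratio[cbind(g$y, g$x)],
                   interpolated = field$interpolated[cbind(g$y, g$x)])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
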