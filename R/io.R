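#' Run configuration
#'
#' Flat key-value configuration for the three pipelines (simulate,
#' velocimetry, morphometrics). Derived quantities (pixel pitch, Reynolds
#' number) are always recomputed from these primitives, never stored.
#' Unknown keys are rejected.
#'
#' @param ... Key = value overrides of [default_run_config()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  with(cfg, {
    stopifnot(fov_um > 0, sensor_px >= 64, frame_rate > 0,
              drop_diameter_um > 0, fluid_viscosity > 0,
              u_free_um_s != 0, n_frames >= 2, n_tracers >= 1,
              grid_spacing_px >= 1, grid_order %in% c(1, 2))
  })
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
default_run_config <- function() {
  list(
    # calibration
    fov_um = 720, sensor_px = 1024, frame_rate = 1000,
    timelapse_interval_s = 30,
    # droplet and fluid
    drop_diameter_um = 150, drop_center_x_um = 360, drop_center_y_um = 360,
    oil_density = 850, fluid_density = 1000, fluid_viscosity = 1e-3,
    u_free_um_s = 2000,
    # simulation
    flow_model = "potential_past_circle", n_frames = 1000, n_tracers = 600,
    background = 120, noise_sd = 8, peak_intensity = 2000, psf_sigma_um = 0.7,
    diffusivity_um2_s = 0,
    # PIV / PTV
    piv_window = 32, piv_overlap = 0.5, piv_search = 8,
    piv_min_peak_ratio = 1.2, detect_sigma_narrow = 1, detect_sigma_wide = 2.5,
    match_radius_px = 3,
    # gridding
    grid_spacing_px = 4, grid_order = 2, grid_radius_factor = 3,
    # morphometrics
    morpho_bins = 72, morpho_z_thresh = 2, flow_dir_deg = 0,
    # reproducibility
    seed = 1)
}

#' Read / write a run configuration as flat key-value text
#'
#' Lines are `key = value`; `#` starts a comment. Unknown keys are rejected
#' with the offending key named.
#'
#' @param path File path.
#' @param cfg A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3]
  if (length(bad)) stop("malformed config line: ", bad[1])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  defaults <- default_run_config()
  parsed <- lapply(seq_along(keys), function(i) {
    if (is.character(defaults[[keys[i]]])) vals[i]
    else {
      x <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(x)) vals[i] else x
    }
  })
  do.call(run_config, stats::setNames(parsed, keys))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(v)
    if (is.character(v)) v else sprintf("%.12g", v), "")
  writeLines(sprintf("%s = %s", names(cfg), fmt), path)
  invisible(path)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' @param x An [image_sequence()] or list of numeric matrices (counts).
#' @param path TIFF path.
#' @export
write_stack <- function(x, path) {
  frames <- if (inherits(x, "image_sequence")) x$frames else x
  tiff::writeTIFF(lapply(frames, function(f) f / 65535),
                  path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_pitch,frame_interval,kind Calibration attached to the
#'   restored sequence.
#' @export
read_stack <- function(path, pixel_pitch, frame_interval,
                       kind = c("burst", "timelapse")) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    m <- if (length(dim(p)) == 3) p[, , 1] else p
    storage.mode(m) <- "double"
    m
  })
  image_sequence(frames, pixel_pitch, frame_interval, match.arg(kind))
}

#' Write a manifest of output files with checksums
#'
#' @param dir Run directory.
#' @param files Character vector of file names relative to `dir`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, files) {
  sums <- tools::md5sum(file.path(dir, files))
  df <- data.frame(file = files, md5 = unname(sums))
  path <- file.path(dir, "manifest.txt")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_keyvalue <- function(x, path) {
  fmt <- vapply(x, function(v)
    if (is.character(v)) v else sprintf("%.12g", v), "")
  writeLines(sprintf("%s = %s", names(x), fmt), path)
  invisible(path)
}
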