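#' sCMOS noise model
#'
#' Standard sCMOS abstraction: Poisson shot noise on the expected photon
#' count, Gaussian read noise (in electrons), a fixed digitizer offset and
#' a linear gain. Setting the model to `NULL` in the renderer disables
#' noise entirely (expected counts are returned).
#'
#' @param photon_flux Photons per emitter-unit per millisecond of dwell.
#' @param read_noise_sd Read noise standard deviation, electrons.
#' @param offset Digitizer offset, counts.
#' @param gain Counts per electron (and per photon; unit quantum
#'   efficiency is absorbed into `photon_flux`).
#' @param seed RNG seed for reproducible frames; `NULL` uses the current
#'   RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_flux = 50, read_noise_sd = 1.6, offset = 100,
                        gain = 1, seed = NULL) {
  check_nonnegative(photon_flux, "photon_flux")
  check_nonnegative(read_noise_sd, "read_noise_sd")
  check_nonnegative(offset, "offset")
  check_positive(gain, "gain")
  structure(list(photon_flux = photon_flux, read_noise_sd = read_noise_sd,
                 offset = offset, gain = gain, seed = seed),
            class = "noise_model")
}

# Axial weight sigma (um) per detector row: waist offset from the row at its
# activation midpoint, mapped through the sheet-thickness curve.
row_axial_sigma <- function(psf, schedule, trajectory, pixel_um) {
  cfg <- attr(schedule, "config")
  if (is.null(trajectory)) {
    off <- rep(0, nrow(schedule))
  } else {
    tm <- (schedule$t_on + schedule$t_off) / 2
    off <- numeric(nrow(schedule))
    for (s in unique(schedule$shutter)) {
      i <- schedule$shutter == s
      off[i] <- waist_row_at(trajectory, tm[i], s) - schedule$row[i]
    }
  }
  fw <- sheet_thickness_at(psf$sheet_profile, off * pixel_um)
  fw / FWHM_PER_SIGMA
}

#' Render a single camera frame from a phantom
#'
#' Image formation per detector row: the row collects photons for its
#' dwell time (`A*T/R`), from the phantom plane at the current focal depth,
#' blurred laterally by the detection PSF and weighted axially by the
#' sheet thickness at the waist-to-row offset of that row (so a
#' desynchronised trajectory thickens the recorded optical section).
#' Counts are `Poisson(expected) * gain + N(0, read_sd * gain) + offset`,
#' clipped to 16 bits.
#'
#' Phantoms carrying a point-emitter list are rendered analytically
#' (separable Gaussian PSF evaluated at pixel centers), which avoids
#' voxelisation broadening; volume phantoms are rendered from the grid.
#'
#' @param phantom A [phantom()].
#' @param psf A `system_psf` from [make_system_psf()].
#' @param schedule A [row_schedule()]; its config defines rows and mode.
#' @param trajectory Optional [focus_trajectory()]; `NULL` means perfect
#'   synchronization.
#' @param noise A [noise_model()], or `NULL` for noise-free expected
#'   counts (gain and offset of an implicit ideal camera: gain 1,
#'   offset 0).
#' @param z_plane_um Focal-plane depth, micrometres from the phantom z
#'   face.
#' @return A numeric matrix of class `ls_frame` (rows x cols) with
#'   acquisition metadata attributes.
#' @export
render_frame <- function(phantom, psf, schedule, trajectory = NULL,
                         noise = NULL, z_plane_um = 0) {
  if (!inherits(phantom, "phantom")) stop_contract("phantom must be a phantom")
  if (!inherits(psf, "system_psf")) stop_contract("psf must be a system_psf")
  if (!inherits(schedule, "row_schedule")) stop_contract("schedule must be a row_schedule")
  cfg <- attr(schedule, "config")
  if (phantom$dims[1] != cfg$total_rows)
    stop_contract("phantom row count (", phantom$dims[1],
                  ") must equal the configured total_rows (", cfg$total_rows, ")")
  pixel_um <- phantom$voxel_um
  n_rows <- phantom$dims[1]; n_cols <- phantom$dims[2]; n_z <- phantom$dims[3]
  dwell <- schedule$t_off - schedule$t_on
  sig_z <- row_axial_sigma(psf, schedule, trajectory, pixel_um)
  flux <- if (is.null(noise)) 1 else noise$photon_flux

  has_emitters <- !is.null(phantom$emitters) && nrow(phantom$emitters) > 0
  expected <- matrix(0, n_rows, n_cols)

  if (!is.null(phantom$volume)) {
    zc <- (seq_len(n_z) - 0.5) * pixel_um
    volmat <- matrix(phantom$volume, n_rows * n_cols, n_z)
    sig_key <- round(sig_z, 9)
    for (sk in unique(sig_key)) {
      rows_i <- which(sig_key == sk)
      w <- exp(-(zc - z_plane_um)^2 / (2 * sk^2))
      sw <- sum(w)
      w <- if (sw > 0) w / sw else w
      plane <- matrix(volmat %*% w, n_rows, n_cols)
      expected[rows_i, ] <- plane[rows_i, , drop = FALSE]
    }
    sig_lat_px <- psf$fwhm_x / FWHM_PER_SIGMA / pixel_um
    if (sig_lat_px > 0.05) expected <- gaussian_blur_2d(expected, sig_lat_px)
  }

  if (has_emitters) {
    em <- phantom$emitters
    sig_lat <- psf$fwhm_x / FWHM_PER_SIGMA
    rc <- (seq_len(n_rows) - 0.5) * pixel_um
    cc <- (seq_len(n_cols) - 0.5) * pixel_um
    for (e in seq_len(nrow(em))) {
      gr <- stats::dnorm(rc, em$row_um[e], sig_lat) * pixel_um
      gc <- stats::dnorm(cc, em$col_um[e], sig_lat) * pixel_um
      wz <- exp(-(em$z_um[e] - z_plane_um)^2 / (2 * sig_z^2))
      expected <- expected + em$amplitude[e] * outer(gr * wz, gc)
    }
  }

  expected <- expected * dwell * flux

  if (is.null(noise)) {
    counts <- expected
  } else {
    n <- length(expected)
    counts <- with_seed(noise$seed, {
      shot <- stats::rpois(n, lambda = as.vector(expected))
      read <- if (noise$read_noise_sd > 0)
        stats::rnorm(n, 0, noise$read_noise_sd * noise$gain) else 0
      round(shot * noise$gain + read + noise$offset)
    })
    counts <- matrix(counts, n_rows, n_cols)
  }
  if (any(counts > 65535)) {
    warning("frame saturates the 16-bit range; clipping")
    counts[counts > 65535] <- 65535
  }
  counts[counts < 0] <- 0
  structure(counts, class = c("ls_frame", class(counts)),
            mode = cfg$mode, exposure_ms = cfg$exposure_ms,
            z_plane_um = z_plane_um, pixel_um = pixel_um)
}

#' Acquire a z-stack of frames
#'
#' Renders `n_planes` frames while stepping the focal plane axially with a
#' step equal to the lateral pixel size (isotropic voxels), mirroring
#' stage-stepped stack acquisition. Stack acquisition time is
#' `n_planes * (exposure + flyback)`.
#'
#' @inheritParams render_frame
#' @param cfg A [shutter_config()].
#' @param n_planes Number of z planes.
#' @param z_start_um First plane depth; default centers the stack on the
#'   phantom's z midpoint.
#' @param z_step_um Plane spacing; default `pixel_size` of the PSF's
#'   optical config.
#' @return A 3D array of class `ls_stack` (rows x cols x planes) with
#'   attributes `z_um`, `pixel_um`, `z_step_um`, `exposure_ms`, `mode` and
#'   `acquisition_time_ms`.
#' @export
acquire_stack <- function(phantom, psf, cfg, noise = NULL, n_planes,
                          trajectory = NULL, z_start_um = NULL,
                          z_step_um = NULL) {
  if (n_planes < 1L) stop_invalid("n_planes must be >= 1")
  if (is.null(z_step_um)) z_step_um <- pixel_size(psf$config)
  if (is.null(z_start_um)) {
    z_mid <- phantom$dims[3] * phantom$voxel_um / 2
    z_start_um <- z_mid - (n_planes - 1) / 2 * z_step_um
  }
  schedule <- row_schedule(cfg)
  z_um <- z_start_um + (seq_len(n_planes) - 1) * z_step_um
  render_one <- function(z, nm) render_frame(phantom, psf, schedule, trajectory, nm, z)
  stack <- with_seed(if (is.null(noise)) NULL else noise$seed, {
    nm <- noise
    if (!is.null(nm)) nm$seed <- NULL  # one seeded stream for the whole stack
    vapply(z_um, render_one, matrix(0, phantom$dims[1], phantom$dims[2]), nm = nm)
  })
  structure(stack, class = c("ls_stack", class(stack)),
            z_um = z_um, pixel_um = phantom$voxel_um, z_step_um = z_step_um,
            exposure_ms = cfg$exposure_ms, mode = cfg$mode,
            acquisition_time_ms = n_planes * (cfg$exposure_ms + cfg$flyback_ms))
}

#' Signal-to-noise ratio of a frame or stack
#'
#' `SNR = (mean(foreground) - mean(background)) / sd(background)`.
#'
#' @param x Numeric matrix/array of counts.
#' @param foreground_mask,background_mask Logical masks of the same shape
#'   as `x` (or index vectors); must be disjoint and nonempty.
#' @return SNR (dimensionless).
#' @export
snr <- function(x, foreground_mask, background_mask) {
  fg_idx <- if (is.logical(foreground_mask)) which(foreground_mask) else as.integer(foreground_mask)
  bg_idx <- if (is.logical(background_mask)) which(background_mask) else as.integer(background_mask)
  if (length(fg_idx) == 0 || length(bg_idx) == 0)
    stop_contract("foreground and background masks must be nonempty")
  if (length(intersect(fg_idx, bg_idx)) > 0)
    stop_contract("foreground and background masks must be disjoint")
  sd_bg <- stats::sd(x[bg_idx])
  if (!is.finite(sd_bg) || sd_bg == 0)
    stop_contract("background standard deviation is zero; SNR undefined")
  (mean(x[fg_idx]) - mean(x[bg_idx])) / sd_bg
}

#' Swept-focus synchronization test image
#'
#' Renders the camera snapshot of a swept 2D focus at a moment during the
#' exposure: only rows inside each shutter's active window record the
#' focus, so an in-sync sweep shows a sharp bright line (one per focus)
#' spanning every column with vertical extent at most the active window,
#' while a desynchronised focus falls outside the window and the recorded
#' intensity collapses.
#'
#' @param cfg A [shutter_config()].
#' @param lag_rows Trajectory lag in rows (0 = perfect sync).
#' @param n_cols Number of columns to render (default `total_rows`).
#' @param focus_fwhm_rows Vertical FWHM of the focal line, rows.
#' @param amplitude Peak focus intensity, counts.
#' @param offset Background offset, counts.
#' @param frac Snapshot time as a fraction of the exposure ramp.
#' @return An `ls_frame` matrix.
#' @export
sweep_line_test <- function(cfg, lag_rows = 0, n_cols = NULL,
                            focus_fwhm_rows = 4, amplitude = 1000,
                            offset = 100, frac = 0.5) {
  if (!inherits(cfg, "shutter_config")) stop_contract("cfg must be a shutter_config")
  if (is.null(n_cols)) n_cols <- cfg$total_rows
  R <- rows_per_shutter(cfg)
  A <- cfg$active_rows
  n_shutters <- if (cfg$mode == "dual") 2L else 1L
  sig <- focus_fwhm_rows / FWHM_PER_SIGMA
  lead <- R * frac
  col_profile <- rep(0, cfg$total_rows)
  for (s in seq_len(n_shutters)) {
    base <- (s - 1L) * R
    active_local <- seq(max(0L, floor(lead - A) + 1L), min(R - 1L, floor(lead)))
    center <- base + lead - A / 2 - lag_rows
    rows_g <- base + active_local
    col_profile[rows_g + 1L] <- col_profile[rows_g + 1L] +
      amplitude * exp(-(rows_g - center)^2 / (2 * sig^2))
  }
  out <- matrix(col_profile, cfg$total_rows, n_cols) + offset
  structure(out, class = c("ls_frame", "matrix", "array"),
            mode = cfg$mode, exposure_ms = cfg$exposure_ms,
            lag_rows = lag_rows, offset = offset)
}
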