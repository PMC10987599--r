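#' Optical configuration for the light-sheet system
#'
#' Bundles the illumination and detection parameters that define pixel
#' scaling, field of view and the system point spread function (PSF).
#'
#' The default illumination NA is back-solved so that the Gaussian sheet
#' waist has a FWHM of `detection_lateral_fwhm_um` (0.97 um) at the default
#' wavelength; it is a calibration to the measured system resolution, not a
#' first-principles value. The magnification of the multi-immersion
#' detection path scales linearly with the immersion refractive index (RI),
#' anchored at the measured 15.28x in water (RI 1.33).
#'
#' @param wavelength_um Illumination vacuum wavelength in micrometres.
#' @param illumination_na Illumination numerical aperture. `NULL` (default)
#'   back-solves the NA so the sheet-waist FWHM equals
#'   `detection_lateral_fwhm_um`.
#' @param immersion_ri Immersion-medium refractive index, in `[1.0, 1.6]`.
#' @param camera_pitch_um Physical camera pixel pitch in micrometres
#'   (6.5 um for the Orca Flash 4.0 class of sCMOS).
#' @param ref_magnification Measured magnification at `ref_ri`.
#' @param ref_ri Refractive index at which `ref_magnification` was measured.
#' @param detection_lateral_fwhm_um Lateral FWHM of the detection PSF in
#'   micrometres.
#' @param chip_rows,chip_cols Camera chip dimensions in pixels.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' pixel_size(cfg)            # 0.425 um in water
#' fov_extent(cfg)            # ~870 um
#' @export
optical_config <- function(wavelength_um = 0.488,
                           illumination_na = NULL,
                           immersion_ri = 1.33,
                           camera_pitch_um = 6.5,
                           ref_magnification = 15.28,
                           ref_ri = 1.33,
                           detection_lateral_fwhm_um = 0.97,
                           chip_rows = 2048L,
                           chip_cols = 2048L) {
  check_positive(wavelength_um, "wavelength_um")
  check_positive(camera_pitch_um, "camera_pitch_um")
  check_positive(ref_magnification, "ref_magnification")
  check_positive(detection_lateral_fwhm_um, "detection_lateral_fwhm_um")
  if (immersion_ri < 1.0 || immersion_ri > 1.6)
    stop_invalid("immersion_ri must lie in [1.0, 1.6]")
  if (ref_ri < 1.0 || ref_ri > 1.6)
    stop_invalid("ref_ri must lie in [1.0, 1.6]")
  if (chip_rows <= 0 || chip_cols <= 0)
    stop_invalid("chip dimensions must be positive")
  if (is.null(illumination_na)) {
    # calibration: waist FWHM == detection_lateral_fwhm_um at this wavelength
    w0 <- detection_lateral_fwhm_um / sqrt(2 * log(2))
    illumination_na <- wavelength_um / (pi * w0)
  }
  if (illumination_na <= 0 || illumination_na >= immersion_ri)
    stop_invalid("illumination_na must satisfy 0 < NA < immersion_ri")
  structure(list(
    wavelength_um = wavelength_um,
    illumination_na = illumination_na,
    immersion_ri = immersion_ri,
    camera_pitch_um = camera_pitch_um,
    ref_magnification = ref_magnification,
    ref_ri = ref_ri,
    detection_lateral_fwhm_um = detection_lateral_fwhm_um,
    chip_rows = as.integer(chip_rows),
    chip_cols = as.integer(chip_cols)
  ), class = "optical_config")
}

#' Gaussian light-sheet beam waist
#'
#' Computes the sheet-waist profile from the illumination NA using the
#' standard Gaussian-beam relations `w0 = lambda / (pi * NA)` and
#' `zR = pi * w0^2 * n / lambda`.
#'
#' @param illumination_na Illumination numerical aperture (0 < NA < 1).
#' @param wavelength_um Vacuum wavelength in micrometres.
#' @param immersion_ri Refractive index of the medium (for the Rayleigh
#'   range).
#' @return An object of class `sheet_profile` with fields `waist_radius_w0`,
#'   `rayleigh_range_zr` and `waist_fwhm` (all micrometres).
#' @examples
#' beam_waist(0.3, 0.488)$waist_radius_w0   # ~0.518 um
#' @export
beam_waist <- function(illumination_na, wavelength_um, immersion_ri = 1.33) {
  check_positive(wavelength_um, "wavelength_um")
  if (!is.numeric(illumination_na) || illumination_na <= 0 || illumination_na >= 1)
    stop_invalid("illumination_na must lie in (0, 1)")
  w0 <- wavelength_um / (pi * illumination_na)
  structure(list(
    waist_radius_w0 = w0,
    rayleigh_range_zr = rayleigh_range(w0, wavelength_um, immersion_ri),
    waist_fwhm = sqrt(2 * log(2)) * w0
  ), class = "sheet_profile")
}

#' Rayleigh range of a Gaussian beam
#'
#' @param w0_um Beam waist radius in micrometres.
#' @param wavelength_um Vacuum wavelength in micrometres.
#' @param immersion_ri Medium refractive index.
#' @return Rayleigh range in micrometres.
#' @export
rayleigh_range <- function(w0_um, wavelength_um, immersion_ri = 1.33) {
  check_positive(w0_um, "w0_um")
  check_positive(wavelength_um, "wavelength_um")
  check_positive(immersion_ri, "immersion_ri")
  pi * w0_um^2 * immersion_ri / wavelength_um
}

#' Sheet thickness away from the waist
#'
#' FWHM thickness of the Gaussian sheet at an axial (propagation) offset
#' from the waist: `w(x) = w0 * sqrt(1 + (x/zR)^2)`, converted to FWHM.
#' Used by the frame renderer to model desynchronisation as axial
#' thickening of the recorded sheet.
#'
#' @param profile A `sheet_profile` from [beam_waist()].
#' @param axial_offset_um Offset from the waist along the propagation axis
#'   (micrometres); the thickness is even in the offset.
#' @return FWHM thickness in micrometres.
#' @export
sheet_thickness_at <- function(profile, axial_offset_um) {
  if (!inherits(profile, "sheet_profile")) stop_contract("profile must be a sheet_profile")
  profile$waist_fwhm * sqrt(1 + (axial_offset_um / profile$rayleigh_range_zr)^2)
}

#' Sample-space pixel size under multi-immersion scaling
#'
#' Magnification scales linearly with immersion RI:
#' `M(ri) = M_ref * ri / ri_ref`; the sample-space pixel is
#' `camera_pitch / M(ri)`. In water (RI 1.33) the measured 15.28x
#' magnification gives a 0.425 um pixel.
#'
#' @param config An `optical_config`.
#' @param ri Immersion refractive index (defaults to the configured one).
#' @return Lateral pixel size in micrometres.
#' @export
pixel_size <- function(config, ri = config$immersion_ri) {
  if (!inherits(config, "optical_config")) stop_contract("config must be an optical_config")
  if (ri < 1.0 || ri > 1.6) stop_invalid("ri must lie in [1.0, 1.6]")
  m <- config$ref_magnification * ri / config$ref_ri
  config$camera_pitch_um / m
}

#' Field-of-view side length
#'
#' @inheritParams pixel_size
#' @return FOV extent along the chip row axis in micrometres
#'   (`chip_rows * pixel_size`).
#' @export
fov_extent <- function(config, ri = config$immersion_ri) {
  config$chip_rows * pixel_size(config, ri)
}

#' Convert a measured FWHM between immersion media
#'
#' A resolution measured in one medium is reported as its equivalent in
#' another via the linear magnification scaling:
#' `fwhm_target = fwhm_measured * ri_measured / ri_target`.
#' The 0.97 um FWHM measured in water (RI 1.33) is equivalent to 0.83 um at
#' RI 1.56.
#'
#' @param fwhm_measured_um Measured FWHM (micrometres).
#' @param ri_measured RI of the medium in which the FWHM was measured.
#' @param ri_target RI to convert to.
#' @return Equivalent FWHM in micrometres.
#' @export
equivalent_fwhm <- function(fwhm_measured_um, ri_measured, ri_target) {
  check_positive(fwhm_measured_um, "fwhm_measured_um")
  check_positive(ri_measured, "ri_measured")
  check_positive(ri_target, "ri_target")
  fwhm_measured_um * ri_measured / ri_target
}

#' Render the system PSF as a normalized 3D Gaussian kernel
#'
#' The system PSF is approximated as a separable 3D Gaussian whose lateral
#' (x, y) FWHM is the detection-path FWHM and whose axial (z) FWHM is the
#' sheet-waist FWHM. With the default calibrated configuration both are
#' 0.97 um, i.e. the PSF is isotropic.
#'
#' @param config An `optical_config`.
#' @param voxel_um Isotropic voxel size of the rendered kernel
#'   (micrometres). Must be at most FWHM/3 for adequate sampling.
#' @param truncate Kernel half-extent in units of sigma.
#' @param check_sampling Set `FALSE` to allow voxels coarser than FWHM/3
#'   (e.g. to match an acquired stack's grid for deconvolution).
#' @return An object of class `system_psf` with fields `fwhm_x`, `fwhm_y`,
#'   `fwhm_z` (micrometres), `kernel` (3D array summing to 1), `voxel_um`
#'   and the underlying `sheet_profile`.
#' @export
make_system_psf <- function(config, voxel_um = 0.2, truncate = 4,
                            check_sampling = TRUE) {
  if (!inherits(config, "optical_config")) stop_contract("config must be an optical_config")
  check_positive(voxel_um, "voxel_um")
  profile <- beam_waist(config$illumination_na, config$wavelength_um,
                        config$immersion_ri)
  fwhm_lat <- config$detection_lateral_fwhm_um
  fwhm_ax <- profile$waist_fwhm
  if (check_sampling && voxel_um > min(fwhm_lat, fwhm_ax) / 3)
    stop_invalid("voxel_um undersamples the PSF: need voxel <= FWHM/3")
  sig <- c(fwhm_lat, fwhm_lat, fwhm_ax) / FWHM_PER_SIGMA / voxel_um
  k1 <- lapply(sig, gaussian_kernel_1d, truncate = truncate)
  kernel <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  kernel <- kernel / sum(kernel)
  structure(list(
    fwhm_x = fwhm_lat, fwhm_y = fwhm_lat, fwhm_z = fwhm_ax,
    kernel = kernel, voxel_um = voxel_um, sheet_profile = profile,
    config = config
  ), class = "system_psf")
}
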