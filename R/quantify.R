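#' Detect bead candidates in a 3D stack
#'
#' Local maxima above an intensity percentile, non-maximum suppressed by a
#' minimum separation and excluded from a margin at the stack faces.
#'
#' @param stack 3D array (rows x cols x planes).
#' @param min_separation_px Minimum center distance between detections,
#'   voxels.
#' @param intensity_percentile Percentile (0-100) of the stack intensity
#'   that candidates must exceed.
#' @param margin_px Margin excluded at each face, voxels.
#' @return Data frame with columns `row`, `col`, `plane` (1-based voxel
#'   indices) and `intensity`, brightest first; may be empty.
#' @export
detect_beads <- function(stack, min_separation_px = 8,
                         intensity_percentile = 99, margin_px = 5L) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L) stop_contract("stack must be a 3D array")
  thr <- stats::quantile(stack, intensity_percentile / 100, names = FALSE)
  cand <- which(stack > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(), col = integer(), plane = integer(),
                      intensity = numeric()))
  inside <- cand[, 1] > margin_px & cand[, 1] <= d[1] - margin_px &
    cand[, 2] > margin_px & cand[, 2] <= d[2] - margin_px &
    cand[, 3] > margin_px & cand[, 3] <= d[3] - margin_px
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(), col = integer(), plane = integer(),
                      intensity = numeric()))
  # local maximum within the 26-neighborhood
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]; p <- cand[i, 3]
    v <- stack[r, c, p]
    v >= max(stack[(r - 1):(r + 1), (c - 1):(c + 1), (p - 1):(p + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  vals <- stack[cand]
  o <- order(vals, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; vals <- vals[o]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    dmin <- min(sqrt(colSums((t(prev) - cand[i, ])^2)))
    keep[i] <- dmin >= min_separation_px
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(row = cand[, 1], col = cand[, 2], plane = cand[, 3],
             intensity = vals[keep])
}

#' Gaussian FWHM fit of a 1D intensity profile
#'
#' Least-squares fit of a four-parameter Gaussian-with-offset
#' (`a * exp(-(x - c)^2 / (2 s^2)) + b`) initialised from moments;
#' `FWHM = 2 sqrt(2 ln 2) s`.
#'
#' @param profile Numeric intensity samples (>= 7, single dominant peak).
#' @param spacing_um Sample spacing in micrometres.
#' @return A list of class `fwhm_fit`: `fwhm_um`, `sigma_um`, `center_um`,
#'   `amplitude`, `baseline`, `r_squared`.
#' @export
fwhm_fit <- function(profile, spacing_um = 1) {
  check_positive(spacing_um, "spacing_um")
  if (length(profile) < 7L) stop_invalid("profile needs at least 7 samples")
  x <- (seq_along(profile) - 1) * spacing_um
  b0 <- min(profile)
  a0 <- max(profile) - b0
  if (a0 <= 0) stop_fit("flat profile")
  w <- pmax(profile - b0, 0)
  c0 <- sum(x * w) / sum(w)
  s0 <- sqrt(sum((x - c0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- spacing_um
  df <- data.frame(x = x, y = profile)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - cc)^2 / (2 * s^2)) + b, data = df,
                      start = list(a = a0, cc = c0, s = s0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) stop_fit(conditionMessage(e)))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((profile - mean(profile))^2)
  structure(list(
    fwhm_um = FWHM_PER_SIGMA * abs(cf[["s"]]),
    sigma_um = abs(cf[["s"]]),
    center_um = cf[["cc"]],
    amplitude = cf[["a"]],
    baseline = cf[["b"]],
    r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  ), class = "fwhm_fit")
}

stop_fit <- function(...) {
  stop(structure(class = c("sweptsheet_fit_failure", "error", "condition"),
                 list(message = paste0("FWHM fit failed: ", ...),
                      call = sys.call(-1))))
}

#' Measure the PSF from a bead stack
#'
#' For each detected bead, extracts axis-aligned intensity profiles
#' through the bead center (sub-voxel center from a local center of mass,
#' sampled by trilinear interpolation) and fits a Gaussian per axis.
#' Reports per-bead FWHMs and the per-axis mean and standard deviation.
#'
#' @param stack 3D array (rows x cols x planes).
#' @param centroids Data frame from [detect_beads()] (or with columns
#'   `row`, `col`, `plane`).
#' @param spacing_um Voxel spacing per axis, length 3 (row, col, plane)
#'   or scalar.
#' @param half_window_px Profile half-length in voxels.
#' @return An object of class `psf_measurement`: `per_bead` (data frame
#'   `bead_id`, `fwhm_x`, `fwhm_y`, `fwhm_z` in micrometres, `r2`),
#'   `mean_um`, `sd_um` (named per axis; sd is `NA` for a single bead) and
#'   `n_beads`.
#' @export
measure_psf <- function(stack, centroids, spacing_um, half_window_px = 8L) {
  d <- dim(stack)
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 3L)
  if (nrow(centroids) == 0L) stop_contract("no centroids supplied")
  rows <- list()
  for (i in seq_len(nrow(centroids))) {
    ctr <- c(centroids$row[i], centroids$col[i], centroids$plane[i])
    # sub-voxel refinement: center of mass in a 5^3 neighborhood
    w <- 2L
    lo <- pmax(ctr - w, 1L); hi <- pmin(ctr + w, d)
    nb <- stack[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    nb0 <- pmax(nb - min(nb), 0)
    gr <- expand.grid(r = lo[1]:hi[1], c = lo[2]:hi[2], p = lo[3]:hi[3])
    com <- colSums(gr * as.vector(nb0)) / sum(nb0)
    fw <- rep(NA_real_, 3); r2 <- rep(NA_real_, 3)
    for (ax in 1:3) {
      offs <- seq(-half_window_px, half_window_px)
      pts <- matrix(rep(com, each = length(offs)), ncol = 3)
      # integer positions along the profiled axis: interpolating along the
      # axis would broaden the profile; orthogonal interpolation only
      # rescales the amplitude of a separable peak
      pts[, ax] <- round(com[ax]) + offs
      if (min(pts[, ax]) < 1 || max(pts[, ax]) > d[ax]) next
      prof <- trilinear(stack, pts)
      ft <- tryCatch(fwhm_fit(prof, spacing_um[ax]), error = function(e) NULL)
      if (!is.null(ft)) { fw[ax] <- ft$fwhm_um; r2[ax] <- ft$r_squared }
    }
    if (all(is.finite(fw)))
      rows[[length(rows) + 1L]] <- data.frame(
        bead_id = i, fwhm_x = fw[2], fwhm_y = fw[1], fwhm_z = fw[3],
        r2 = mean(r2))
  }
  if (length(rows) == 0L) stop_contract("all bead fits failed")
  per_bead <- do.call(rbind, rows)
  m <- colMeans(per_bead[, c("fwhm_x", "fwhm_y", "fwhm_z")])
  s <- if (nrow(per_bead) > 1L)
    vapply(per_bead[, c("fwhm_x", "fwhm_y", "fwhm_z")], stats::sd, numeric(1))
  else c(fwhm_x = NA_real_, fwhm_y = NA_real_, fwhm_z = NA_real_)
  structure(list(per_bead = per_bead, mean_um = m, sd_um = s,
                 n_beads = nrow(per_bead)),
            class = "psf_measurement")
}

#' Maximum-intensity projection of a stack
#'
#' @param stack 3D array.
#' @param n_planes Number of slices (from the start) to project; defaults
#'   to all slices along the chosen axis.
#' @param axis Axis to project along (1 = rows, 2 = cols, 3 = planes).
#' @return 2D matrix of per-pixel maxima.
#' @export
mip <- function(stack, n_planes = NULL, axis = 3L) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L) stop_contract("stack must be a 3D array")
  if (!axis %in% 1:3) stop_contract("axis must be 1, 2 or 3")
  if (is.null(n_planes)) n_planes <- d[axis]
  if (n_planes < 1L || n_planes > d[axis])
    stop_contract("n_planes exceeds the stack depth along that axis")
  sub <- switch(axis,
                stack[seq_len(n_planes), , , drop = FALSE],
                stack[, seq_len(n_planes), , drop = FALSE],
                stack[, , seq_len(n_planes), drop = FALSE])
  apply(sub, setdiff(1:3, axis), max)
}

# FFT-based 3D convolution, 'same' output, zero-padded boundaries.
conv3d_same <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  dp <- dv + dk - 1L
  pv <- array(0, dp); pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(stats::fft(stats::fft(pv) * stats::fft(pk), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) %/% 2L
  full[off[1] + seq_len(dv[1]), off[2] + seq_len(dv[2]), off[3] + seq_len(dv[3])]
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy update with a normalized PSF
#' and boundary correction by PSF-mass renormalisation (convolution with a
#' unit volume), so flux is approximately conserved for interior objects.
#'
#' @param stack 3D array of counts (nonnegative).
#' @param psf A `system_psf` (its `kernel` is used) or a 3D kernel array;
#'   kernel voxel size must match the stack.
#' @param iterations Number of RL iterations (>= 1).
#' @param eps Numerical floor in the ratio denominator.
#' @return Deconvolved 3D array, nonnegative.
#' @export
richardson_lucy <- function(stack, psf, iterations = 20L, eps = 1e-12) {
  kern <- if (inherits(psf, "system_psf")) psf$kernel else psf
  if (is.null(dim(kern)) || length(dim(kern)) != 3L)
    stop_contract("psf kernel must be a 3D array")
  if (sum(kern) <= 0) stop_contract("PSF kernel must have positive mass")
  if (iterations < 1L) stop_invalid("iterations must be >= 1")
  kern <- kern / sum(kern)
  flipped <- kern[rev(seq_len(dim(kern)[1])), rev(seq_len(dim(kern)[2])),
                  rev(seq_len(dim(kern)[3])), drop = FALSE]
  obs <- pmax(stack, 0)
  est <- obs  # standard initialisation: first estimate is the observation
  # edge correction: renormalise both the forward blur and the update by
  # the PSF mass actually inside the volume, so a flat field is a fixed
  # point and flux is conserved for interior objects
  norm_f <- conv3d_same(array(1, dim(obs)), kern)
  norm_f[norm_f < eps] <- 1
  norm_b <- conv3d_same(array(1, dim(obs)), flipped)
  norm_b[norm_b < eps] <- 1
  for (it in seq_len(iterations)) {
    blurred <- conv3d_same(est, kern) / norm_f
    ratio <- obs / pmax(blurred, eps)
    est <- est * conv3d_same(ratio, flipped) / norm_b
    est[est < 0] <- 0
  }
  est
}
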