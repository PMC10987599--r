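#' Construct a phantom object
#'
#' A phantom is a 3D emitter-density volume (rows x cols x planes) with a
#' physical voxel size, optionally carrying a list of point emitters. When
#' emitters are present the frame renderer evaluates them analytically
#' (exact separable-Gaussian image formation); otherwise it renders from
#' the voxel grid.
#'
#' @param volume 3D numeric array of nonnegative emitter density, or `NULL`
#'   for a pure emitter-list phantom (then `dims` must be given).
#' @param voxel_um Voxel size in micrometres (scalar, isotropic laterally;
#'   the renderer uses it for both lateral pixels and z spacing).
#' @param emitters Optional data frame with columns `row_um`, `col_um`,
#'   `z_um`, `amplitude` (positions in micrometres from the volume corner).
#' @param dims Integer vector `c(rows, cols, planes)` when `volume` is NULL.
#' @return An object of class `phantom`.
#' @export
phantom <- function(volume = NULL, voxel_um = 0.425, emitters = NULL, dims = NULL) {
  check_positive(voxel_um, "voxel_um")
  if (is.null(volume)) {
    if (is.null(dims) || length(dims) != 3L)
      stop_invalid("dims = c(rows, cols, planes) required when volume is NULL")
    dims <- as.integer(dims)
  } else {
    if (length(dim(volume)) != 3L) stop_invalid("volume must be a 3D array")
    if (any(volume < 0)) stop_invalid("emitter densities must be nonnegative")
    dims <- dim(volume)
  }
  structure(list(volume = volume, voxel_um = voxel_um,
                 emitters = emitters, dims = dims),
            class = "phantom")
}

#' Random bead phantom
#'
#' Places `n_beads` spherical emitters (500 nm fluorescent-bead analogue)
#' at uniform random, non-overlapping positions inside the volume, with a
#' guard margin from the faces. Beads are stored as point emitters with the
#' given amplitude; the bead diameter is recorded for reference (beads at
#' or below the voxel size act as point sources).
#'
#' @param n_beads Number of beads.
#' @param volume_um Physical extent `c(rows, cols, planes)` in micrometres.
#' @param voxel_um Voxel size in micrometres.
#' @param bead_diameter_um Bead diameter (default 0.5 um).
#' @param amplitude Emitter amplitude (arbitrary units).
#' @param min_separation_um Minimum pairwise center distance.
#' @param margin_um Margin kept free at every face.
#' @param seed RNG seed (positions are reproducible given the seed).
#' @param max_tries Rejection-sampling budget per bead.
#' @return A `phantom` whose `emitters` field holds the bead table.
#' @export
bead_phantom <- function(n_beads, volume_um, voxel_um = 0.425,
                         bead_diameter_um = 0.5, amplitude = 1,
                         min_separation_um = 4, margin_um = 4,
                         seed = NULL, max_tries = 2000L) {
  if (n_beads < 0) stop_invalid("n_beads must be >= 0")
  if (length(volume_um) != 3L || any(volume_um <= 0))
    stop_invalid("volume_um must be three positive extents")
  dims <- as.integer(round(volume_um / voxel_um))
  if (n_beads > 0 && any(volume_um <= 2 * margin_um))
    stop_invalid("volume too small for the requested margin")
  pos <- matrix(numeric(0), 0, 3)
  if (n_beads > 0) {
    pos <- with_seed(seed, {
      acc <- matrix(NA_real_, n_beads, 3)
      k <- 0L
      for (tries in seq_len(max_tries * n_beads)) {
        cand <- margin_um + stats::runif(3) * (volume_um - 2 * margin_um)
        ok <- k == 0L ||
          min(sqrt(colSums((t(acc[seq_len(k), , drop = FALSE]) - cand)^2))) >=
            min_separation_um
        if (ok) {
          k <- k + 1L
          acc[k, ] <- cand
          if (k == n_beads) break
        }
      }
      if (k < n_beads)
        stop_invalid("could not place ", n_beads, " beads at the requested separation")
      acc
    })
  }
  emitters <- data.frame(row_um = pos[, 1], col_um = pos[, 2], z_um = pos[, 3],
                         amplitude = rep(amplitude, nrow(pos)))
  ph <- phantom(volume = NULL, voxel_um = voxel_um, emitters = emitters,
                dims = dims)
  ph$bead_diameter_um <- bead_diameter_um
  ph
}

#' Uniform fluorescent-plane phantom
#'
#' A homogeneous emitter slab: constant density `level` across the lateral
#' field in every plane. Useful for flat-field and mode-equivalence checks.
#'
#' @param level Emitter density (level 0 gives a dark frame: offset only).
#' @param dims `c(rows, cols, planes)` voxel dimensions.
#' @param voxel_um Voxel size, micrometres.
#' @return A `phantom`.
#' @export
uniform_plane_phantom <- function(level, dims = c(128L, 128L, 1L), voxel_um = 0.425) {
  check_nonnegative(level, "level")
  phantom(array(level, dims), voxel_um = voxel_um)
}

#' Labeled tile corpus for classifier training
#'
#' Generates a balanced synthetic corpus emulating a low-resolution tile
#' screen: informative tiles carry structured foreground (Gaussian
#' nuclei-like blobs or smooth vessel-like curves) on top of a camera
#' offset plus Gaussian read noise; non-informative tiles are offset plus
#' noise only. Defaults produce 2080 tiles per class (4160 total).
#'
#' @param n_per_class Tiles per class.
#' @param tile_size Tile side length in pixels.
#' @param foreground One of `"nuclei-blobs"`, `"vessel-curves"`.
#' @param density_range Range of per-blob (or per-curve) peak amplitudes in
#'   counts above offset.
#' @param n_features_range Range of blob/curve counts per informative tile.
#' @param noise_sd Gaussian noise standard deviation, counts.
#' @param offset Camera offset, counts.
#' @param seed RNG seed; corpora are bit-reproducible given the seed.
#' @return A list of class `tile_corpus`: `tiles` (array
#'   `tile_size x tile_size x n`), `labels` (integer 0/1), `manifest`
#'   (data frame with tile_id, label and generator parameters).
#' @export
tissue_tile_corpus <- function(n_per_class = 2080L,
                               tile_size = 128L,
                               foreground = c("nuclei-blobs", "vessel-curves"),
                               density_range = c(30, 120),
                               n_features_range = c(4L, 16L),
                               noise_sd = 5,
                               offset = 100,
                               seed = 1L) {
  foreground <- match.arg(foreground)
  if (n_per_class < 1L) stop_invalid("n_per_class must be >= 1")
  n_total <- 2L * n_per_class
  with_seed(seed, {
    tiles <- array(stats::rnorm(tile_size^2 * n_total, mean = offset, sd = noise_sd),
                   c(tile_size, tile_size, n_total))
    labels <- rep(c(1L, 0L), each = n_per_class)
    xy <- seq_len(tile_size)
    for (i in seq_len(n_per_class)) {
      nfeat <- sample(n_features_range[1]:n_features_range[2], 1L)
      fg <- matrix(0, tile_size, tile_size)
      if (foreground == "nuclei-blobs") {
        for (f in seq_len(nfeat)) {
          cx <- stats::runif(1, 8, tile_size - 8)
          cy <- stats::runif(1, 8, tile_size - 8)
          sg <- stats::runif(1, 2.5, 7)
          amp <- stats::runif(1, density_range[1], density_range[2])
          fg <- fg + amp * exp(-(outer((xy - cy)^2, (xy - cx)^2, "+")) / (2 * sg^2))
        }
      } else {
        for (f in seq_len(nfeat)) {
          npt <- 200L
          ang <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(npt - 1, 0, 0.15)))
          px <- cumsum(c(stats::runif(1, 10, tile_size - 10), cos(ang[-1]) * 1.2))
          py <- cumsum(c(stats::runif(1, 10, tile_size - 10), sin(ang[-1]) * 1.2))
          keep <- px > 2 & px < tile_size - 1 & py > 2 & py < tile_size - 1
          amp <- stats::runif(1, density_range[1], density_range[2])
          curve <- matrix(0, tile_size, tile_size)
          curve[cbind(round(py[keep]), round(px[keep]))] <- amp
          fg <- fg + gaussian_blur_2d(curve, 1.5) * 6
        }
      }
      tiles[, , i] <- tiles[, , i] + fg
    }
    manifest <- data.frame(
      tile_id = seq_len(n_total), label = labels,
      foreground = ifelse(labels == 1L, foreground, "none"),
      tile_size = tile_size, noise_sd = noise_sd, offset = offset, seed = seed)
    structure(list(tiles = tiles, labels = labels, manifest = manifest),
              class = "tile_corpus")
  })
}
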