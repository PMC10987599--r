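#' Plan a tile grid over a sample bounding box
#'
#' Lays a regular 3D grid of overlapping tiles covering the requested
#' extent. Per axis the tile step is `size * (1 - overlap)` and the count
#' is `1 + ceiling(max(0, L - size) / step)`, with the grid origin at the
#' box corner and row-major XYZ ordering.
#'
#' @param extent_um Bounding box `c(x, y, z)` in micrometres.
#' @param tile_fov_um Lateral tile field of view (x and y), micrometres.
#' @param tile_depth_um Tile depth (z), micrometres.
#' @param overlap_fraction Fractional overlap between neighboring tiles,
#'   in `[0, 1)` (applied to all three axes).
#' @param z_step_um Frame spacing within a tile (defaults to the 0.425 um
#'   pixel in water); `frames_per_tile = ceiling(tile_depth / z_step)`.
#' @param n_channels Number of acquisition channels.
#' @return An object of class `tile_plan`: `origins` (data frame x, y, z in
#'   micrometres), `tile_fov_um`, `tile_depth_um`, `overlap_fraction`,
#'   `frames_per_tile`, `n_channels`, `n_tiles`.
#' @examples
#' plan <- plan_tiles(c(2000, 2000, 500), tile_fov_um = 870,
#'                    tile_depth_um = 170)
#' plan$n_tiles
#' @export
plan_tiles <- function(extent_um, tile_fov_um, tile_depth_um,
                       overlap_fraction = 0.1, z_step_um = 0.425,
                       n_channels = 1L) {
  if (length(extent_um) != 3L || any(extent_um <= 0))
    stop_invalid("extent_um must be three positive lengths")
  check_positive(tile_fov_um, "tile_fov_um")
  check_positive(tile_depth_um, "tile_depth_um")
  check_positive(z_step_um, "z_step_um")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_invalid("overlap_fraction must lie in [0, 1)")
  axis_origins <- function(L, size) {
    step <- size * (1 - overlap_fraction)
    n <- 1L + as.integer(ceiling(max(0, L - size) / step))
    (seq_len(n) - 1L) * step
  }
  ox <- axis_origins(extent_um[1], tile_fov_um)
  oy <- axis_origins(extent_um[2], tile_fov_um)
  oz <- axis_origins(extent_um[3], tile_depth_um)
  origins <- expand.grid(x = ox, y = oy, z = oz, KEEP.OUT.ATTRS = FALSE)
  structure(list(
    origins = origins,
    tile_fov_um = tile_fov_um,
    tile_depth_um = tile_depth_um,
    overlap_fraction = overlap_fraction,
    frames_per_tile = as.integer(ceiling(tile_depth_um / z_step_um)),
    z_step_um = z_step_um,
    n_channels = as.integer(n_channels),
    n_tiles = nrow(origins),
    extent_um = extent_um
  ), class = "tile_plan")
}

#' Acquisition timing model
#'
#' Per-frame and per-stack delays governing the total imaging time: the
#' exposure and flyback per frame cycle and the stack delay (stage motion,
#' filter wheel, data writing) between tiles.
#'
#' @param exposure_ms Camera exposure per frame, milliseconds.
#' @param flyback_ms Actuator return time per frame cycle, milliseconds.
#' @param stack_delay_s Delay between consecutive tile stacks, seconds.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(exposure_ms, flyback_ms = 10, stack_delay_s = 5) {
  check_positive(exposure_ms, "exposure_ms")
  check_nonnegative(flyback_ms, "flyback_ms")
  check_nonnegative(stack_delay_s, "stack_delay_s")
  structure(list(exposure_ms = exposure_ms, flyback_ms = flyback_ms,
                 stack_delay_s = stack_delay_s), class = "timing_model")
}

n_frames_total <- function(plan) {
  plan$n_tiles * plan$frames_per_tile * plan$n_channels
}

#' Total frame acquisition time
#'
#' Frames times exposure only, excluding flyback and stack delays — the
#' quantity whose single-focus (100 ms) to dual-foci (25 ms) ratio is
#' exactly fourfold for identical plans.
#'
#' @param plan A [plan_tiles()] result.
#' @param timing A [timing_model()].
#' @return Hours.
#' @export
frame_acquisition_time <- function(plan, timing) {
  if (!inherits(plan, "tile_plan")) stop_contract("plan must be a tile_plan")
  if (!inherits(timing, "timing_model")) stop_contract("timing must be a timing_model")
  n_frames_total(plan) * timing$exposure_ms / 3.6e6
}

#' Total imaging time including overheads
#'
#' `n_tiles * n_channels * (frames_per_tile * (exposure + flyback) +
#' stack_delay)`, in hours. Always at least the frame acquisition time;
#' flyback and stack delays pull the dual/single speedup below the
#' fourfold frame-acquisition bound.
#'
#' @inheritParams frame_acquisition_time
#' @return Hours.
#' @export
total_imaging_time <- function(plan, timing) {
  if (!inherits(plan, "tile_plan")) stop_contract("plan must be a tile_plan")
  if (!inherits(timing, "timing_model")) stop_contract("timing must be a timing_model")
  per_tile_s <- plan$frames_per_tile * (timing$exposure_ms + timing$flyback_ms) / 1000 +
    timing$stack_delay_s
  plan$n_tiles * plan$n_channels * per_tile_s / 3600
}

#' Raw data size of a plan
#'
#' @inheritParams frame_acquisition_time
#' @param bytes_per_pixel Bytes per pixel (2 for 16-bit).
#' @param rows,cols Frame dimensions in pixels.
#' @return Decimal terabytes (1e12 bytes).
#' @export
data_size <- function(plan, bytes_per_pixel = 2, rows = 2048, cols = 2048) {
  if (!inherits(plan, "tile_plan")) stop_contract("plan must be a tile_plan")
  n_frames_total(plan) * rows * cols * bytes_per_pixel / 1e12
}

#' Compare single-focus and dual-foci acquisition budgets
#'
#' @param plan A [plan_tiles()] result (shared by both modes).
#' @param timing_single Timing model of the single-focus mode
#'   (default 100 ms exposure).
#' @param timing_dual Timing model of the dual-foci mode (default 25 ms).
#' @return A list of class `mode_comparison`: per-mode data frame
#'   (`frame_acquisition_h`, `total_imaging_h`, `data_tb`) and the
#'   `frame_acquisition_speedup` and `total_imaging_speedup` ratios.
#' @export
compare_modes <- function(plan,
                          timing_single = timing_model(100),
                          timing_dual = timing_model(25)) {
  tab <- data.frame(
    mode = c("single", "dual"),
    exposure_ms = c(timing_single$exposure_ms, timing_dual$exposure_ms),
    frame_acquisition_h = c(frame_acquisition_time(plan, timing_single),
                            frame_acquisition_time(plan, timing_dual)),
    total_imaging_h = c(total_imaging_time(plan, timing_single),
                        total_imaging_time(plan, timing_dual)),
    data_tb = rep(data_size(plan), 2L))
  structure(list(
    table = tab,
    frame_acquisition_speedup = tab$frame_acquisition_h[1] / tab$frame_acquisition_h[2],
    total_imaging_speedup = tab$total_imaging_h[1] / tab$total_imaging_h[2]
  ), class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("frame-acquisition speedup: %.2f\ntotal-imaging speedup: %.2f\n",
              x$frame_acquisition_speedup, x$total_imaging_speedup))
  invisible(x)
}
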