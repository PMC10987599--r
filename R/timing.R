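#' Rolling-shutter timing configuration
#'
#' Parameters of the camera rolling shutter and the focus sweep. In single
#' mode one light-sheet focus sweeps all `total_rows` rows per frame; in
#' dual mode two foci, held at a fixed separation of `foci_separation_rows`
#' (half the chip), each sweep half the rows with their own shutter. The
#' active window is the band of rows (default 40) exposing at any instant.
#'
#' @param total_rows Number of detector rows swept per frame (chip rows).
#' @param active_rows Number of simultaneously active rows.
#' @param mode `"single"` (classic ASLM) or `"dual"` (two foci).
#' @param foci_separation_rows Row separation of the two foci in dual mode;
#'   must equal `total_rows / 2`.
#' @param exposure_ms Camera exposure time per frame (the leading-edge
#'   transit time across the swept rows), milliseconds.
#' @param flyback_ms Actuator return (settle) time per cycle, milliseconds.
#' @return An object of class `shutter_config`.
#' @examples
#' dual <- shutter_config(mode = "dual", exposure_ms = 25)
#' frame_rate(dual$exposure_ms)  # 40 fps
#' @export
shutter_config <- function(total_rows = 2048L,
                           active_rows = 40L,
                           mode = c("dual", "single"),
                           foci_separation_rows = NULL,
                           exposure_ms = 25,
                           flyback_ms = 10) {
  mode <- match.arg(mode)
  total_rows <- as.integer(total_rows)
  active_rows <- as.integer(active_rows)
  check_positive(exposure_ms, "exposure_ms")
  check_nonnegative(flyback_ms, "flyback_ms")
  if (total_rows <= 0) stop_invalid("total_rows must be positive")
  if (active_rows <= 0 || active_rows >= total_rows)
    stop_invalid("active_rows must satisfy 0 < active_rows < total_rows")
  if (mode == "dual") {
    if (total_rows %% 2L != 0L) stop_invalid("dual mode requires an even row count")
    if (is.null(foci_separation_rows)) foci_separation_rows <- total_rows %/% 2L
    foci_separation_rows <- as.integer(foci_separation_rows)
    if (foci_separation_rows != total_rows %/% 2L)
      stop_invalid("dual mode requires foci_separation_rows == total_rows / 2")
    if (active_rows >= foci_separation_rows)
      stop_invalid("active_rows must be smaller than the rows swept per shutter")
  } else {
    foci_separation_rows <- 0L
  }
  structure(list(
    total_rows = total_rows,
    active_rows = active_rows,
    mode = mode,
    foci_separation_rows = foci_separation_rows,
    exposure_ms = exposure_ms,
    flyback_ms = flyback_ms,
    readout_direction = "top_to_bottom"
  ), class = "shutter_config")
}

# rows swept by each shutter (N in single mode, N/2 per focus in dual mode)
rows_per_shutter <- function(cfg) {
  if (cfg$mode == "dual") cfg$total_rows %/% 2L else cfg$total_rows
}

#' Per-row activation schedule of the rolling shutter
#'
#' Row `r` (0-based, within its shutter) is active while the shutter's
#' leading edge lies in `[r, r + A)`, i.e. for
#' `t` in `[r*T/R, (r+A)*T/R)` where `R` is the rows swept per shutter. In
#' dual mode both shutters start simultaneously, one per chip half.
#'
#' @param cfg A `shutter_config`.
#' @return A data frame of class `row_schedule` with columns `row`
#'   (0-based global row index), `shutter` (1 or 2), `t_on`, `t_off`
#'   (milliseconds), carrying the config as attribute `config`.
#' @export
row_schedule <- function(cfg) {
  if (!inherits(cfg, "shutter_config")) stop_contract("cfg must be a shutter_config")
  R <- rows_per_shutter(cfg)
  rows <- seq_len(cfg$total_rows) - 1L
  shutter <- if (cfg$mode == "dual") ifelse(rows < R, 1L, 2L) else rep(1L, cfg$total_rows)
  local_row <- rows - (shutter - 1L) * R
  t_on <- local_row * cfg$exposure_ms / R
  t_off <- (local_row + cfg$active_rows) * cfg$exposure_ms / R
  out <- data.frame(row = rows, shutter = shutter, t_on = t_on, t_off = t_off)
  attr(out, "config") <- cfg
  class(out) <- c("row_schedule", "data.frame")
  out
}

#' Effective per-row exposure (dwell) time
#'
#' Each row is active for `A * T / R` milliseconds (`A` active rows, `T`
#' exposure, `R` rows swept per shutter). At equal exposure time, dual mode
#' halves `R` and therefore doubles the per-row dwell — the twofold signal
#' gain of the dual-foci scheme.
#'
#' @param cfg A `shutter_config`.
#' @return Dwell time per row in milliseconds.
#' @export
effective_row_exposure <- function(cfg) {
  if (!inherits(cfg, "shutter_config")) stop_contract("cfg must be a shutter_config")
  cfg$active_rows * cfg$exposure_ms / rows_per_shutter(cfg)
}

#' Frame rate from exposure time
#'
#' @param exposure_ms Camera exposure time per full-FOV frame, ms.
#' @return Frames per second (`1000 / exposure_ms`); 25 ms gives 40 fps,
#'   100 ms gives 10 fps.
#' @export
frame_rate <- function(exposure_ms) {
  check_positive(exposure_ms, "exposure_ms")
  1000 / exposure_ms
}

#' Sawtooth focus-actuator command waveform
#'
#' One cycle is a linear ramp over the exposure time followed by a linear
#' return over the flyback time; the cycle period is
#' `exposure_ms + flyback_ms`.
#'
#' @param cfg A `shutter_config`.
#' @param n_cycles Number of cycles to generate.
#' @param sample_rate_khz Sampling rate in kHz; must resolve the flyback
#'   with at least 10 samples.
#' @return A data frame of class `waveform_trace` with columns `time_ms`,
#'   `amplitude` (normalized 0..1) and `cycle`.
#' @export
sawtooth_waveform <- function(cfg, n_cycles = 1L, sample_rate_khz = 10) {
  if (!inherits(cfg, "shutter_config")) stop_contract("cfg must be a shutter_config")
  if (n_cycles < 1L) stop_invalid("n_cycles must be >= 1")
  check_positive(sample_rate_khz, "sample_rate_khz")
  if (cfg$flyback_ms > 0 && cfg$flyback_ms * sample_rate_khz < 10)
    stop_invalid("sample_rate_khz too low to resolve the flyback (need >= 10 samples)")
  period <- cfg$exposure_ms + cfg$flyback_ms
  dt <- 1 / sample_rate_khz
  t <- seq(0, n_cycles * period, by = dt)
  phase <- t %% period
  cycle <- pmin(floor(t / period), n_cycles - 1L) + 1L
  amp <- ifelse(phase < cfg$exposure_ms,
                phase / cfg$exposure_ms,
                ifelse(cfg$flyback_ms > 0,
                       1 - (phase - cfg$exposure_ms) / cfg$flyback_ms, 0))
  out <- data.frame(time_ms = t, amplitude = amp, cycle = as.integer(cycle))
  attr(out, "config") <- cfg
  attr(out, "period_ms") <- period
  class(out) <- c("waveform_trace", "data.frame")
  out
}

#' Focus trajectory in detector-row units
#'
#' Maps the actuator ramp to waist positions: during the exposure ramp the
#' ideal waist tracks the center of each shutter's active window, so the
#' waist of shutter `s` is at global row
#' `(s-1)*S + R*t/T - A/2`. A constant `lag_rows` offset and an optional
#' seeded sinusoidal wobble model actuator nonlinearity; in dual mode both
#' foci share the actuator, so their separation stays exactly `S` rows
#' regardless of lag.
#'
#' @param cfg A `shutter_config`.
#' @param waveform Optional `waveform_trace`; when `NULL` a single-cycle
#'   waveform sampled at 10 kHz is generated.
#' @param lag_rows Constant trailing offset of the waist, rows.
#' @param wobble_rows Amplitude of a sinusoidal perturbation, rows.
#' @param seed Seed for the wobble phase (`NULL` = random phase).
#' @return A data frame of class `focus_trajectory` with columns `time_ms`,
#'   `focus1_row` and (dual mode) `focus2_row`; times are restricted to the
#'   exposure ramp of the first cycle.
#' @export
focus_trajectory <- function(cfg, waveform = NULL, lag_rows = 0,
                             wobble_rows = 0, seed = NULL) {
  if (!inherits(cfg, "shutter_config")) stop_contract("cfg must be a shutter_config")
  check_nonnegative(lag_rows, "lag_rows")
  check_nonnegative(wobble_rows, "wobble_rows")
  if (is.null(waveform)) waveform <- sawtooth_waveform(cfg, 1L, 10)
  if (!identical(attr(waveform, "config")$exposure_ms, cfg$exposure_ms))
    stop_contract("waveform was generated from a different timing config")
  R <- rows_per_shutter(cfg)
  keep <- waveform$time_ms <= cfg$exposure_ms  # exposure ramp of the first cycle
  t <- waveform$time_ms[keep]
  phase <- if (wobble_rows > 0) with_seed(seed, stats::runif(1, 0, 2 * pi)) else 0
  perturb <- -lag_rows + wobble_rows * sin(2 * pi * t / cfg$exposure_ms + phase)
  f1 <- R * t / cfg$exposure_ms - cfg$active_rows / 2 + perturb
  # quantize to 2^-20 rows so that adding the integer separation is exact
  # in floating point (the dual separation is then exactly S at every sample)
  f1 <- round(f1 * 2^20) / 2^20
  out <- data.frame(time_ms = t, focus1_row = f1)
  if (cfg$mode == "dual") out$focus2_row <- f1 + cfg$foci_separation_rows
  attr(out, "config") <- cfg
  class(out) <- c("focus_trajectory", "data.frame")
  out
}

# Interpolated waist row (global index) of shutter `shutter` at times t_ms.
# Times beyond the sampled ramp are linearly extrapolated from the end
# segments (rows at the chip edges finish exposing just past the ramp).
waist_row_at <- function(trajectory, t_ms, shutter = 1L) {
  col <- if (shutter == 1L) "focus1_row" else "focus2_row"
  if (is.null(trajectory[[col]])) stop_contract("trajectory has no focus for that shutter")
  tt <- trajectory$time_ms; ff <- trajectory[[col]]
  y <- stats::approx(tt, ff, xout = t_ms, rule = 2)$y
  n <- length(tt)
  hi <- t_ms > tt[n]
  if (any(hi)) {
    slope <- (ff[n] - ff[n - 1L]) / (tt[n] - tt[n - 1L])
    y[hi] <- ff[n] + slope * (t_ms[hi] - tt[n])
  }
  lo <- t_ms < tt[1L]
  if (any(lo)) {
    slope <- (ff[2L] - ff[1L]) / (tt[2L] - tt[1L])
    y[lo] <- ff[1L] + slope * (t_ms[lo] - tt[1L])
  }
  y
}

#' Synchronization error between shutter and focus trajectory
#'
#' For every row, the waist position of the row's shutter is evaluated at
#' the row's activation midpoint; the error is the maximum absolute
#' deviation from the row index. The system is considered in sync when the
#' error does not exceed half the active window (`A/2` rows) — the sheet
#' waist then stays inside the active band, which is what renders the
#' "sharp line" in a swept-focus test image.
#'
#' @param schedule A `row_schedule`.
#' @param trajectory A `focus_trajectory` built from the same config.
#' @return Maximum error in rows, with attribute `in_sync` (logical,
#'   error <= active_rows / 2).
#' @export
sync_error <- function(schedule, trajectory) {
  cfg_s <- attr(schedule, "config"); cfg_t <- attr(trajectory, "config")
  if (!identical(cfg_s[c("total_rows", "active_rows", "mode", "exposure_ms")],
                 cfg_t[c("total_rows", "active_rows", "mode", "exposure_ms")]))
    stop_contract("schedule and trajectory come from different configs")
  tm <- (schedule$t_on + schedule$t_off) / 2
  err <- numeric(nrow(schedule))
  for (s in unique(schedule$shutter)) {
    i <- schedule$shutter == s
    err[i] <- abs(waist_row_at(trajectory, tm[i], s) - schedule$row[i])
  }
  out <- max(err)
  attr(out, "in_sync") <- out <= cfg_s$active_rows / 2
  out
}
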