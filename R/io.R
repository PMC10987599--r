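#' Write a stack as a multi-page 16-bit TIFF
#'
#' One page per z-plane, 16-bit grayscale, with an optional JSON metadata
#' sidecar (`<path>.json`) recording acquisition parameters. A
#' write-then-read round trip is bit-identical, including page order.
#'
#' @param stack 3D array (rows x cols x planes) or a matrix (one page);
#'   integer counts in `[0, 65535]`.
#' @param path Output TIFF path.
#' @param metadata Optional named list written to the JSON sidecar.
#'   `ls_stack` attributes (`exposure_ms`, `mode`, `pixel_um`,
#'   `z_step_um`) are included automatically.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L) stop_contract("stack must be a 2D or 3D array")
  if (any(stack < 0) || any(stack > 65535))
    stop_invalid("counts must lie in the 16-bit range [0, 65535]")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) round(stack[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  auto <- list()
  for (a in c("exposure_ms", "mode", "pixel_um", "z_step_um"))
    if (!is.null(attr(stack, a))) auto[[a]] <- attr(stack, a)
  meta <- utils::modifyList(auto, as.list(metadata))
  if (length(meta) > 0)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF stack
#'
#' @param path TIFF path (8- or 16-bit grayscale; RGB and other multi-
#'   channel layouts are rejected).
#' @return 3D array of integer counts with attribute `metadata` (the JSON
#'   sidecar contents, if present).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (!is.null(dim(p)) && length(dim(p)) > 2L)
      stop_invalid("unsupported TIFF: expected single-channel grayscale, got ",
                   dim(p)[3], " samples per pixel")
  }
  stack <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(stack, "metadata") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stack
}

#' Write a tile-position map in TileConfiguration format
#'
#' The plain-text manifest consumed by stitching software: a `dim=3`
#' header, then one line per tile `id;;(x, y, z)` with positions in pixel
#' units (micrometre origins divided by the pixel size). Tiles are written
#' in plan order (deterministic).
#'
#' @param plan A `tile_plan` (possibly from [select_tiles()]).
#' @param path Output text path.
#' @param pixel_um Lateral pixel size used to convert micrometres to
#'   pixels.
#' @return `path`, invisibly; warns when the map is empty.
#' @export
write_tile_map <- function(plan, path, pixel_um = 0.425) {
  if (!inherits(plan, "tile_plan")) stop_contract("plan must be a tile_plan")
  check_positive(pixel_um, "pixel_um")
  ids <- if (!is.null(plan$tile_id)) plan$tile_id else seq_len(plan$n_tiles)
  lines <- "dim=3"
  if (plan$n_tiles == 0L) {
    warning("empty tile selection; writing header-only map")
  } else {
    pos <- as.matrix(plan$origins) / pixel_um
    lines <- c(lines, sprintf("%d;;(%.6g, %.6g, %.6g)",
                              ids, pos[, 1], pos[, 2], pos[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TileConfiguration tile map
#'
#' @param path Text path written by [write_tile_map()].
#' @param pixel_um Pixel size to convert positions back to micrometres.
#' @return Data frame with `tile_id`, `x`, `y`, `z` (micrometres).
#' @export
read_tile_map <- function(path, pixel_um = 0.425) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "dim=3")
    stop_invalid("not a TileConfiguration file: missing 'dim=3' header")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(data.frame(tile_id = integer(), x = numeric(), y = numeric(),
                      z = numeric()))
  m <- regmatches(body, regexec(
    "^([0-9]+);;\\(([-0-9.eE+]+), ([-0-9.eE+]+), ([-0-9.eE+]+)\\)$", body))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop_invalid("malformed tile line: ", body[which(bad)[1]])
  num <- function(i) vapply(m, function(g) as.numeric(g[i]), numeric(1))
  data.frame(tile_id = as.integer(num(2)), x = num(3) * pixel_um,
             y = num(4) * pixel_um, z = num(5) * pixel_um)
}

run_config_blocks <- c("optics", "timing", "planner", "classifier", "noise",
                       "seed", "output_dir")

#' Read and validate a run configuration
#'
#' YAML or JSON configuration with blocks `optics`, `timing`, `planner`,
#' `classifier`, `noise` plus `seed` and `output_dir`. Unknown top-level
#' keys are rejected; the parse/serialize round trip is lossless.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_blocks)
  if (length(unknown) > 0)
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "),
                 " (expected a subset of: ",
                 paste(run_config_blocks, collapse = ", "), ")")
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg A named list / `run_config`.
#' @param path Output path (`.yaml` or `.json` selects the format).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_blocks)
  if (length(unknown) > 0)
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Export a waveform trace as delimited text
#'
#' Two-column tab-separated text (`time_ms`, `amplitude`).
#'
#' @param waveform A `waveform_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(waveform, path) {
  if (!inherits(waveform, "waveform_trace"))
    stop_contract("waveform must be a waveform_trace")
  utils::write.table(waveform[, c("time_ms", "amplitude")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
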