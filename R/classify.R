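#' Intensity-rule configuration
#'
#' Parameters of the five-step intensity-based tile classification:
#' axial MIP, smoothing by two uniform (box) filters, difference image,
#' fraction of pixels above a count threshold, and a percentage cutoff.
#'
#' @param kernel_small Side of the small box filter, pixels.
#' @param kernel_large Side of the large box filter, pixels.
#' @param pixel_threshold Count threshold applied to the (signed)
#'   difference image.
#' @param score_cutoff Percentage cutoff: tiles scoring below this are
#'   non-informative.
#' @return An object of class `intensity_rule_config`.
#' @export
intensity_rule_config <- function(kernel_small = 20L, kernel_large = 40L,
                                  pixel_threshold = 2.5, score_cutoff = 0.1) {
  if (kernel_small <= 0 || kernel_large <= 0 || kernel_small >= kernel_large)
    stop_invalid("kernels must satisfy 0 < kernel_small < kernel_large")
  check_positive(pixel_threshold, "pixel_threshold")
  check_positive(score_cutoff, "score_cutoff")
  structure(list(kernel_small = as.integer(kernel_small),
                 kernel_large = as.integer(kernel_large),
                 pixel_threshold = pixel_threshold,
                 score_cutoff = score_cutoff),
            class = "intensity_rule_config")
}

#' Maximum-intensity projection along the axial dimension
#'
#' @param tile A 3D array (rows x cols x planes) or `ls_stack`.
#' @return Per-pixel maximum over planes (matrix).
#' @export
mip_axial <- function(tile) {
  d <- dim(tile)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop_contract("tile must be a 3D stack with at least one plane")
  apply(tile, c(1, 2), max)
}

# Box-filter mean with half-sample symmetric padding. Even kernels center
# on the window rows [i - k/2, i + k/2 - 1] (pad k/2 ahead, k/2 - 1 behind).
box_filter <- function(img, k) {
  k <- as.integer(k)
  lo <- k %/% 2L
  hi <- k - 1L - lo
  pr <- pad_sym_index(nrow(img), lo, hi)
  pc <- pad_sym_index(ncol(img), lo, hi)
  p <- img[pr, pc, drop = FALSE]
  # summed-area table with a zero first row/col
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  i <- seq_len(nrow(img)); j <- seq_len(ncol(img))
  (s[i + k, j + k, drop = FALSE] - s[i, j + k, drop = FALSE] -
     s[i + k, j, drop = FALSE] + s[i, j, drop = FALSE]) / (k * k)
}

#' Intensity-based informativeness score
#'
#' Difference-of-box-filters score: the MIP is smoothed by a small and a
#' large uniform filter; the signed difference removes the background; the
#' score is the percentage of pixels whose difference exceeds the
#' threshold. Constant images (and any added constant background) score
#' exactly zero.
#'
#' @param mip 2D image (matrix), at least `kernel_large` in each dimension.
#' @param cfg An [intensity_rule_config()].
#' @return Score in percent of pixels.
#' @export
intensity_score <- function(mip, cfg = intensity_rule_config()) {
  if (!is.matrix(mip)) stop_contract("mip must be a matrix")
  if (nrow(mip) < cfg$kernel_large || ncol(mip) < cfg$kernel_large)
    stop_invalid("image must be at least kernel_large (", cfg$kernel_large,
                 " px) in each dimension")
  d <- box_filter(mip, cfg$kernel_small) - box_filter(mip, cfg$kernel_large)
  100 * mean(d > cfg$pixel_threshold)
}

#' Label a tile from its intensity score
#'
#' Tiles scoring below the cutoff (0.1 % of pixels) are non-informative
#' (label 0); a score at or above the cutoff is informative (label 1).
#'
#' @param score Score in percent, from [intensity_score()].
#' @param cfg An [intensity_rule_config()].
#' @return Integer label(s), 0 or 1.
#' @export
classify_by_intensity <- function(score, cfg = intensity_rule_config()) {
  if (any(score < 0)) stop_invalid("scores must be nonnegative")
  as.integer(score >= cfg$score_cutoff)
}

#' ROC curve and AUC
#'
#' Computes the receiver operating characteristic over all thresholds and
#' the area under it by the trapezoid rule (which equals the
#' Mann-Whitney pair-counting estimator, ties counted half).
#'
#' @param probabilities Numeric scores, higher = more likely positive.
#' @param labels Binary labels (0/1), both classes present.
#' @return A list of class `roc_points`: `fpr`, `tpr`, `thresholds`
#'   (descending) and `auc`.
#' @export
roc_curve <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (length(probabilities) != length(labels))
    stop_contract("probabilities and labels must have equal length")
  if (length(unique(labels)) < 2L)
    stop_contract("both classes must be present")
  o <- order(probabilities, decreasing = TRUE)
  p <- probabilities[o]; y <- labels[o]
  # collapse tied scores to single operating points
  grp_end <- c(diff(p) != 0, TRUE)
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1L - y)[grp_end]
  n_pos <- sum(y); n_neg <- length(y) - n_pos
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, p[grp_end]), auc = auc),
            class = "roc_points")
}

#' Select informative tiles from a plan
#'
#' Subsets the tile plan to the tiles labeled informative, producing the
#' coordinate map handed to high-resolution imaging.
#'
#' @param scores A data frame with columns `tile_id` (1-based indices into
#'   the plan origins) and `label` (0/1), e.g. from [predict_proba()].
#' @param plan A [plan_tiles()] result.
#' @return A `tile_plan` restricted to the selected origins, carrying the
#'   selected `tile_id`s; warns when the selection is empty.
#' @export
select_tiles <- function(scores, plan) {
  if (!inherits(plan, "tile_plan")) stop_contract("plan must be a tile_plan")
  if (is.null(scores$tile_id) || is.null(scores$label))
    stop_contract("scores must have tile_id and label columns")
  if (any(scores$tile_id < 1L | scores$tile_id > plan$n_tiles) ||
      anyDuplicated(scores$tile_id))
    stop_contract("tile ids do not align with the plan origins")
  keep <- scores$tile_id[scores$label == 1L]
  if (length(keep) == 0L) warning("no informative tiles selected; map is empty")
  out <- plan
  out$origins <- plan$origins[keep, , drop = FALSE]
  out$n_tiles <- length(keep)
  out$tile_id <- keep
  out
}
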