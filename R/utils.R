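# Internal helpers shared across modules.

# fwhm = 2*sqrt(2*ln 2) * sigma for a Gaussian profile
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

stop_invalid <- function(...) {
  stop(structure(class = c("sweptsheet_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_contract <- function(...) {
  stop(structure(class = c("sweptsheet_contract_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
    stop_invalid(name, " must be a positive finite number")
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x < 0))
    stop_invalid(name, " must be a nonnegative finite number")
  invisible(x)
}

# Evaluate expr with the RNG seeded by `seed`, restoring global RNG state after.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1D Gaussian kernel sampled at unit spacing, truncated at +/- 4 sigma, sum 1.
gaussian_kernel_1d <- function(sigma_px, truncate = 4) {
  if (sigma_px <= 0) return(1)
  half <- max(1L, as.integer(ceiling(truncate * sigma_px)))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian blur of a matrix with half-sample symmetric padding.
gaussian_blur_2d <- function(img, sigma_px, truncate = 4) {
  if (sigma_px <= 0) return(img)
  k <- gaussian_kernel_1d(sigma_px, truncate)
  img <- conv_rows_sym(img, k)
  t(conv_rows_sym(t(img), k))
}

# Convolve each column (along the row index) with kernel k, symmetric padding.
conv_rows_sym <- function(img, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(img)
  idx <- pad_sym_index(n, half, half)
  padded <- img[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[j + seq_len(n) - 1L, , drop = FALSE]
  }
  out
}

# Half-sample symmetric ("reflect") padding index for a length-n axis:
# e.g. n=4, lo=2 -> 2 1 | 1 2 3 4 | 4 3
pad_sym_index <- function(n, lo, hi) {
  base <- seq_len(n)
  period <- c(base, rev(base))  # length 2n, symmetric extension
  i <- ((seq_len(lo + n + hi) - 1L - lo) %% (2L * n)) + 1L
  period[i]
}

# Block-mean downsample of an [H, W, n] array (or matrix) by integer factor f.
block_mean_downsample <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  if (is.null(d)) stop_contract("block_mean_downsample expects a matrix or array")
  if (length(d) == 2L) d <- c(d, 1L)
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop_invalid("image dimensions must be divisible by the downsample factor")
  h2 <- d[1] %/% f; w2 <- d[2] %/% f
  m1 <- array(colMeans(matrix(x, f, h2 * d[2] * d[3])), c(h2, d[2], d[3]))
  ap <- aperm(m1, c(2, 1, 3))
  m2 <- array(colMeans(matrix(ap, f, w2 * h2 * d[3])), c(w2, h2, d[3]))
  out <- aperm(m2, c(2, 1, 3))
  if (length(dim(x)) == 2L) out[, , 1] else out
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based, columns x/y/z of `pts`). Out-of-range points clamp to the border.
trilinear <- function(vol, pts) {
  d <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x <- cl(pts[, 1], d[1]); y <- cl(pts[, 2], d[2]); z <- cl(pts[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(i, j, k) vol[cbind(i, j, k)]
  c00 <- at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx
  c10 <- at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx
  c01 <- at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx
  c11 <- at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}
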