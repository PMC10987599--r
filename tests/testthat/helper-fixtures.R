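# Shared fixtures and independent oracles for the test suite.

# Numeric FWHM of a sampled profile by linear interpolation of the
# half-maximum crossings (independent of the Gaussian fitting code).
fwhm_numeric <- function(profile, spacing = 1) {
  b <- min(profile)
  half <- b + (max(profile) - b) / 2
  above <- which(profile >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  left <- if (i1 > 1) {
    i1 - 1 + (half - profile[i1 - 1]) / (profile[i1] - profile[i1 - 1])
  } else i1
  right <- if (i2 < length(profile)) {
    i2 + (half - profile[i2]) / (profile[i2 + 1] - profile[i2])
  } else i2
  (right - left) * spacing
}

# Mirror index into 1..n with half-sample symmetric boundary handling.
mirror_index <- function(i, n) {
  p <- ((i - 1) %% (2 * n)) + 1
  ifelse(p <= n, p, 2 * n + 1 - p)
}

# Brute-force box-filter mean: direct window loop with symmetric padding,
# window rows/cols [i - k/2, i + k/2 - 1] for even k.
box_mean_brute <- function(img, k) {
  lo <- k %/% 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    ri <- mirror_index((i - lo):(i - lo + k - 1), nrow(img))
    for (j in seq_len(ncol(img))) {
      ci <- mirror_index((j - lo):(j - lo + k - 1), ncol(img))
      out[i, j] <- mean(img[ri, ci])
    }
  }
  out
}

# Independent implementation of the five-step intensity rule on a MIP.
intensity_score_brute <- function(mip, k1 = 20, k2 = 40, thr = 2.5) {
  d <- box_mean_brute(mip, k1) - box_mean_brute(mip, k2)
  100 * sum(d > thr) / length(d)
}

# Brute-force AUC by pair counting (ties count one half).
auc_brute <- function(prob, labels) {
  pos <- prob[labels == 1]; neg <- prob[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Small-chip shutter config for affordable rendering in tests.
small_cfg <- function(mode = "single", exposure_ms = 100, rows = 64L,
                      active = 8L) {
  shutter_config(total_rows = rows, active_rows = active, mode = mode,
                 exposure_ms = exposure_ms)
}

default_optics <- function() optical_config()

# Synthetic bead stack built directly from separable Gaussians (independent
# of the frame renderer) for quantify-module tests.
gaussian_bead_stack <- function(centers, sigma_px, dims, amplitude = 1000,
                                offset = 100) {
  stopifnot(length(sigma_px) == 3)
  st <- array(offset, dims)
  ax <- lapply(dims, seq_len)
  for (b in seq_len(nrow(centers))) {
    gx <- exp(-(ax[[1]] - centers[b, 1])^2 / (2 * sigma_px[1]^2))
    gy <- exp(-(ax[[2]] - centers[b, 2])^2 / (2 * sigma_px[2]^2))
    gz <- exp(-(ax[[3]] - centers[b, 3])^2 / (2 * sigma_px[3]^2))
    st <- st + amplitude * outer(outer(gx, gy), gz)
  }
  st
}
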