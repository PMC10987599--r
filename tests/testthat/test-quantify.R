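test_that("Gaussian fits recover sigma exactly on noiseless profiles", {
  x <- 0:40
  for (sigma in c(0.5, 1, 2, 4)) {
    prof <- 3 + 10 * exp(-(x - 20)^2 / (2 * sigma^2))
    ft <- fwhm_fit(prof, spacing_um = 1)
    expect_equal(ft$sigma_um, sigma, tolerance = 1e-9)
    expect_equal(ft$fwhm_um, 2 * sqrt(2 * log(2)) * sigma, tolerance = 1e-9)
    expect_equal(ft$center_um, 20, tolerance = 1e-7)
  }
  # closed-form FWHM examples
  expect_equal(fwhm_fit(10 * exp(-((0:20) - 10)^2 / 2))$fwhm_um, 2.3548,
               tolerance = 1e-4)
  expect_equal(fwhm_fit(10 * exp(-((0:30) - 15)^2 / 8))$fwhm_um, 4.7096,
               tolerance = 1e-4)
  expect_error(fwhm_fit(c(1, 2, 3)), class = "sweptsheet_invalid_parameter")
})

test_that("Gaussian fits stay accurate under measurement noise", {
  x <- 0:30
  truth <- 2 * sqrt(2 * log(2)) * 2.5
  set.seed(17)
  est <- replicate(20, {
    prof <- 100 + 500 * exp(-(x - 15)^2 / (2 * 2.5^2))
    prof <- prof + rnorm(length(prof), 0, 0.05 * 500)
    fwhm_fit(prof)$fwhm_um
  })
  expect_equal(mean(est), truth, tolerance = 0.03)
})

test_that("bead detection finds isolated peaks and suppresses near-duplicates", {
  set.seed(23)
  n <- 40
  ctr <- cbind(sample(10:90, n), sample(10:90, n),
               sample(8:40, n, replace = TRUE))
  # enforce comfortable separation by rejection
  keep <- rep(TRUE, n)
  for (i in 2:n) {
    d <- sqrt(colSums((t(ctr[seq_len(i - 1), , drop = FALSE]) - ctr[i, ])^2))
    if (min(d[keep[seq_len(i - 1)]]) < 12) keep[i] <- FALSE
  }
  ctr <- ctr[keep, , drop = FALSE]
  st <- gaussian_bead_stack(ctr, c(1.5, 1.5, 1.5), c(100, 100, 48))
  det <- detect_beads(st, min_separation_px = 6, intensity_percentile = 98)
  expect_equal(nrow(det), nrow(ctr))
  dd <- as.matrix(det[, c("row", "col", "plane")])
  for (i in seq_len(nrow(ctr))) {
    expect_lte(min(sqrt(colSums((t(dd) - ctr[i, ])^2))), 1)
  }
  # two beads closer than min_separation collapse to one detection
  st2 <- gaussian_bead_stack(rbind(c(30, 30, 20), c(33, 30, 20)),
                             c(1.5, 1.5, 1.5), c(64, 64, 40))
  det2 <- detect_beads(st2, min_separation_px = 8, intensity_percentile = 99)
  expect_equal(nrow(det2), 1)
  # featureless stack yields no detections
  det0 <- detect_beads(array(5, c(30, 30, 30)), intensity_percentile = 99)
  expect_equal(nrow(det0), 0)
})

test_that("PSF measurement recovers known isotropic and anisotropic widths", {
  set.seed(29)
  n <- 12
  ctr <- cbind(seq(15, 85, length.out = n),
               (seq_len(n) * 37) %% 70 + 15,
               (seq_len(n) * 13) %% 30 + 10)
  sig <- c(2, 2, 2)
  st <- gaussian_bead_stack(ctr, sig, c(100, 100, 48))
  det <- detect_beads(st, min_separation_px = 6, intensity_percentile = 98)
  meas <- measure_psf(st, det, spacing_um = 0.5)
  truth <- 2 * sqrt(2 * log(2)) * 2 * 0.5
  expect_equal(unname(meas$mean_um["fwhm_x"]), truth, tolerance = 0.05)
  expect_equal(unname(meas$mean_um["fwhm_y"]), truth, tolerance = 0.05)
  expect_equal(unname(meas$mean_um["fwhm_z"]), truth, tolerance = 0.05)
  ratio <- meas$mean_um["fwhm_z"] / ((meas$mean_um["fwhm_x"] +
                                        meas$mean_um["fwhm_y"]) / 2)
  expect_equal(unname(ratio), 1, tolerance = 0.05)
  # axially elongated PSF: z twice the lateral width
  st2 <- gaussian_bead_stack(ctr, c(2, 2, 4), c(100, 100, 48))
  det2 <- detect_beads(st2, min_separation_px = 6, intensity_percentile = 98)
  meas2 <- measure_psf(st2, det2, spacing_um = 0.5, half_window_px = 12)
  r2 <- meas2$mean_um["fwhm_z"] / meas2$mean_um["fwhm_x"]
  expect_equal(unname(r2), 2, tolerance = 0.1)
  # single bead: n = 1 and undefined spread
  one <- gaussian_bead_stack(matrix(c(30, 30, 20), 1), sig, c(60, 60, 40))
  m1 <- measure_psf(one, data.frame(row = 30, col = 30, plane = 20),
                    spacing_um = 0.5)
  expect_equal(m1$n_beads, 1)
  expect_true(all(is.na(m1$sd_um)))
})

test_that("MIP projections follow the selected axis and commute with transpose", {
  st <- array(seq_len(4 * 5 * 3), c(4, 5, 3))
  expect_equal(mip(st, n_planes = 1, axis = 3), st[, , 1])
  # brute-force bookkeeping along each axis
  expect_equal(mip(st, axis = 3), apply(st, c(1, 2), max))
  expect_equal(mip(st, axis = 1), apply(st, c(2, 3), max))
  expect_equal(mip(st, axis = 2), apply(st, c(1, 3), max))
  expect_equal(t(mip(st, axis = 3)), mip(aperm(st, c(2, 1, 3)), axis = 3))
  expect_error(mip(st, axis = 4), class = "sweptsheet_contract_error")
  expect_error(mip(st, n_planes = 9), class = "sweptsheet_contract_error")
})

test_that("Richardson-Lucy is the identity for a delta PSF and conserves flux", {
  set.seed(41)
  st <- array(runif(20 * 20 * 12, 10, 50), c(20, 20, 12))
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  out <- richardson_lucy(st, delta, iterations = 3)
  expect_equal(out, st, tolerance = 1e-8)
  # flux conservation for an interior object under a real kernel
  obj <- array(0, c(32, 32, 20))
  obj[12:20, 12:20, 8:12] <- 100
  oc <- default_optics()
  psf <- make_system_psf(oc, voxel_um = 0.3)
  dec <- richardson_lucy(obj + 1, psf, iterations = 5)
  expect_equal(sum(dec), sum(obj + 1), tolerance = 0.01)
  expect_true(all(dec >= 0))
  expect_error(richardson_lucy(st, array(0, c(3, 3, 3))),
               class = "sweptsheet_contract_error")
})

test_that("deconvolution with the true PSF sharpens simulated beads monotonically", {
  oc <- default_optics()
  voxel <- 0.3
  psf <- make_system_psf(oc, voxel_um = voxel)
  sig_px <- 0.97 / (2 * sqrt(2 * log(2))) / voxel
  ctr <- rbind(c(20, 20, 16), c(44, 40, 22))
  st <- gaussian_bead_stack(ctr, rep(sig_px, 3), c(64, 64, 36),
                            amplitude = 2000, offset = 0)
  width_at <- function(stack) {
    p <- ctr[1, ]
    fwhm_numeric(stack[, p[2], p[3]], voxel)
  }
  w0 <- width_at(st)
  widths <- c(w0, vapply(c(2, 4, 7, 10),
                         function(k) width_at(richardson_lucy(st, psf, k)),
                         numeric(1)))
  expect_true(all(diff(widths) < 1e-9))
  # >= 10% reduction by 10 iterations
  expect_lt(widths[length(widths)], 0.9 * w0)
})
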