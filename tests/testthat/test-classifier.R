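test_that("axial MIP is the per-pixel maximum over planes", {
  one <- array(matrix(1:12, 3, 4), c(3, 4, 1))
  expect_equal(mip_axial(one), matrix(1:12, 3, 4))
  # disjoint bright spots across planes survive in the union
  two <- array(0, c(5, 5, 2))
  two[2, 2, 1] <- 7; two[4, 4, 2] <- 9
  m <- mip_axial(two)
  expect_equal(m[2, 2], 7); expect_equal(m[4, 4], 9)
  # brute-force oracle on a random stack
  set.seed(3)
  st <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  brute <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7) brute[i, j] <- max(st[i, j, ])
  expect_equal(mip_axial(st), brute)
  expect_error(mip_axial(matrix(1, 3, 3)), class = "sweptsheet_contract_error")
})

test_that("intensity score matches an independent brute-force rule evaluation", {
  # constant images score exactly zero (background removal by box difference)
  expect_equal(intensity_score(matrix(0, 60, 60)), 0)
  expect_equal(intensity_score(matrix(137.5, 60, 60)), 0)
  # block of signal on a zero background
  img <- matrix(0, 100, 100)
  img[45:54, 45:54] <- 100
  sc <- intensity_score(img)
  expect_gt(sc, 0.1)
  expect_equal(sc, intensity_score_brute(img), tolerance = 1e-9)
  # random images agree with the brute-force implementation to 1e-9
  set.seed(8)
  for (rep in 1:8) {
    m <- matrix(rnorm(60 * 70, 100, 5), 60, 70)
    if (rep %% 2 == 0) {
      cx <- sample(20:40, 1); cy <- sample(20:50, 1)
      m[cx:(cx + 9), cy:(cy + 9)] <- m[cx:(cx + 9), cy:(cy + 9)] + runif(1, 10, 80)
    }
    expect_equal(intensity_score(m), intensity_score_brute(m), tolerance = 1e-9)
  }
  expect_error(intensity_score(matrix(0, 30, 30)),
               class = "sweptsheet_invalid_parameter")
})

test_that("intensity score is background invariant and feature monotone", {
  set.seed(5)
  base <- matrix(rnorm(80 * 80, 100, 3), 80, 80)
  blob <- matrix(0, 80, 80)
  blob[35:44, 35:44] <- 1
  s0 <- intensity_score(base + 50 * blob)
  expect_equal(intensity_score(base + 50 * blob + 200), s0, tolerance = 1e-12)
  # nondecreasing in the amplitude of a compact bright feature
  amps <- c(0, 10, 30, 60, 120)
  scores <- vapply(amps, function(a) intensity_score(base + a * blob), numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("the 0.1% cutoff separates informative from non-informative", {
  expect_identical(classify_by_intensity(0), 0L)
  expect_identical(classify_by_intensity(0.05), 0L)
  expect_identical(classify_by_intensity(0.1), 1L)  # "less than 0.1%" is non-informative
  expect_identical(classify_by_intensity(5.3), 1L)
  expect_identical(classify_by_intensity(c(0, 0.2, 0.01)), c(0L, 1L, 0L))
  expect_error(classify_by_intensity(-1), class = "sweptsheet_invalid_parameter")
})

test_that("ROC AUC equals the pair-counting statistic", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, auc_brute(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)))
  # property: trapezoid AUC == brute-force pair statistic on random small
  # instances, including ties
  set.seed(12)
  for (i in 1:30) {
    n <- sample(4:15, 1)
    labs <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    probs <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_curve(probs, labs)$auc, auc_brute(probs, labs),
                 tolerance = 1e-12)
  }
  # chance level for independent labels
  set.seed(13)
  p <- runif(1000); y <- sample(0:1, 1000, replace = TRUE)
  expect_equal(roc_curve(p, y)$auc, 0.5, tolerance = 0.05)
  # endpoints and monotonicity of the curve
  expect_equal(r2$fpr[1], 0); expect_equal(r2$tpr[length(r2$tpr)], 1)
  expect_true(all(diff(r2$fpr) >= 0) && all(diff(r2$tpr) >= 0))
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)),
               class = "sweptsheet_contract_error")
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  p <- runif(200); y <- as.integer(p + rnorm(200, 0, 0.3) > 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  ref <- suppressMessages(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(roc_curve(p, y)$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("tile selection maps informative labels back to plan coordinates", {
  plan <- plan_tiles(c(2000, 2000, 150), 870, 170)
  scores <- data.frame(tile_id = seq_len(plan$n_tiles),
                       label = rep(1L, plan$n_tiles))
  sel <- select_tiles(scores, plan)
  expect_equal(sel$origins, plan$origins)
  scores$label <- 0L
  expect_warning(sel0 <- select_tiles(scores, plan), "empty")
  expect_equal(sel0$n_tiles, 0)
  # a known subset selects exactly those origins
  scores$label <- as.integer(seq_len(plan$n_tiles) %% 3 == 0)
  sel3 <- select_tiles(scores, plan)
  expect_equal(sel3$n_tiles, sum(scores$label))
  expect_equal(sel3$origins, plan$origins[scores$label == 1, ])
  bad <- data.frame(tile_id = c(1, plan$n_tiles + 5), label = c(1L, 1L))
  expect_error(select_tiles(bad, plan), class = "sweptsheet_contract_error")
})
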