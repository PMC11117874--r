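test_that("genSPD draws symmetric positive-definite matrices deterministically", {
  expect_error(genSPD(0), "positive integer")
  m1 <- genSPD(1, scale = 1, seed = 7)
  expect_equal(dim(m1), c(1L, 1L))
  expect_gt(m1[1, 1], 0)
  expect_identical(genSPD(5, seed = 42), genSPD(5, seed = 42))
  minEig <- vapply(1:100, function(s) {
    M <- genSPD(6, seed = s)
    expect_lt(max(abs(M - t(M))), 1e-12)
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  expect_true(all(minEig > 0))
})

test_that("two-class trials are balanced, reproducible, and separate with class_sep", {
  spec <- trialGenSpec(n_channels = 6, n_trials_per_class = 15,
                       n_samples = 256, fs = 250, class_sep = 2, seed = 3)
  ts <- genTwoClassTrials(spec)
  expect_s4_class(ts, "TrialSet")
  expect_equal(nTrials(ts), 30L)
  expect_equal(as.integer(table(trialLabels(ts))), c(15L, 15L))
  expect_identical(trialData(genTwoClassTrials(spec)), trialData(ts))

  classDist <- function(sep, seed) {
    s <- trialGenSpec(n_channels = 6, n_trials_per_class = 15,
                      n_samples = 256, fs = 250, class_sep = sep,
                      seed = seed)
    x <- genTwoClassTrials(s)
    covs <- trialCovariances(x)
    lab <- trialLabels(covs)
    m1 <- riemannianMean(covs@covs[[1]][lab == 1, , ])
    m2 <- riemannianMean(covs@covs[[1]][lab == 2, , ])
    geodesicDistance(m1, m2)
  }
  # between-class distance grows with class_sep (fixed seeds)
  grid <- c(0, 0.5, 1.5, 3)
  d <- vapply(grid, classDist, numeric(1), seed = 11)
  expect_true(all(diff(d) > 0))
  # at class_sep = 0 the two empirical class means are about as far
  # apart as within-class resampling noise
  expect_lt(d[1], 0.5 * d[3])
})

test_that("gen_two_class_trials rejects invalid specifications", {
  expect_error(trialGenSpec(n_channels = 1), "n_channels")
  expect_error(trialGenSpec(n_channels = 8, n_samples = 10), "n_samples")
  expect_error(trialGenSpec(class_sep = -1), "class_sep")
  expect_error(trialGenSpec(fs = 50, band = c(8, 30)), "fs")
})

test_that("sparse-regression bench hits its correlation target and support size", {
  # uncorrelated design: all off-diagonal correlations near zero
  b0 <- genSparseRegression(regressionGenSpec(n = 10000, p = 4, k = 2,
                                              rho_block = 0, seed = 5))
  co <- cor(featureValues(b0$features))
  expect_lt(max(abs(co[upper.tri(co)])), 0.05)

  # block-correlated design converges to rho_block
  b1 <- genSparseRegression(regressionGenSpec(n = 10000, p = 10, k = 2,
                                              rho_block = 0.6,
                                              block_size = 5, seed = 5))
  co <- cor(featureValues(b1$features))
  within <- co[1:5, 1:5][upper.tri(co[1:5, 1:5])]
  expect_lt(max(abs(within - 0.6)), 0.05)

  # exactly k nonzero coefficients
  expect_equal(sum(b1$betaTrue != 0), 2L)
  expect_error(genSparseRegression(regressionGenSpec(p = 5, k = 6)), "k")

  # noiseless identity: y == X beta
  b2 <- genSparseRegression(regressionGenSpec(n = 50, p = 8, k = 3,
                                              noise_sd = 0, seed = 2))
  expect_equal(response(b2$features),
               as.numeric(featureValues(b2$features) %*% b2$betaTrue))

  # k = 0: y is pure noise, the best linear fit explains ~nothing
  b3 <- genSparseRegression(regressionGenSpec(n = 2000, p = 5, k = 0,
                                              seed = 9))
  r2 <- summary(lm(response(b3$features) ~
                     featureValues(b3$features)))$r.squared
  expect_lt(r2, 0.02)
})
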