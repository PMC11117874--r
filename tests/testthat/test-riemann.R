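test_that("sample covariance is consistent and shrinkage keeps it SPD", {
  set.seed(1)
  X <- matrix(rnorm(8 * 1e5), 8, 1e5)
  S <- sampleCovariance(X, shrinkage = "none")
  expect_lt(max(abs(diag(S) - 1)), 0.05)
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
  # duplicated channel: rank-deficient without shrinkage, SPD with it
  Xd <- rbind(X[, 1:100], X[1, 1:100])
  expect_error(sampleCovariance(Xd, shrinkage = "none"), "singular")
  for (mode in c("lw", "ridge")) {
    Sd <- sampleCovariance(Xd, shrinkage = mode)
    expect_gt(min(eigen(Sd, symmetric = TRUE)$values), 0)
  }
  # single channel reduces to the scalar variance
  v <- rnorm(500)
  expect_equal(sampleCovariance(matrix(v, 1), "none")[1, 1], var(v))
  # zero-variance trial cannot produce a covariance
  expect_error(sampleCovariance(matrix(1, 3, 50), "none"), "zero variance")
})

test_that("geodesic distance matches the log-eigenvalue formula and its symmetries", {
  A <- genSPD(5, seed = 1); B <- genSPD(5, seed = 2)
  expect_equal(geodesicDistance(A, A), 0, tolerance = 1e-10)
  expect_equal(geodesicDistance(diag(2), diag(c(exp(2), 1))), 2,
               tolerance = 1e-12)
  expect_equal(geodesicDistance(A, B), geodesicDistance(B, A),
               tolerance = 1e-10)
  # congruence invariance under an invertible transform
  for (s in 1:5) {
    G <- matrix(rnorm(25, sd = 1), 5, 5) + diag(5)
    expect_equal(geodesicDistance(t(G) %*% A %*% G, t(G) %*% B %*% G),
                 geodesicDistance(A, B), tolerance = 1e-8)
  }
  expect_error(geodesicDistance(A, genSPD(4, seed = 3)), "dimension")
})

test_that("Frechet mean satisfies its closed forms and minimizes dispersion", {
  C1 <- genSPD(4, seed = 5)
  expect_equal(riemannianMean(list(C1, C1, C1)), C1,
               tolerance = 1e-10, ignore_attr = TRUE)
  # two matrices: the geodesic midpoint in closed form
  A <- genSPD(4, seed = 6); B <- genSPD(4, seed = 7)
  Ah <- mipflasso:::spdPower(A, 0.5); Aw <- mipflasso:::spdPower(A, -0.5)
  mid <- Ah %*% mipflasso:::spdPower(Aw %*% B %*% Aw, 0.5) %*% Ah
  expect_equal(riemannianMean(list(A, B)), mid, tolerance = 1e-8,
               ignore_attr = TRUE)
  # commuting (diagonal) inputs: elementwise geometric mean
  D1 <- diag(c(1, 4, 9)); D2 <- diag(c(4, 1, 1))
  expect_equal(riemannianMean(list(D1, D2)), diag(c(2, 2, 3)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # the mean beats 100 random competitors in summed squared distance
  covs <- lapply(1:6, function(s) genSPD(3, seed = 100 + s))
  M <- riemannianMean(covs)
  dispersion <- function(Q) sum(vapply(covs, function(Ci)
    geodesicDistance(Q, Ci)^2, numeric(1)))
  dM <- dispersion(M)
  worse <- vapply(1:100, function(s) dispersion(genSPD(3, seed = 200 + s)),
                  numeric(1))
  expect_true(all(dM <= worse + 1e-10))
  expect_error(riemannianMean(list(A, B), maxIter = 1L), "converge")
})

test_that("tangent mapping is isometric at the reference and invertible", {
  covs <- lapply(1:8, function(s) genSPD(5, seed = 10 + s))
  basis <- fitTangentBasis(covs)
  M <- basis@reference
  expect_equal(tangentProject(M, basis), rep(0, 15), tolerance = 1e-9)
  for (Ci in covs[1:4]) {
    v <- tangentProject(Ci, basis)
    expect_equal(sqrt(sum(v^2)), geodesicDistance(M, Ci),
                 tolerance = 1e-10)
    expect_equal(expMap(v, basis), Ci, tolerance = 1e-8)
    # scaling the tangent vector traces the geodesic toward Ci:
    # the half-way point has half the distance
    half <- expMap(v / 2, basis)
    expect_equal(geodesicDistance(M, half),
                 geodesicDistance(M, Ci) / 2, tolerance = 1e-8)
  }
  expect_error(tangentProject(matrix(c(1, 2, 0, 1), 2), basis),
               "symmetric")
  expect_error(expMap(rep(0, 7), basis), "C\\(C\\+1\\)/2|dimension")
})

test_that("feature matrix dimensions follow n_bands * C(C+1)/2", {
  mkSPDSet <- function(nTrials, C, nBandsN, seed) {
    covs <- lapply(seq_len(nBandsN), function(b) {
      a <- array(0, c(nTrials, C, C))
      for (i in seq_len(nTrials))
        a[i, , ] <- genSPD(C, seed = seed + 97 * b + i)
      a
    })
    new("SPDSet", covs = covs,
        bands = matrix(NA_real_, nBandsN, 2,
                       dimnames = list(NULL, c("low", "high"))),
        labels = rep(1:2, length.out = nTrials))
  }
  spd <- mkSPDSet(4, 3, 9, seed = 1)
  bases <- lapply(spd@covs, fitTangentBasis)
  fm <- buildFeatureMatrix(spd, bases)
  expect_equal(ncol(featureValues(fm)), 9L * 6L)
  expect_equal(nrow(columnInfo(fm)), 54L)
  # 22-channel geometry: C(C+1)/2 = 253 columns per band
  spd22 <- mkSPDSet(3, 22, 2, seed = 5)
  fm22 <- buildFeatureMatrix(spd22, lapply(spd22@covs, fitTangentBasis))
  expect_equal(ncol(featureValues(fm22)), 2L * 253L)
  # a trial equal to the band mean maps to a zero row
  one <- spd@covs[[1]][1, , , drop = FALSE]
  spd1 <- new("SPDSet", covs = list(array(one, c(1, 3, 3))),
              bands = matrix(NA_real_, 1, 2,
                             dimnames = list(NULL, c("low", "high"))),
              labels = 1L)
  b1 <- fitTangentBasis(list(spd@covs[[1]][1, , ]))
  expect_equal(as.numeric(featureValues(buildFeatureMatrix(spd1, list(b1)))),
               rep(0, 6), tolerance = 1e-9)
  expect_error(buildFeatureMatrix(spd, bases[1:2]), "per band")
})
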