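test_that("column correlations are Pearson on standardized columns, clipped", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, 5)
  rho <- columnCorrelations(X)
  expect_equal(rho, cor(X), tolerance = 1e-12, ignore_attr = TRUE)
  # duplicated columns hit the clipping bound
  Xd <- cbind(X, X[, 1])
  rhod <- columnCorrelations(Xd, clip = 0.999)
  expect_equal(rhod[1, 6], 0.999)
  # orthogonal (and centered) columns: zero off-diagonal
  Q <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1), c(1, 1, -1, -1))
  rq <- columnCorrelations(Q)
  expect_equal(rq[upper.tri(rq)], rep(0, 3), tolerance = 1e-12)
  expect_error(columnCorrelations(cbind(X, 1)), "zero-variance")
})

test_that("fusion penalty and its quadratic form W agree exactly", {
  # hand-expanded two-feature case, rho = 0
  rho2 <- diag(2)
  expect_equal(fusionPenalty(c(1, 1), rho2), 4)
  expect_equal(fusionWeightMatrix(rho2), 2 * diag(2))
  expect_equal(fusionPenalty(c(0, 0), rho2), 0)
  expect_error(fusionPenalty(c(1, 2), matrix(c(1, 1, 1, 1), 2)), "clip")
  expect_error(fusionWeightMatrix(matrix(c(1, -1, -1, 1), 2)), "clip")
  # strong positive correlation penalizes coefficient differences hard
  rhoHi <- matrix(c(1, 0.999, 0.999, 1), 2)
  expect_gt(fusionPenalty(c(1, -1), rhoHi), 1000)
  # quadratic-form identity on random instances
  set.seed(2)
  for (i in 1:50) {
    p <- sample(3:8, 1)
    X <- matrix(rnorm(40 * p), 40, p)
    rho <- columnCorrelations(X)
    W <- fusionWeightMatrix(rho)
    expect_lt(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
              Inf)
    expect_gte(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(W)))
    for (k in 1:4) {
      beta <- rnorm(p)
      J <- fusionPenalty(beta, rho)
      expect_lt(abs(as.numeric(t(beta) %*% W %*% beta) - J),
                1e-10 * (1 + J))
    }
  }
})

test_that("square-root factor reproduces W on full-rank and deficient cases", {
  expect_equal(crossprod(sqrtFactor(diag(2))), diag(2))
  W <- fusionWeightMatrix(columnCorrelations(matrix(rnorm(200), 40, 5)))
  expect_equal(crossprod(sqrtFactor(W)), W, tolerance = 1e-10)
  # duplicated features give a (near) rank-deficient W: eigen path
  Wdef <- matrix(c(1, 1, 1, 1), 2)
  R <- sqrtFactor(Wdef)
  expect_equal(crossprod(R), Wdef, tolerance = 1e-10)
  expect_error(sqrtFactor(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("data augmentation converts the fusion penalty into a residual block", {
  set.seed(3)
  n <- 30; p <- 6
  X <- stdCols(matrix(rnorm(n * p), n, p))
  y <- rnorm(n)
  rho <- columnCorrelations(X)
  W <- fusionWeightMatrix(rho)
  R <- sqrtFactor(W)
  alpha <- runif(p, 0.2, 1)
  for (lambda2 in c(0.3, 2)) {
    aug <- augmentProblem(X, y, lambda2, R, alpha)
    for (k in 1:10) {
      beta <- rnorm(p)
      lhs <- sum((aug$yhat - aug$Xhat %*% beta)^2)
      rhs <- sum((y - X %*% beta)^2) +
        lambda2 * as.numeric(t(beta) %*% W %*% beta)
      expect_lt(abs(lhs - rhs), 1e-10 * (1 + rhs))
    }
    # the adaptive rescale divides columns by alpha
    expect_equal(sweep(aug$Xstar, 2, alpha, "*"), aug$Xhat,
                 tolerance = 1e-12)
  }
  # lambda2 = 0: the bottom block vanishes
  aug0 <- augmentProblem(X, y, 0, NULL, alpha)
  expect_equal(aug0$Xhat[(n + 1):(n + p), ], matrix(0, p, p))
  expect_error(augmentProblem(X, y, 1, R, rep(1e-9, p)), "floor")
})

test_that("coordinate descent solves the LASSO subproblem", {
  set.seed(4)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  # unpenalized limit: least squares
  ls <- cdLasso(X, y, lambda1 = 0, tol = 1e-10)
  expect_equal(ls$beta, as.numeric(coef(lm(y ~ X - 1))), tolerance = 1e-6)
  # KKT inactivity: lambda1 >= 2 max |x_j' y| zeroes everything
  lmax <- 2 * max(abs(crossprod(X, y)))
  expect_equal(cdLasso(X, y, lambda1 = lmax * 1.0001)$beta, rep(0, p))
  # one-dimensional closed form
  x1 <- matrix(rnorm(n), n, 1)
  lam <- 3
  b1 <- cdLasso(x1, y, lam, tol = 1e-12)$beta
  z <- sum(x1 * y)
  expect_equal(b1, sign(z) * max(abs(z) - lam / 2, 0) / sum(x1^2),
               tolerance = 1e-10)
  # objective never increases across sweeps
  path <- cdLasso(X, y, lambda1 = 5)$objectivePath
  expect_true(all(diff(path) <= 1e-10))
  expect_error(cdLasso(X, y, -1), "nonnegative")
})

test_that("the full fit reduces to its special cases", {
  set.seed(5)
  n <- 50; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 2 * X[, 4] + rnorm(n, sd = 0.5)
  Xs <- stdCols(X)
  yc <- y - mean(y)
  # alpha = 1, lambda2 = 0: plain LASSO (independent oracle)
  lam1 <- 4
  fitL <- fitMipfLasso(X, y, config = solverConfig(lambda1 = lam1,
                                                   variant = "lasso",
                                                   tol = 1e-9))
  bOracle <- proxGradOracle(Xs, yc, lam1)
  expect_equal(fitL@beta, bOracle, tolerance = 1e-6)
  # lambda1 = 0: closed-form ridge fusion
  rho <- columnCorrelations(X)
  W <- fusionWeightMatrix(rho)
  fitRF <- fitMipfLasso(X, y, config = solverConfig(lambda1 = 0,
                                                    lambda2 = 0.8,
                                                    tol = 1e-10))
  expect_equal(fitRF@beta, ridgeFusion(Xs, yc, 0.8, W), tolerance = 1e-6)
  # ridge fusion itself: orthonormal design, lambda2 = 0 gives X'y
  Q <- qr.Q(qr(matrix(rnorm(240), 40, 6)))
  yy <- rnorm(40)
  expect_equal(ridgeFusion(Q, yy, 0, matrix(0, 6, 6)),
               as.numeric(crossprod(Q, yy)), tolerance = 1e-10)
  # infinite fusion shrinks everything away
  expect_lt(sqrt(sum(ridgeFusion(Xs, yc, 1e8, W)^2)), 1e-3)
  # singular unpenalized system errors
  Xpn <- matrix(rnorm(5 * 12), 5, 12)
  expect_error(ridgeFusion(Xpn, rnorm(5), 0, matrix(0, 12, 12)),
               "singular")
  # variant = none keeps every feature
  fitN <- fitMipfLasso(X, y, config = solverConfig(variant = "none"))
  expect_equal(selectFeatures(fitN), seq_len(p))
})

test_that("the full MIPF objective matches the proximal-gradient oracle", {
  set.seed(6)
  for (s in 1:6) {
    n <- sample(30:60, 1); p <- sample(6:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta0 <- c(rnorm(3), rep(0, p - 3))
    y <- X %*% beta0 + rnorm(n, sd = 0.5)
    alpha <- runif(p, 0.05, 1)
    lam1 <- runif(1, 0.5, 4); lam2 <- runif(1, 0.1, 1)
    fit <- fitMipfLasso(X, y, alpha = alpha,
                        config = solverConfig(lambda1 = lam1,
                                              lambda2 = lam2,
                                              tol = 1e-10))
    Xs <- stdCols(X); yc <- y - mean(y)
    W <- fusionWeightMatrix(columnCorrelations(Xs))
    bO <- proxGradOracle(Xs, yc, lam1, lam2, alpha, W)
    expect_equal(fit@beta, bO, tolerance = 1e-5)
    # and the reported objective is the direct evaluation
    expect_equal(fit@objective,
                 penObjective(fit@beta, Xs, yc, lam1, lam2, alpha, W),
                 tolerance = 1e-8)
  }
})

test_that("strongly correlated columns are fused as lambda2 grows", {
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  X <- cbind(x, x, matrix(rnorm(n * 4), n, 4))  # exact duplicate pair
  y <- 2 * x + rnorm(n, sd = 0.3)
  gaps <- vapply(c(0.01, 0.1, 1, 10), function(l2) {
    fit <- fitMipfLasso(X, y, config = solverConfig(lambda1 = 1,
                                                    lambda2 = l2,
                                                    tol = 1e-10))
    abs(fit@beta[1] - fit@beta[2])
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-8))
  expect_lt(gaps[length(gaps)], 1e-3)
})

test_that("support shrinks monotonically along the lambda1 path", {
  set.seed(8)
  X <- matrix(rnorm(80 * 12), 80, 12)
  y <- X[, 1] + X[, 2] + rnorm(80, sd = 0.5)
  sizes <- vapply(c(0.1, 0.5, 2, 8, 40, 200), function(l1) {
    length(selectFeatures(fitMipfLasso(X, y,
      config = solverConfig(lambda1 = l1, lambda2 = 0.05))))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # selectFeatures reports 1-based sorted indices of nonzeros
  fit <- fitMipfLasso(X, y, config = solverConfig(lambda1 = 1e6))
  expect_equal(selectFeatures(fit), integer(0))
})

test_that("p > n instances stay finite and convergent with lambda2 > 0", {
  set.seed(9)
  n <- 20; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - X[, 2] + rnorm(n, sd = 0.2)
  fit <- fitMipfLasso(X, y, config = solverConfig(lambda1 = 0.5,
                                                  lambda2 = 0.5))
  expect_true(all(is.finite(fit@beta)))
  expect_true(all(diff(fit@objectivePath) <= 1e-10))
  expect_true(fit@converged)
})

test_that("CV tuning is deterministic, degenerate-grid-stable, and noise-sparse", {
  set.seed(10)
  bench <- genSparseRegression(regressionGenSpec(n = 60, p = 12, k = 2,
                                                 rho_block = 0.3,
                                                 seed = 4))
  X <- featureValues(bench$features); y <- response(bench$features)
  t1 <- tuneMipfLasso(X, y, lambda1Grid = 3, lambda2Grid = 0.2,
                      kFolds = 4, seed = 2, scoring = "mse")
  expect_equal(t1$lambda1, 3)
  expect_equal(t1$lambda2, 0.2)
  t2 <- tuneMipfLasso(X, y, lambda1Grid = c(1, 5), lambda2Grid = c(0, 0.5),
                      kFolds = 4, seed = 2, scoring = "mse")
  t3 <- tuneMipfLasso(X, y, lambda1Grid = c(1, 5), lambda2Grid = c(0, 0.5),
                      kFolds = 4, seed = 2, scoring = "mse")
  expect_identical(t2$cvTable, t3$cvTable)
  # pure-noise response: the sparsest grid point wins most of the time
  hits <- vapply(1:10, function(s) {
    Xn <- matrix(rnorm(60 * 8), 60, 8)
    yn <- rnorm(60)
    std <- stdCols(Xn)
    lmax <- 2 * max(abs(crossprod(std, yn - mean(yn))))
    tn <- tuneMipfLasso(Xn, yn, lambda1Grid = lmax * c(1.05, 0.5, 0.1),
                        lambda2Grid = 0, kFolds = 4, seed = s,
                        scoring = "mse", rule = "1se")
    tn$lambda1 == lmax * 1.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # stratification guard: a class too small to appear in every fold
  expect_error(
    tuneMipfLasso(X, rep(c(1, 2), c(59, 1)), lambda1Grid = 1,
                  lambda2Grid = 0, kFolds = 4, seed = 1,
                  scoring = "accuracy"),
    "single class")
})
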