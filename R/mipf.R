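#' @useDynLib mipflasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Standardize columns to zero mean and unit Euclidean norm, so the
# sample correlation between columns is exactly their inner product.
standardizeColumns <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  nrm <- sqrt(colSums(Xc^2))
  bad <- which(nrm <= .Machine$double.eps * nrow(X))
  if (length(bad))
    stop(sprintf("zero-variance column(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  list(X = sweep(Xc, 2L, nrm, "/"), center = ctr, norm = nrm)
}

#' Column-correlation matrix with clipping
#'
#' Standardizes columns to zero mean and unit Euclidean norm (so
#' `rho_ij = x_i' x_j` is the sample correlation) and clips
#' off-diagonal entries to `|rho| <= clip`, keeping the fusion-penalty
#' denominators `1 - rho^2` bounded away from zero even for duplicated
#' columns.
#'
#' @param X numeric matrix or [FeatureMatrix-class].
#' @param clip clipping bound in `(0, 1)`; default 0.999.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
columnCorrelations <- function(X, clip = 0.999) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  if (clip <= 0 || clip >= 1) stop("clip must lie in (0, 1)")
  Xs <- standardizeColumns(X)$X
  rho <- crossprod(Xs)
  rho[rho > clip] <- clip
  rho[rho < -clip] <- -clip
  diag(rho) <- 1
  symmetrize(rho)
}

#' Weighted fusion penalty (direct double sum)
#'
#' `J(beta) = sum_{j<i} (b_i - b_j)^2 / (1 - rho_ij)
#'          + (b_i + b_j)^2 / (1 + rho_ij)`.
#' For strongly positively correlated pairs (`rho` near 1) the first
#' term dominates and forces the coefficients together (the grouping
#' effect). Zero iff `beta = 0`.
#'
#' @param beta coefficient vector.
#' @param rho correlation matrix with off-diagonal `|rho| < 1`
#'   (clip first; see [columnCorrelations()]).
#' @return nonnegative scalar.
#' @export
fusionPenalty <- function(beta, rho) {
  p <- length(beta)
  stopifnot(nrow(rho) == p, ncol(rho) == p)
  off <- rho[upper.tri(rho)]
  if (any(abs(off) >= 1))
    stop("off-diagonal |rho| must be < 1; clip correlations first")
  J <- 0
  for (j in seq_len(p - 1L)) {
    for (i in (j + 1L):p) {
      J <- J + (beta[i] - beta[j])^2 / (1 - rho[i, j]) +
        (beta[i] + beta[j])^2 / (1 + rho[i, j])
    }
  }
  J
}

#' Fusion weight matrix (quadratic form of the fusion penalty)
#'
#' Returns the symmetric positive semi-definite `W` with
#' `W_ii = sum_{j != i} 2 / (1 - rho_ij^2)` and
#' `W_ij = -2 rho_ij / (1 - rho_ij^2)`, so that
#' `beta' W beta == fusionPenalty(beta, rho)` exactly.
#'
#' @param rho correlation matrix, off-diagonal `|rho| < 1`.
#' @return `p x p` symmetric PSD matrix.
#' @examples
#' fusionWeightMatrix(diag(2))  # 2 * I
#' @export
fusionWeightMatrix <- function(rho) {
  p <- nrow(rho)
  off <- rho[upper.tri(rho)]
  if (any(abs(off) >= 1))
    stop("off-diagonal |rho| must be < 1; clip correlations first")
  W <- -2 * rho / (1 - rho^2)
  for (i in seq_len(p))
    W[i, i] <- sum(2 / (1 - rho[i, -i]^2))
  symmetrize(W)
}

#' Closed-form ridge-fusion estimator
#'
#' Solves `min ||y - X b||^2 + lambda2 b' W b`, giving
#' `b = (X'X + lambda2 W)^{-1} X'y`. For `p > n` the system remains
#' well-posed whenever `lambda2 > 0` and `W` is positive definite on the
#' null space of `X` (the fusion analogue of ridge loading).
#'
#' @param X design matrix (standardized columns).
#' @param y centered response.
#' @param lambda2 fusion strength (`>= 0`).
#' @param W fusion weight matrix from [fusionWeightMatrix()].
#' @return coefficient vector.
#' @export
ridgeFusion <- function(X, y, lambda2, W) {
  p <- ncol(X)
  M <- crossprod(X) + lambda2 * W
  tryCatch(
    as.numeric(solve(M, crossprod(X, y))),
    error = function(e) {
      if (lambda2 <= 0)
        stop("X'X is singular and lambda2 = 0; ridge-fusion undefined")
      # tiny jitter for numerically semi-definite systems
      as.numeric(solve(M + diag(1e-10 * (1 + mean(diag(M))), p),
                       crossprod(X, y)))
    })
}

#' Square-root factor of the fusion weight matrix
#'
#' Returns `R` with `R'R = W`. Uses the Cholesky factor when `W` is
#' numerically positive definite, otherwise a symmetric eigendecomposition
#' square root with negative eigenvalues clipped at zero (rank-deficient
#' `W` arises from duplicated features).
#'
#' @param W symmetric PSD matrix.
#' @return matrix `R` such that `crossprod(R)` reproduces `W` to
#'   relative `1e-8`.
#' @export
sqrtFactor <- function(W) {
  if (max(abs(W - t(W))) > 1e-8 * (1 + max(abs(W))))
    stop("W must be symmetric")
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) {
    e <- eigen(symmetrize(W), symmetric = TRUE)
    R <- sqrt(pmax(e$values, 0)) * t(e$vectors)
  }
  R
}

#' Data augmentation reducing the fusion penalty to ordinary LASSO
#'
#' Stacks `yhat = [y; 0_p]` and `Xhat = [X; sqrt(lambda2) R]` with
#' `R'R = W`, so that
#' `||yhat - Xhat b||^2 = ||y - X b||^2 + lambda2 b' W b` identically.
#' `Xstar` divides column `j` of `Xhat` by the adaptive weight
#' `alpha_j`, absorbing the weighted L1 penalty into a plain one.
#'
#' @param X design matrix (`n x p`).
#' @param y response of length `n`.
#' @param lambda2 fusion strength; `lambda2 = 0` stacks a zero block.
#' @param R square-root factor from [sqrtFactor()] (ignored when
#'   `lambda2 = 0`; may be `NULL` then).
#' @param alpha adaptive weights (`>= 1e-8` each).
#' @return list with `yhat`, `Xhat`, `Xstar`, `alpha`.
#' @export
augmentProblem <- function(X, y, lambda2, R, alpha) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(alpha) == p)
  if (any(alpha < 1e-8))
    stop("alpha below the 1e-8 floor; apply adaptiveWeights() flooring")
  if (lambda2 < 0) stop("lambda2 must be nonnegative")
  bottom <- if (lambda2 > 0) {
    stopifnot(ncol(R) == p)
    sqrt(lambda2) * R
  } else matrix(0, p, p)
  Xhat <- rbind(X, bottom)
  yhat <- c(y, rep(0, nrow(bottom)))
  Xstar <- sweep(Xhat, 2L, alpha, "/")
  list(yhat = yhat, Xhat = Xhat, Xstar = Xstar, alpha = alpha)
}

#' Cyclic coordinate-descent LASSO
#'
#' Minimizes `||y - X b||^2 + lambda1 ||b||_1` by cyclic coordinate
#' updates `b_j <- S(x_j' r_(-j), lambda1/2) / ||x_j||^2` with
#' soft-threshold `S`; the objective is non-increasing across sweeps.
#' Stops when the largest coefficient change in a sweep falls below
#' `tol`; hitting `maxSweeps` flags `converged = FALSE` without error.
#'
#' @param X design matrix.
#' @param y response.
#' @param lambda1 L1 strength (`>= 0`).
#' @param tol convergence tolerance on max coefficient change.
#' @param maxSweeps sweep cap.
#' @param beta0 optional warm start.
#' @return list with `beta`, `nSweeps`, `converged`, `objectivePath`.
#' @export
cdLasso <- function(X, y, lambda1, tol = 1e-6, maxSweeps = 10000L,
                    beta0 = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (lambda1 < 0) stop("lambda1 must be nonnegative")
  if (is.null(beta0)) beta0 <- numeric(ncol(X))
  cdLassoCpp(X, as.numeric(y), lambda1, tol, as.integer(maxSweeps),
             as.numeric(beta0))
}

#' Solver configuration for [fitMipfLasso()]
#'
#' @param lambda1 adaptive-L1 strength (`>= 0`).
#' @param lambda2 fusion strength (`>= 0`).
#' @param tol coordinate-descent tolerance on max coefficient change.
#' @param maxSweeps sweep cap.
#' @param standardize standardize columns (zero mean, unit Euclidean
#'   norm) before fitting.
#' @param variant model variant: `"mipf"` (full model),
#'   `"adaptive_lasso"` (forces `lambda2 = 0`), `"lasso"` (forces
#'   `lambda2 = 0` and `alpha = 1`), `"none"` (all features,
#'   unpenalized least squares / minimum norm).
#' @param clip correlation clipping bound.
#' @return a list of class `"SolverConfig"`.
#' @export
solverConfig <- function(lambda1 = 0, lambda2 = 0, tol = 1e-6,
                         maxSweeps = 10000L, standardize = TRUE,
                         variant = c("mipf", "adaptive_lasso", "lasso",
                                     "none"),
                         clip = 0.999) {
  variant <- match.arg(variant)
  if (lambda1 < 0 || lambda2 < 0) stop("lambda penalties must be >= 0")
  if (tol <= 0) stop("tol must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, tol = tol,
                 maxSweeps = as.integer(maxSweeps),
                 standardize = standardize, variant = variant,
                 clip = clip),
            class = "SolverConfig")
}

# Map a binary response to +/-1 and center; other responses are only
# centered.
codeResponse <- function(y) {
  u <- sort(unique(y))
  if (length(u) == 2L) y <- ifelse(y == u[1L], -1, 1)
  list(y = y - mean(y), mean = mean(y))
}

#' Fit the MIPF-LASSO model
#'
#' Minimizes
#' `||y - X b||^2 + lambda1 sum_j alpha_j |b_j| + lambda2 b' W b`
#' where `alpha` are mutual-information adaptive weights and `W` the
#' correlation-driven fusion weight matrix. The fit composes: column
#' correlations -> `W` -> square-root factor -> data augmentation ->
#' coordinate-descent LASSO on the rescaled design -> back-transformation
#' `b_j = b*_j / alpha_j`.
#'
#' Binary responses are coded as -1/+1 and centered; columns are
#' standardized to zero mean and unit Euclidean norm (coefficients are
#' also reported back on the original scale).
#'
#' @param X design matrix or [FeatureMatrix-class].
#' @param y response; defaults to the FeatureMatrix response.
#' @param alpha adaptive weight vector (e.g. from [adaptiveWeights()]);
#'   defaults to all 1 (no adaptivity).
#' @param config a [solverConfig()].
#' @param beta0 optional warm start (solver scale).
#' @return a [MipfLassoFit-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 10), 50, 10)
#' y <- X[, 1] - X[, 2] + rnorm(50, sd = 0.1)
#' fit <- fitMipfLasso(X, y, config = solverConfig(lambda1 = 5,
#'                                                 lambda2 = 0.1))
#' selectFeatures(fit)
#' @export
fitMipfLasso <- function(X, y = NULL, alpha = NULL, config = solverConfig(),
                         beta0 = NULL) {
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- response(X)
    X <- featureValues(X)
  }
  X <- as.matrix(X)
  p <- ncol(X)
  if (inherits(alpha, "AdaptiveWeights")) alpha <- alpha$alpha
  if (is.null(alpha)) alpha <- rep(1, p)
  stopifnot(length(alpha) == p, length(y) == nrow(X))

  lambda1 <- config$lambda1
  lambda2 <- config$lambda2
  variant <- config$variant
  if (variant == "lasso") { alpha <- rep(1, p); lambda2 <- 0 }
  if (variant == "adaptive_lasso") lambda2 <- 0
  if (variant == "none") { lambda1 <- 0; lambda2 <- 0 }

  if (config$standardize) {
    std <- standardizeColumns(X)
    Xs <- std$X
  } else {
    std <- list(center = rep(0, p), norm = rep(1, p))
    Xs <- X
  }
  yc <- codeResponse(y)

  if (variant == "none") {
    beta <- as.numeric(MASS::ginv(Xs) %*% yc$y)
    rss <- sum((yc$y - Xs %*% beta)^2)
    betaOrig <- beta / std$norm
    return(new("MipfLassoFit", beta = beta, betaStar = beta,
               betaOrig = betaOrig,
               intercept = yc$mean - sum(betaOrig * std$center),
               alpha = rep(1, p), lambda1 = 0, lambda2 = 0,
               support = seq_len(p), nSweeps = 0L, converged = TRUE,
               objective = rss, objectivePath = rss,
               variant = variant))
  }

  W <- NULL
  R <- NULL
  if (lambda2 > 0) {
    rho <- columnCorrelations(Xs, clip = config$clip)
    W <- fusionWeightMatrix(rho)
    R <- sqrtFactor(W)
  }
  aug <- augmentProblem(Xs, yc$y, lambda2, R, alpha)
  sol <- cdLasso(aug$Xstar, aug$yhat, lambda1, tol = config$tol,
                 maxSweeps = config$maxSweeps, beta0 = beta0)
  betaStar <- sol$beta
  beta <- betaStar / alpha
  obj <- sum((yc$y - Xs %*% beta)^2) + lambda1 * sum(alpha * abs(beta)) +
    if (lambda2 > 0) lambda2 * as.numeric(t(beta) %*% W %*% beta) else 0
  betaOrig <- beta / std$norm
  new("MipfLassoFit", beta = as.numeric(beta),
      betaStar = as.numeric(betaStar), betaOrig = as.numeric(betaOrig),
      intercept = yc$mean - sum(betaOrig * std$center),
      alpha = alpha, lambda1 = lambda1, lambda2 = lambda2,
      support = as.integer(which(abs(beta) > 1e-8)),
      nSweeps = as.integer(sol$nSweeps), converged = sol$converged,
      objective = obj, objectivePath = sol$objectivePath,
      variant = variant)
}

#' Predict from a MIPF-LASSO fit
#' @param object a [MipfLassoFit-class].
#' @param newdata matrix on the original column scale.
#' @param ... unused.
#' @return numeric predictions `intercept + newdata %*% betaOrig`.
#' @export
predictMipfLasso <- function(object, newdata, ...) {
  as.numeric(object@intercept + as.matrix(newdata) %*% object@betaOrig)
}
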