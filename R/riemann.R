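checkSPD <- function(M, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("%s must be square", what))
  if (max(abs(M - t(M))) > 1e-8)
    stop(sprintf("%s must be symmetric", what))
  if (min(eigen(symmetrize(M), symmetric = TRUE,
                only.values = TRUE)$values) <= 0)
    stop(sprintf("%s must be positive definite", what))
  invisible(TRUE)
}

#' Spatial covariance of one trial, with shrinkage
#'
#' Computes the channel covariance of a `channels x samples` trial after
#' removing channel means. Shrinkage guarantees positive definiteness
#' even for rank-deficient trials:
#' * `"lw"` (default): analytic convex combination with the scaled
#'   identity, with data-driven intensity (optimal under Frobenius risk);
#' * `"ridge"`: fixed diagonal loading `1e-6 * trace/C`;
#' * `"none"`: plain sample covariance; errors if singular.
#'
#' @param trial numeric matrix, `channels x samples` (`samples >= 2`).
#' @param shrinkage one of `"lw"`, `"ridge"`, `"none"`.
#' @return a `C x C` SPD matrix.
#' @examples
#' X <- matrix(rnorm(4 * 100), 4, 100)
#' min(eigen(sampleCovariance(X))$values) > 0
#' @export
sampleCovariance <- function(trial, shrinkage = c("lw", "ridge", "none")) {
  shrinkage <- match.arg(shrinkage)
  if (!is.matrix(trial)) trial <- matrix(trial, nrow = 1L)
  C <- nrow(trial); n <- ncol(trial)
  if (n < 2L) stop("at least 2 samples required")
  Xc <- trial - rowMeans(trial)
  S <- tcrossprod(Xc) / (n - 1L)
  if (sum(diag(S)) <= 0)
    stop("trial has zero variance; covariance is singular")
  out <- switch(shrinkage,
    none = S,
    ridge = S + diag(1e-6 * sum(diag(S)) / C, C),
    lw = {
      m <- sum(diag(S)) / C
      d2 <- sum((S - diag(m, C))^2) / C
      if (d2 < .Machine$double.eps) S else {
        colnorm4 <- sum(colSums(Xc^2)^2)
        b2bar <- (colnorm4 - (n - 1L)^2 / n * sum(S^2)) / (n^2 * C)
        b2 <- max(min(b2bar, d2), 0)
        (b2 / d2) * diag(m, C) + (1 - b2 / d2) * S
      }
    })
  out <- symmetrize(out)
  if (min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("covariance is singular",
         if (shrinkage == "none") " (shrinkage disabled)" else "")
  out
}

#' Per-trial, per-band covariance matrices
#'
#' @param bands a list of [TrialSet-class] objects (one per band, e.g.
#'   the output of [filterBank()]) or a single TrialSet (treated as one
#'   band).
#' @param shrinkage passed to [sampleCovariance()].
#' @return an [SPDSet-class].
#' @export
trialCovariances <- function(bands, shrinkage = "lw") {
  if (is(bands, "TrialSet")) bands <- list(bands)
  bandTab <- attr(bands, "bands")
  covs <- lapply(bands, function(ts) {
    d <- ts@data
    nT <- dim(d)[1L]; C <- dim(d)[2L]
    a <- array(0, c(nT, C, C))
    for (tr in seq_len(nT))
      a[tr, , ] <- sampleCovariance(d[tr, , , drop = TRUE], shrinkage)
    a
  })
  if (is.null(bandTab))
    bandTab <- data.frame(low = rep(NA_real_, length(bands)),
                          high = rep(NA_real_, length(bands)))
  new("SPDSet", covs = covs,
      bands = as.matrix(bandTab[, c("low", "high"), drop = FALSE]),
      labels = bands[[1L]]@labels)
}

#' Affine-invariant geodesic distance between SPD matrices
#'
#' `d(A, B) = || log(A^{-1/2} B A^{-1/2}) ||_F`, the Riemannian manifold
#' distance under the affine-invariant metric. Symmetric, zero iff
#' `A == B`, and invariant under congruence `A -> G' A G`.
#'
#' @param A,B SPD matrices of the same dimension.
#' @return nonnegative scalar.
#' @examples
#' geodesicDistance(diag(2), diag(c(exp(2), 1)))  # 2
#' @export
geodesicDistance <- function(A, B) {
  checkSPD(A, "A"); checkSPD(B, "B")
  if (nrow(A) != nrow(B)) stop("dimension mismatch between A and B")
  Wh <- spdPower(A, -0.5)
  ev <- eigen(symmetrize(Wh %*% B %*% Wh), symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Riemannian (Frechet) mean of SPD matrices
#'
#' Fixed-point iteration
#' `M <- M^{1/2} exp(mean_i log(M^{-1/2} C_i M^{-1/2})) M^{1/2}`,
#' initialized at the arithmetic mean. At the solution the tangent-space
#' mean of the inputs vanishes (Frechet stationarity).
#'
#' @param covs list of SPD matrices, or a `n x C x C` array.
#' @param tol convergence tolerance on the Frobenius norm of the tangent
#'   mean.
#' @param maxIter iteration cap; non-convergence is an error carrying
#'   the last residual.
#' @return the mean SPD matrix, with attributes `"iterations"` and
#'   `"residual"`.
#' @export
riemannianMean <- function(covs, tol = 1e-8, maxIter = 50L) {
  if (is.array(covs) && length(dim(covs)) == 3L)
    covs <- lapply(seq_len(dim(covs)[1L]), function(i) covs[i, , ])
  if (!length(covs)) stop("empty covariance list")
  for (Ci in covs) checkSPD(Ci, "input covariance")
  M <- symmetrize(Reduce(`+`, covs) / length(covs))
  res <- Inf
  for (it in seq_len(maxIter)) {
    Wh <- spdPower(M, -0.5)
    Tm <- Reduce(`+`, lapply(covs, function(Ci)
      spdLog(symmetrize(Wh %*% Ci %*% Wh)))) / length(covs)
    res <- sqrt(sum(Tm^2))
    if (res < tol) {
      attr(M, "iterations") <- it
      attr(M, "residual") <- res
      return(M)
    }
    Mh <- spdPower(M, 0.5)
    M <- symmetrize(Mh %*% symExp(Tm) %*% Mh)
  }
  stop(sprintf("Frechet mean did not converge in %d iterations (residual %g)",
               maxIter, res))
}

#' Fit a tangent basis (reference point) from covariance matrices
#'
#' @param covs list of SPD matrices or `n x C x C` array (training
#'   trials only, to avoid leakage).
#' @param tol,maxIter passed to [riemannianMean()].
#' @return a [TangentBasis-class].
#' @export
fitTangentBasis <- function(covs, tol = 1e-8, maxIter = 50L) {
  M <- riemannianMean(covs, tol, maxIter)
  it <- attr(M, "iterations")
  attributes(M) <- attributes(M)[c("dim")]
  new("TangentBasis", reference = M, whitening = spdPower(M, -0.5),
      iterations = as.integer(it))
}

#' Project an SPD matrix to the tangent space at a reference
#'
#' Returns the vectorized symmetric matrix
#' `S = log(M^{-1/2} C M^{-1/2})`: diagonal entries unscaled,
#' off-diagonals scaled by `sqrt(2)`, so the Euclidean norm of the
#' vector equals `geodesicDistance(M, C)` exactly.
#'
#' @param C an SPD matrix.
#' @param basis a [TangentBasis-class] of matching dimension.
#' @return numeric vector of length `C(C+1)/2`.
#' @export
tangentProject <- function(C, basis) {
  stopifnot(is(basis, "TangentBasis"))
  checkSPD(C, "C")
  if (nrow(C) != nrow(basis@reference))
    stop("dimension mismatch between C and basis")
  Wh <- basis@whitening
  vecUpper(spdLog(symmetrize(Wh %*% C %*% Wh)))
}

#' Exponential map: tangent vector back to the SPD manifold
#'
#' Inverse of [tangentProject()] at the same basis:
#' `expMap(tangentProject(C, b), b)` recovers `C`.
#'
#' @param v tangent vector of length `C(C+1)/2`.
#' @param basis a [TangentBasis-class].
#' @return an SPD matrix.
#' @export
expMap <- function(v, basis) {
  stopifnot(is(basis, "TangentBasis"))
  S <- unvecUpper(v)
  if (nrow(S) != nrow(basis@reference))
    stop("vector length does not match basis dimension")
  Mh <- spdPower(basis@reference, 0.5)
  symmetrize(Mh %*% symExp(S) %*% Mh)
}

#' Build the tangent-space feature matrix
#'
#' Row `i` concatenates the per-band tangent vectors of trial `i`, giving
#' `p = n_bands * C(C+1)/2` columns. Bases must have been fit on
#' training trials only.
#'
#' @param spd an [SPDSet-class].
#' @param bases list of [TangentBasis-class], one per band of `spd`.
#' @return a [FeatureMatrix-class] whose response slot carries the trial
#'   labels and whose `columnInfo` records `(band, i, j)` per column.
#' @export
buildFeatureMatrix <- function(spd, bases) {
  stopifnot(is(spd, "SPDSet"))
  if (length(bases) != nBands(spd))
    stop("one TangentBasis per band required")
  C <- nChannels(spd)
  for (b in bases) {
    if (!is(b, "TangentBasis") || nrow(b@reference) != C)
      stop("basis dimension does not match SPDSet")
  }
  nT <- nTrials(spd)
  pb <- C * (C + 1L) / 2L
  X <- matrix(0, nT, pb * nBands(spd))
  for (bi in seq_len(nBands(spd))) {
    cols <- ((bi - 1L) * pb + 1L):(bi * pb)
    for (tr in seq_len(nT))
      X[tr, cols] <- tangentProject(spd@covs[[bi]][tr, , ], bases[[bi]])
  }
  ij <- vecUpperIndex(C)
  info <- do.call(rbind, lapply(seq_len(nBands(spd)), function(bi)
    data.frame(band = bi, i = ij$i, j = ij$j)))
  FeatureMatrix(X, y = as.numeric(spd@labels), columnInfo = info)
}
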