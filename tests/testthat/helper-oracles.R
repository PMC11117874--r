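# Independent oracles used to cross-check the solver. These minimize the
# penalized objective directly (no data augmentation, no coordinate
# descent) by accelerated proximal gradient (FISTA) with a Lipschitz
# step, so they share no code path with the package solver.

# min_b ||y - X b||^2 + lambda1 * sum(alpha * |b|) + lambda2 * b' W b
proxGradOracle <- function(X, y, lambda1, lambda2 = 0, alpha = NULL,
                           W = NULL, maxIter = 100000L, tol = 1e-12) {
  p <- ncol(X)
  if (is.null(alpha)) alpha <- rep(1, p)
  if (is.null(W)) W <- matrix(0, p, p)
  H <- crossprod(X) + lambda2 * W
  L <- 2 * max(eigen((H + t(H)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values)
  Xty <- crossprod(X, y)
  b <- numeric(p)
  z <- b
  tk <- 1
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (it in seq_len(maxIter)) {
    grad <- 2 * (H %*% z - Xty)
    bNew <- soft(z - grad / L, lambda1 * alpha / L)
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zNew <- bNew + ((tk - 1) / tNew) * (bNew - b)
    delta <- max(abs(bNew - b))
    b <- as.numeric(bNew)
    z <- as.numeric(zNew)
    tk <- tNew
    if (delta < tol) break
  }
  b
}

# Objective value of the penalized problem (direct evaluation).
penObjective <- function(beta, X, y, lambda1, lambda2 = 0, alpha = NULL,
                         W = NULL) {
  p <- length(beta)
  if (is.null(alpha)) alpha <- rep(1, p)
  sum((y - X %*% beta)^2) + lambda1 * sum(alpha * abs(beta)) +
    if (!is.null(W) && lambda2 > 0)
      lambda2 * as.numeric(t(beta) %*% W %*% beta) else 0
}

# Standardization matching the solver's convention (zero mean, unit
# Euclidean norm), for feeding the oracle the same problem the solver
# sees.
stdCols <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  sweep(Xc, 2L, sqrt(colSums(Xc^2)), "/")
}

# Support-recovery F1 between a selected index set and the true one.
supportF1 <- function(selected, true) {
  tp <- length(intersect(selected, true))
  if (length(selected) + length(true) == 0) return(1)
  if (!length(selected)) return(0)
  2 * tp / (length(selected) + length(true))
}
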