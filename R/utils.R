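# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

symmetrize <- function(M) (M + t(M)) / 2

# Matrix power of a symmetric matrix through its eigendecomposition.
# Negative powers require strictly positive eigenvalues.
spdPower <- function(M, p) {
  e <- eigen(symmetrize(M), symmetric = TRUE)
  if (p < 0 && min(e$values) <= 0)
    stop("matrix is not positive definite")
  symmetrize(e$vectors %*% (e$values^p * t(e$vectors)))
}

# Matrix logarithm / exponential of a symmetric (positive-definite) matrix.
spdLog <- function(M) {
  e <- eigen(symmetrize(M), symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("matrix logarithm requires positive eigenvalues")
  symmetrize(e$vectors %*% (log(e$values) * t(e$vectors)))
}

symExp <- function(S) {
  e <- eigen(symmetrize(S), symmetric = TRUE)
  symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

# Upper-triangular vectorization of a symmetric matrix: diagonal entries
# unscaled, off-diagonals scaled by sqrt(2), so the Euclidean norm of the
# vector equals the Frobenius norm of the matrix.
vecUpper <- function(S) {
  C <- nrow(S)
  idx <- upper.tri(S, diag = FALSE)
  c(diag(S), sqrt(2) * S[idx])
}

unvecUpper <- function(v) {
  # length C + C(C-1)/2 = C(C+1)/2
  C <- (-1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(C - round(C)) > 1e-9)
    stop("vector length is not C(C+1)/2 for any integer C")
  C <- as.integer(round(C))
  S <- matrix(0, C, C)
  diag(S) <- v[seq_len(C)]
  S[upper.tri(S)] <- v[-seq_len(C)] / sqrt(2)
  symmetrize(S + t(S) - diag(diag(S)))
}

# Indices (i, j) of vecUpper entries, matching its ordering.
vecUpperIndex <- function(C) {
  ij <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  data.frame(i = c(seq_len(C), ij[, 1L]),
             j = c(seq_len(C), ij[, 2L]))
}

softThreshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
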