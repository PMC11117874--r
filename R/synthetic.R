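#' Random symmetric positive-definite matrix
#'
#' Draws a random SPD matrix as `Q diag(l) Q'` with `Q` the orthogonal
#' factor of a Gaussian matrix and eigenvalues `l` uniform on
#' `[0.5, 2] * scale`, sorted decreasing.
#'
#' @param dim matrix dimension (`>= 1`).
#' @param scale positive scale of the eigenvalue distribution.
#' @param seed integer seed; draws are a pure function of the arguments.
#' @return a `dim x dim` SPD matrix.
#' @examples
#' M <- genSPD(4, seed = 1)
#' min(eigen(M, symmetric = TRUE)$values) > 0
#' @export
genSPD <- function(dim, scale = 1, seed = 1L) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1)
    stop("dim must be a positive integer")
  if (scale <= 0) stop("scale must be positive")
  dim <- as.integer(dim)
  withSeed(seed, {
    lam <- sort(stats::runif(dim, 0.5, 2) * scale, decreasing = TRUE)
    if (dim == 1L) return(matrix(lam, 1L, 1L))
    Q <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))
    symmetrize(Q %*% (lam * t(Q)))
  })
}

#' Specification for the two-class trial generator
#'
#' Defaults emulate a short motor-imagery-like recording: 8 channels at
#' 250 Hz, 2 s epochs, signal content in the 8-30 Hz sensorimotor range,
#' with the two class-conditional spatial covariances separated on the
#' SPD manifold by inflating half of the eigenvalues of a base covariance
#' by `1 + class_sep`.
#'
#' @param n_channels number of channels (`>= 2`).
#' @param n_trials_per_class trials per class.
#' @param n_samples samples per trial (`>= 2 * n_channels`).
#' @param fs sampling rate (Hz), must exceed `2 * band[2]`.
#' @param class_sep nonnegative scalar; eigenvalues of the base
#'   covariance on half the channels are inflated by `1 + class_sep` for
#'   class 2, so the geodesic distance between the class covariances
#'   grows like `sqrt(C/2) * log(1 + class_sep)`.
#' @param noise_sd standard deviation of additive white sensor noise.
#' @param band `(low, high)` Hz pass-band of the signal content.
#' @param seed integer seed.
#' @return a validated list of class `"TrialGenSpec"`.
#' @export
trialGenSpec <- function(n_channels = 8L, n_trials_per_class = 40L,
                         n_samples = 500L, fs = 250,
                         class_sep = 1, noise_sd = 0.2,
                         band = c(8, 30), seed = 1L) {
  spec <- list(n_channels = as.integer(n_channels),
               n_trials_per_class = as.integer(n_trials_per_class),
               n_samples = as.integer(n_samples), fs = fs,
               class_sep = class_sep, noise_sd = noise_sd,
               band = band, seed = as.integer(seed))
  if (spec$n_channels < 2L) stop("n_channels must be >= 2")
  if (spec$n_samples < 2L * spec$n_channels)
    stop("n_samples must be >= 2 * n_channels")
  if (spec$class_sep < 0) stop("class_sep must be nonnegative")
  if (length(band) != 2L || band[1L] >= band[2L])
    stop("band must be (low, high) with low < high")
  if (fs <= 2 * band[2L]) stop("fs must exceed twice the band upper edge")
  if (spec$n_trials_per_class < 1L) stop("n_trials_per_class must be >= 1")
  class(spec) <- "TrialGenSpec"
  spec
}

#' Generate two-class multichannel trials with controlled covariance
#' separation
#'
#' Each trial is band-limited colored Gaussian noise: white noise is
#' band-pass filtered (same filter implementation as the preprocessing
#' stage) and spatially mixed by the square root of a class-specific
#' target covariance, plus additive white sensor noise. Class 1 uses a
#' base SPD matrix; class 2 uses the same eigenvectors with the largest
#' `ceil(C/2)` eigenvalues inflated by `1 + class_sep`, so the two class
#' covariances commute and their geodesic distance is
#' `sqrt(ceil(C/2)) * log(1 + class_sep)` exactly.
#'
#' @param spec a [trialGenSpec()].
#' @return a [TrialSet-class] with `2 * n_trials_per_class` trials and
#'   balanced labels in `{1, 2}`.
#' @examples
#' ts <- genTwoClassTrials(trialGenSpec(n_trials_per_class = 5,
#'                                      n_samples = 128))
#' table(trialLabels(ts))
#' @export
genTwoClassTrials <- function(spec) {
  if (!inherits(spec, "TrialGenSpec"))
    stop("spec must be created by trialGenSpec()")
  C <- spec$n_channels
  S <- spec$n_samples
  nt <- spec$n_trials_per_class
  withSeed(spec$seed, {
    base <- {
      lam <- sort(stats::runif(C, 0.5, 2), decreasing = TRUE)
      Q <- qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
      list(Q = Q, lam = lam)
    }
    infl <- rep(1, C)
    infl[seq_len(ceiling(C / 2))] <- 1 + spec$class_sep
    mix <- list(
      base$Q %*% (sqrt(base$lam) * t(base$Q)),
      base$Q %*% (sqrt(base$lam * infl) * t(base$Q))
    )
    dat <- array(0, c(2L * nt, C, S))
    labels <- rep(1:2, each = nt)
    for (tr in seq_len(2L * nt)) {
      Z <- matrix(stats::rnorm(C * S), C, S)
      Zf <- t(apply(Z, 1L, butterBandpass, low = spec$band[1L],
                    high = spec$band[2L], fs = spec$fs))
      dat[tr, , ] <- mix[[labels[tr]]] %*% Zf +
        spec$noise_sd * matrix(stats::rnorm(C * S), C, S)
    }
    TrialSet(dat, fs = spec$fs, labels = labels, t0 = 0)
  })
}

#' Specification for the sparse-regression benchmark generator
#'
#' @param n sample count.
#' @param p feature count.
#' @param k true support size (`k <= p`).
#' @param rho_block within-block correlation of design columns, in
#'   `[0, 1)`.
#' @param beta_scale magnitude of nonzero coefficients (alternating
#'   sign).
#' @param noise_sd residual standard deviation.
#' @param block_size number of consecutive columns per correlated block.
#' @param seed integer seed.
#' @return a validated list of class `"RegressionGenSpec"`.
#' @export
regressionGenSpec <- function(n = 100L, p = 50L, k = 5L, rho_block = 0.5,
                              beta_scale = 1, noise_sd = 0.25,
                              block_size = 5L, seed = 1L) {
  spec <- list(n = as.integer(n), p = as.integer(p), k = as.integer(k),
               rho_block = rho_block, beta_scale = beta_scale,
               noise_sd = noise_sd, block_size = as.integer(block_size),
               seed = as.integer(seed))
  if (spec$k > spec$p) stop("k must not exceed p")
  if (spec$k < 0L) stop("k must be nonnegative")
  if (rho_block < 0 || rho_block >= 1) stop("rho_block must lie in [0, 1)")
  if (spec$block_size < 1L) stop("block_size must be >= 1")
  class(spec) <- "RegressionGenSpec"
  spec
}

#' Generate a linear-model benchmark with block-correlated design
#'
#' Columns are block-equicorrelated Gaussian (factor construction:
#' `x_j = sqrt(rho) f_b + sqrt(1 - rho) z_j` within block `b`), then
#' standardized to zero mean and unit standard deviation, so the
#' population within-block correlation equals `rho_block`. The true
#' coefficient vector has exactly `k` nonzero entries of magnitude
#' `beta_scale` with alternating signs, placed on the first column of
#' each successive block (spilling over round-robin if `k` exceeds the
#' number of blocks). The response is `y = X beta + eps` with
#' `eps ~ N(0, noise_sd^2)` computed on the standardized design.
#'
#' @param spec a [regressionGenSpec()].
#' @return a list with elements `features` (a [FeatureMatrix-class] whose
#'   response slot holds `y`) and `betaTrue` (the true coefficients).
#' @examples
#' bench <- genSparseRegression(regressionGenSpec(n = 50, p = 10, k = 2))
#' sum(bench$betaTrue != 0)
#' @export
genSparseRegression <- function(spec) {
  if (!inherits(spec, "RegressionGenSpec"))
    stop("spec must be created by regressionGenSpec()")
  n <- spec$n; p <- spec$p; k <- spec$k
  bs <- spec$block_size
  block <- rep(seq_len(ceiling(p / bs)), each = bs)[seq_len(p)]
  withSeed(spec$seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    if (spec$rho_block > 0) {
      for (b in unique(block)) {
        cols <- which(block == b)
        f <- stats::rnorm(n)
        X[, cols] <- sqrt(spec$rho_block) * f +
          sqrt(1 - spec$rho_block) * X[, cols]
      }
    }
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    beta <- numeric(p)
    if (k > 0L) {
      firsts <- match(unique(block), block)  # first column of each block
      supp <- rep(firsts, length.out = max(k, 0L))
      # round-robin spillover: offset within block on later passes
      pass <- (seq_len(k) - 1L) %/% length(firsts)
      supp <- pmin(supp[seq_len(k)] + pass, p)
      supp <- unique(supp)
      i <- 1L
      while (length(supp) < k) {  # fill any collisions with unused indices
        if (!(i %in% supp)) supp <- c(supp, i)
        i <- i + 1L
      }
      beta[supp] <- spec$beta_scale * (-1)^(seq_len(k) - 1L)
    }
    y <- as.numeric(X %*% beta)
    if (spec$noise_sd > 0) y <- y + stats::rnorm(n, sd = spec$noise_sd)
    fm <- FeatureMatrix(X, y = y,
                        columnInfo = data.frame(band = NA_integer_,
                                                i = seq_len(p), j = block))
    list(features = fm, betaTrue = beta)
  })
}
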