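#' @import methods
NULL

#' TrialSet: labeled multichannel epochs
#'
#' Container for epoched multichannel time-series trials with sampling
#' metadata. The data live in a 3-dimensional array of shape
#' `n_trials x n_channels x n_samples`; each trial carries an integer class
#' label. `t0` is the time (in seconds) of sample index 0 relative to the
#' start of the trial's timing scheme, so a window cut at `[2.5, 6)` s from
#' epochs recorded from cue onset has `t0 = 2.5`.
#'
#' @slot data numeric array, `n_trials x n_channels x n_samples`; no
#'   NaN/Inf values allowed.
#' @slot fs sampling rate in Hz (positive scalar).
#' @slot labels integer vector of per-trial class labels, length
#'   `n_trials`.
#' @slot t0 time (s) of sample index 0 relative to trial start.
#' @slot channelNames optional character vector of channel names (length
#'   0 or `n_channels`).
#'
#' @seealso [TrialSet()] for the user-facing constructor,
#'   [genTwoClassTrials()] for the synthetic generator.
#' @export
setClass("TrialSet",
  representation(
    data = "array",
    fs = "numeric",
    labels = "integer",
    t0 = "numeric",
    channelNames = "character"
  )
)

setValidity("TrialSet", function(object) {
  msgs <- character()
  d <- object@data
  if (length(dim(d)) != 3L)
    msgs <- c(msgs, "data must be a 3-d array (trials x channels x samples)")
  if (any(!is.finite(d)))
    msgs <- c(msgs, "data contains non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0)
    msgs <- c(msgs, "fs must be a positive scalar")
  if (length(dim(d)) == 3L && length(object@labels) != dim(d)[1L])
    msgs <- c(msgs, "length(labels) must equal the number of trials")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msgs <- c(msgs, "t0 must be a finite scalar")
  if (length(object@channelNames) > 0L && length(dim(d)) == 3L &&
      length(object@channelNames) != dim(d)[2L])
    msgs <- c(msgs, "channelNames must be empty or one per channel")
  if (length(msgs)) msgs else TRUE
})

#' SPDSet: per-trial, per-band covariance matrices
#'
#' Collection of symmetric positive-definite spatial covariance matrices,
#' one per (trial, band). Stored as a list of length `n_bands`, each
#' element a `n_trials x C x C` array.
#'
#' @slot covs list of numeric arrays, one per band, each
#'   `n_trials x C x C`.
#' @slot bands numeric matrix with columns `low`, `high` (Hz), one row
#'   per band.
#' @slot labels integer vector of trial labels.
#' @export
setClass("SPDSet",
  representation(
    covs = "list",
    bands = "matrix",
    labels = "integer"
  )
)

setValidity("SPDSet", function(object) {
  msgs <- character()
  if (length(object@covs) == 0L)
    msgs <- c(msgs, "at least one band required")
  dims <- vapply(object@covs, function(a) dim(a)[2L], numeric(1))
  if (length(unique(dims)) > 1L)
    msgs <- c(msgs, "all bands must share channel dimension")
  ntr <- vapply(object@covs, function(a) dim(a)[1L], numeric(1))
  if (length(unique(ntr)) > 1L)
    msgs <- c(msgs, "all bands must cover the same trials")
  if (length(ntr) && length(object@labels) != ntr[1L])
    msgs <- c(msgs, "length(labels) must equal the number of trials")
  if (nrow(object@bands) != length(object@covs))
    msgs <- c(msgs, "one band descriptor per covariance array required")
  if (length(msgs)) msgs else TRUE
})

#' TangentBasis: reference point for tangent-space mapping
#'
#' The Riemannian (Frechet) mean `M` of a set of training covariance
#' matrices together with its inverse square root, the whitening factor
#' used by the logarithmic map.
#'
#' @slot reference SPD matrix `M` (the Frechet mean).
#' @slot whitening matrix `M^{-1/2}` satisfying
#'   `whitening %*% reference %*% whitening = I` to tolerance.
#' @slot iterations number of fixed-point iterations used to reach `M`.
#' @export
setClass("TangentBasis",
  representation(
    reference = "matrix",
    whitening = "matrix",
    iterations = "integer"
  )
)

setValidity("TangentBasis", function(object) {
  M <- object@reference
  Wh <- object@whitening
  if (nrow(M) != ncol(M)) return("reference must be square")
  if (max(abs(M - t(M))) > 1e-8) return("reference must be symmetric")
  I <- Wh %*% M %*% Wh
  if (max(abs(I - diag(nrow(M)))) > 1e-6)
    return("whitening factor does not invert the reference")
  TRUE
})

#' FeatureMatrix: tangent-space design matrix with metadata
#'
#' The `n x p` design matrix of vectorized tangent-space features (rows =
#' trials, columns = per-band upper-triangular covariance entries), with
#' per-column metadata and an optional response.
#'
#' @slot X numeric matrix, `n x p`.
#' @slot y numeric response vector (length `n` or 0).
#' @slot columnInfo data.frame with one row per column: `band`, `i`, `j`
#'   (matrix entry indices) for tangent features, or generic indices for
#'   synthetic regression designs.
#' @export
setClass("FeatureMatrix",
  representation(
    X = "matrix",
    y = "numeric",
    columnInfo = "data.frame"
  )
)

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (any(!is.finite(object@X)))
    msgs <- c(msgs, "X contains non-finite values")
  if (length(object@y) > 0L && length(object@y) != nrow(object@X))
    msgs <- c(msgs, "length(y) must equal nrow(X)")
  if (nrow(object@columnInfo) > 0L &&
      nrow(object@columnInfo) != ncol(object@X))
    msgs <- c(msgs, "columnInfo must describe every column")
  if (length(msgs)) msgs else TRUE
})

#' MipfLassoFit: fitted penalized regression model
#'
#' Result of [fitMipfLasso()]. Coefficients are reported on three scales:
#' `betaStar` (solver scale, after dividing the augmented design columns
#' by the adaptive weights), `beta` (standardized-column scale,
#' `beta = betaStar / alpha`), and `betaOrig` (original column scale,
#' with `intercept`).
#'
#' @slot beta coefficients on the standardized-column scale.
#' @slot betaStar solver-scale coefficients.
#' @slot betaOrig coefficients on the original column scale.
#' @slot intercept intercept on the original scale.
#' @slot alpha adaptive weight vector used.
#' @slot lambda1,lambda2 tuning parameters.
#' @slot support integer indices with `|beta_j| > 1e-8` (ascending).
#' @slot nSweeps coordinate-descent sweeps used.
#' @slot converged logical convergence flag.
#' @slot objective final value of the penalized objective
#'   `||y - X b||^2 + lambda1 * sum(alpha |b|) + lambda2 * b' W b`.
#' @slot objectivePath per-sweep augmented-LASSO objective values.
#' @slot variant model variant: `"mipf"`, `"adaptive_lasso"`, `"lasso"`
#'   or `"none"`.
#' @export
setClass("MipfLassoFit",
  representation(
    beta = "numeric",
    betaStar = "numeric",
    betaOrig = "numeric",
    intercept = "numeric",
    alpha = "numeric",
    lambda1 = "numeric",
    lambda2 = "numeric",
    support = "integer",
    nSweeps = "integer",
    converged = "logical",
    objective = "numeric",
    objectivePath = "numeric",
    variant = "character"
  )
)

setValidity("MipfLassoFit", function(object) {
  msgs <- character()
  if (!is.finite(object@objective))
    msgs <- c(msgs, "objective must be finite")
  if (length(object@support) &&
      (min(object@support) < 1L || max(object@support) > length(object@beta)))
    msgs <- c(msgs, "support indices out of range")
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: cross-validated pipeline evaluation
#'
#' Per-fold and aggregate classification performance for a pipeline run:
#' accuracy, F1 score and G-mean (geometric mean of sensitivity and
#' specificity), plus pooled confusion counts and the configuration used.
#'
#' @slot accuracy,f1,gmean mean metric over folds, each in \[0, 1\].
#' @slot perFold data.frame with one row per fold (fold, accuracy, f1,
#'   gmean, nSelected).
#' @slot sd named numeric vector of fold standard deviations.
#' @slot confusion pooled confusion matrix (true x predicted).
#' @slot config the configuration list echoed back.
#' @export
setClass("EvalReport",
  representation(
    accuracy = "numeric",
    f1 = "numeric",
    gmean = "numeric",
    perFold = "data.frame",
    sd = "numeric",
    confusion = "matrix",
    config = "list"
  )
)

setValidity("EvalReport", function(object) {
  m <- c(object@accuracy, object@f1, object@gmean)
  if (any(m < -1e-12 | m > 1 + 1e-12))
    return("metrics must lie in [0, 1]")
  TRUE
})
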