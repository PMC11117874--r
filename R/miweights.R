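# Entropy/MI are computed in nats (natural log) by default so the
# adaptive weights alpha = exp(-r * I) compose without base conversions.

#' Shannon entropy of a discrete distribution
#'
#' `H = -sum p log p` with `0 log 0 := 0`; maximized by the uniform law.
#'
#' @param p numeric vector of probabilities (nonnegative, summing to 1).
#' @param base logarithm base; default `exp(1)` (nats).
#' @return nonnegative scalar.
#' @examples
#' shannonEntropy(c(0.5, 0.5))  # log(2)
#' @export
shannonEntropy <- function(p, base = exp(1)) {
  if (any(p < -1e-12)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Conditional entropy from a joint table
#'
#' `H(X|Y) = -sum_y p(y) sum_x p(x|y) log p(x|y)`, with rows of the
#' table indexing `x` and columns indexing `y`. Satisfies
#' `0 <= H(X|Y) <= H(X)` and the chain rule `H(X|Y) = H(X,Y) - H(Y)`.
#'
#' @param joint numeric matrix of joint probabilities `p(x, y)`.
#' @param base logarithm base; default nats.
#' @return nonnegative scalar.
#' @export
conditionalEntropy <- function(joint, base = exp(1)) {
  if (!is.matrix(joint) || any(joint < -1e-12))
    stop("joint must be a nonnegative matrix")
  if (abs(sum(joint) - 1) > 1e-8) stop("joint must sum to 1")
  py <- colSums(joint)
  h <- 0
  for (y in which(py > 0)) {
    pxy <- joint[, y] / py[y]
    pxy <- pxy[pxy > 0]
    h <- h - py[y] * sum(pxy * log(pxy, base = base))
  }
  h
}

# Equal-frequency binning; ties broken by rank order (deterministic).
# A feature with no more distinct values than bins is binned by value
# identity, so already-discrete features keep their exact distribution.
binEqualFrequency <- function(x, nBins) {
  u <- unique(x)
  if (length(u) <= nBins)
    return(match(x, sort(u)))
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * nBins / n)
}

#' Mutual information between a continuous feature and class labels
#'
#' The feature is discretized into `nBins` equal-frequency bins (ties
#' broken by rank order) and the plug-in mutual information of the
#' binned feature with the label is returned, in nats. Always
#' nonnegative and equal to `H(X) - H(X|Y)` of the binned variable.
#'
#' @param feature numeric vector.
#' @param labels class vector of the same length.
#' @param nBins number of bins (`>= 2`); default 8.
#' @param base logarithm base; default nats.
#' @return nonnegative scalar; a constant feature returns 0 with a
#'   warning (it carries no information).
#' @examples
#' y <- rep(0:1, each = 50)
#' mutualInformation(as.numeric(y), y)  # log(2)
#' @export
mutualInformation <- function(feature, labels, nBins = 8L, base = exp(1)) {
  if (length(feature) != length(labels))
    stop("feature and labels must have equal length")
  if (nBins < 2L) stop("nBins must be >= 2")
  if (length(unique(feature)) < 2L) {
    warning("constant feature carries no information; returning 0")
    return(0)
  }
  bins <- binEqualFrequency(feature, nBins)
  tab <- table(bins, labels)
  joint <- tab / sum(tab)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  max(0, sum(joint[nz] * log(joint[nz] / outer(px, py)[nz], base = base)))
}

#' Per-column mutual information of a feature matrix
#'
#' @param X numeric matrix or [FeatureMatrix-class] (columns =
#'   features).
#' @param labels class vector, one per row.
#' @param nBins passed to [mutualInformation()].
#' @return numeric vector of MI scores (nats), one per column.
#' @export
miScores <- function(X, labels, nBins = 8L) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  apply(X, 2L, function(col)
    suppressWarnings(mutualInformation(col, labels, nBins)))
}

#' Adaptive penalty weights from mutual information
#'
#' `alpha_j = exp(-r * I_j)`: features that share more information with
#' the class label receive smaller weights and are penalized less.
#' Weights are floored at `1e-8` to keep the downstream rescaling
#' `beta = beta_star / alpha` bounded.
#'
#' @param I vector of nonnegative MI scores (nats).
#' @param r trade-off parameter (`> 0`); default 5.
#' @return a list of class `"AdaptiveWeights"` with elements `I`, `r`,
#'   `alpha`.
#' @examples
#' adaptiveWeights(c(0, log(2)), r = 5)$alpha  # 1 and 2^-5
#' @export
adaptiveWeights <- function(I, r = 5) {
  if (any(I < 0)) stop("MI scores must be nonnegative")
  if (r <= 0) stop("r must be positive")
  structure(list(I = I, r = r, alpha = pmax(exp(-r * I), 1e-8)),
            class = "AdaptiveWeights")
}

#' Diagonal weight-matrix view of adaptive weights
#' @param w an [adaptiveWeights()] object.
#' @return `diag(alpha)`.
#' @export
weightMatrix <- function(w) {
  stopifnot(inherits(w, "AdaptiveWeights"))
  diag(w$alpha, length(w$alpha))
}
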