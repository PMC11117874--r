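#' Construct a TrialSet
#'
#' @param data numeric array of shape `n_trials x n_channels x n_samples`.
#' @param fs sampling rate in Hz.
#' @param labels integer class labels, one per trial.
#' @param t0 time (s) of sample index 0 relative to trial start.
#' @param channelNames optional channel names.
#' @return a [TrialSet-class]
#' @examples
#' ts <- TrialSet(array(rnorm(2 * 3 * 10), c(2, 3, 10)), fs = 100,
#'                labels = c(1L, 2L))
#' nChannels(ts)
#' @export
TrialSet <- function(data, fs, labels, t0 = 0, channelNames = character()) {
  new("TrialSet", data = data, fs = as.numeric(fs),
      labels = as.integer(labels), t0 = as.numeric(t0),
      channelNames = as.character(channelNames))
}

#' @describeIn TrialSet number of trials
#' @param x a TrialSet
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@data)[1L])

#' @describeIn TrialSet number of channels
#' @export
setMethod("nChannels", "TrialSet", function(x) dim(x@data)[2L])

#' @describeIn TrialSet samples per trial
#' @export
setMethod("nSamples", "TrialSet", function(x) dim(x@data)[3L])

#' @describeIn TrialSet sampling rate in Hz
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @describeIn TrialSet per-trial class labels
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @describeIn TrialSet the raw data array
#' @export
setMethod("trialData", "TrialSet", function(x) x@data)

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@fs))
  cat(sprintf("  t0 = %g s; classes: %s\n", object@t0,
              paste(sprintf("%d (n=%d)", as.integer(names(table(object@labels))),
                            as.integer(table(object@labels))),
                    collapse = ", ")))
})

setMethod("nTrials", "SPDSet", function(x) dim(x@covs[[1L]])[1L])
setMethod("nChannels", "SPDSet", function(x) dim(x@covs[[1L]])[2L])
setMethod("trialLabels", "SPDSet", function(x) x@labels)

#' Number of frequency bands in an SPDSet
#' @param x an [SPDSet-class]
#' @return integer count
#' @export
nBands <- function(x) length(x@covs)

#' Extract the covariance matrix of one (trial, band)
#' @param x an [SPDSet-class]
#' @param trial trial index
#' @param band band index
#' @return a `C x C` SPD matrix
#' @export
covMatrix <- function(x, trial, band = 1L) {
  stopifnot(is(x, "SPDSet"))
  x@covs[[band]][trial, , ]
}

setMethod("show", "SPDSet", function(object) {
  cat(sprintf("SPDSet: %d trials, %d channels, %d band(s)\n",
              nTrials(object), nChannels(object), nBands(object)))
})

setMethod("show", "TangentBasis", function(object) {
  cat(sprintf("TangentBasis: %dx%d reference (Frechet mean, %d iterations)\n",
              nrow(object@reference), ncol(object@reference),
              object@iterations))
})

#' Construct a FeatureMatrix
#' @param X numeric design matrix `n x p`.
#' @param y optional numeric response of length `n`.
#' @param columnInfo optional data.frame of per-column metadata.
#' @return a [FeatureMatrix-class]
#' @export
FeatureMatrix <- function(X, y = numeric(), columnInfo = data.frame()) {
  new("FeatureMatrix", X = as.matrix(X), y = as.numeric(y),
      columnInfo = columnInfo)
}

#' @describeIn FeatureMatrix the design matrix
#' @param x a FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@X)

#' @describeIn FeatureMatrix the response vector
#' @export
setMethod("response", "FeatureMatrix", function(x) x@y)

#' @describeIn FeatureMatrix per-column metadata
#' @export
setMethod("columnInfo", "FeatureMatrix", function(x) x@columnInfo)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features%s\n",
              nrow(object@X), ncol(object@X),
              if (length(object@y)) " (with response)" else ""))
})

#' @describeIn MipfLassoFit coefficients on the standardized-column scale
#' @param object a MipfLassoFit
#' @param ... unused
#' @export
setMethod("coefficients", "MipfLassoFit", function(object, ...) object@beta)

#' @describeIn MipfLassoFit indices of the selected (nonzero) features
#' @param fit a MipfLassoFit
#' @export
setMethod("selectFeatures", "MipfLassoFit", function(fit) fit@support)

setMethod("show", "MipfLassoFit", function(object) {
  cat(sprintf(
    "MipfLassoFit (%s): %d/%d features selected\n",
    object@variant, length(object@support), length(object@beta)))
  cat(sprintf("  lambda1 = %g, lambda2 = %g; %d sweeps (%s); objective %.6g\n",
              object@lambda1, object@lambda2, object@nSweeps,
              if (object@converged) "converged" else "NOT converged",
              object@objective))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  accuracy %.4f +/- %.4f | F1 %.4f +/- %.4f | G-mean %.4f +/- %.4f\n",
              object@accuracy, object@sd[["accuracy"]],
              object@f1, object@sd[["f1"]],
              object@gmean, object@sd[["gmean"]]))
  cat(sprintf("  %d folds; pooled confusion:\n", nrow(object@perFold)))
  print(object@confusion)
})
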