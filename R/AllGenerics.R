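#' Number of trials
#' @param x a [TrialSet-class] or [SPDSet-class]
#' @return integer count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of channels
#' @param x a [TrialSet-class] or [SPDSet-class]
#' @return integer count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of samples per trial
#' @param x a [TrialSet-class]
#' @return integer count
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate (Hz)
#' @param x a [TrialSet-class]
#' @return numeric scalar
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Per-trial class labels
#' @param x a [TrialSet-class], [SPDSet-class] or [FeatureMatrix-class]
#' @return integer vector
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Raw trial data array
#' @param x a [TrialSet-class]
#' @return numeric array `n_trials x n_channels x n_samples`
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' Design matrix of a FeatureMatrix
#' @param x a [FeatureMatrix-class]
#' @return numeric matrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Response vector of a FeatureMatrix
#' @param x a [FeatureMatrix-class]
#' @return numeric vector (length 0 if unset)
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' Column metadata of a FeatureMatrix
#' @param x a [FeatureMatrix-class]
#' @return data.frame
#' @export
setGeneric("columnInfo", function(x) standardGeneric("columnInfo"))

#' Coefficients of a fit on the standardized-column scale
#' @param object a [MipfLassoFit-class]
#' @param ... unused
#' @return numeric vector
#' @export
setGeneric("coefficients")

#' Selected feature indices of a fit
#'
#' Indices `j` with `|beta_j| > 1e-8`, ascending.
#' @param fit a [MipfLassoFit-class]
#' @return integer vector
#' @export
setGeneric("selectFeatures", function(fit) standardGeneric("selectFeatures"))
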