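# Portable text epoch container: a directory holding meta.json (fs, t0,
# labels, channel names, dimensions) and data.csv (trials*channels rows
# x samples columns, trial-major).

#' Write a TrialSet to the text epoch container
#'
#' @param x a [TrialSet-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeTrialSet <- function(x, path) {
  stopifnot(is(x, "TrialSet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x@data)
  meta <- list(fs = x@fs, t0 = x@t0, labels = x@labels,
               channel_names = x@channelNames,
               n_trials = d[1L], n_channels = d[2L], n_samples = d[3L])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(x@data, c(3L, 2L, 1L)), nrow = d[1L] * d[2L],
                 ncol = d[3L], byrow = TRUE)
  utils::write.table(flat, file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TrialSet from the text epoch container
#'
#' @param path directory written by [writeTrialSet()].
#' @return a [TrialSet-class].
#' @export
readTrialSet <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"),
                                      sep = ",", header = FALSE))
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  dat <- aperm(array(t(flat), c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  TrialSet(dat, fs = meta$fs, labels = meta$labels, t0 = meta$t0,
           channelNames = as.character(meta$channel_names %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a FeatureMatrix as CSV with a JSON metadata sidecar
#'
#' @param fm a [FeatureMatrix-class].
#' @param path basename; writes `<path>.csv` (the design matrix, plus a
#'   `y` column when a response is present) and `<path>.json` (column
#'   metadata).
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  df <- as.data.frame(featureValues(fm))
  names(df) <- sprintf("f%d", seq_len(ncol(df)))
  if (length(response(fm))) df$y <- response(fm)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(columnInfo(fm), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fit as JSON
#'
#' @param fit a [MipfLassoFit-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFit <- function(fit, path) {
  stopifnot(is(fit, "MipfLassoFit"))
  jsonlite::write_json(
    list(variant = fit@variant, lambda1 = fit@lambda1,
         lambda2 = fit@lambda2, beta = fit@beta,
         betaOrig = fit@betaOrig, intercept = fit@intercept,
         support = fit@support, nSweeps = fit@nSweeps,
         converged = fit@converged, objective = fit@objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize an EvalReport as JSON
#'
#' @param report an [EvalReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  cfg <- report@config
  cfg <- cfg[vapply(cfg, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  jsonlite::write_json(
    list(accuracy = report@accuracy, f1 = report@f1,
         gmean = report@gmean, sd = as.list(report@sd),
         perFold = report@perFold,
         confusion = as.data.frame.matrix(report@confusion),
         config = cfg),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
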