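#' Pipeline configuration
#'
#' Collects every setting of the end-to-end run: data source, analysis
#' window, filter bank, covariance shrinkage, MI binning, penalty
#' variant and strengths, folds and seed. Either `data` (a
#' [TrialSet-class]) or `trialSpec` (a [trialGenSpec()] for the
#' synthetic generator) must be supplied.
#'
#' @param data a [TrialSet-class], or `NULL` to generate from
#'   `trialSpec`.
#' @param trialSpec a [trialGenSpec()] (used when `data` is `NULL`).
#' @param window a [windowSpec()] or `NULL` for the full epoch.
#' @param bank a [filterBankSpec()]; ignored when `bands` is given.
#' @param bands optional explicit band table (data.frame with `low`,
#'   `high` in Hz) overriding the bank tiling.
#' @param filterOrder Butterworth order for explicit `bands`.
#' @param shrinkage covariance shrinkage mode (see
#'   [sampleCovariance()]).
#' @param nBins equal-frequency bins for the MI estimator.
#' @param r MI weight trade-off parameter (default 5).
#' @param variant solver variant (see [solverConfig()]).
#' @param lambda1 adaptive-L1 strength, or `NULL` to set it per fold to
#'   `lambda1Frac` times the smallest value that zeroes every
#'   coefficient.
#' @param lambda1Frac fraction used when `lambda1` is `NULL`.
#' @param lambda2 fusion strength.
#' @param folds stratified CV folds.
#' @param seed integer seed controlling folds and classifier tuning.
#' @param verbose log stage dimensions and timings via `message()`.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(data = NULL, trialSpec = NULL, window = NULL,
                           bank = filterBankSpec(), bands = NULL,
                           filterOrder = 2L, shrinkage = "lw",
                           nBins = 8L, r = 5, variant = "mipf",
                           lambda1 = NULL, lambda1Frac = 0.05,
                           lambda2 = 0.1, folds = 5L, seed = 1L,
                           verbose = FALSE) {
  if (is.null(data) && is.null(trialSpec))
    stop("supply either data or trialSpec")
  structure(list(data = data, trialSpec = trialSpec, window = window,
                 bank = bank, bands = bands,
                 filterOrder = as.integer(filterOrder),
                 shrinkage = shrinkage, nBins = as.integer(nBins), r = r,
                 variant = variant, lambda1 = lambda1,
                 lambda1Frac = lambda1Frac, lambda2 = lambda2,
                 folds = as.integer(folds), seed = as.integer(seed),
                 verbose = verbose),
            class = "PipelineConfig")
}

# Filter a TrialSet per row of an explicit band table.
filterBandsTable <- function(trials, bandsTab, order = 2L) {
  fs <- trials@fs
  if (max(bandsTab$high) >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  d <- trials@data
  out <- vector("list", nrow(bandsTab))
  for (b in seq_len(nrow(bandsTab))) {
    fd <- d
    for (tr in seq_len(dim(d)[1L]))
      for (ch in seq_len(dim(d)[2L]))
        fd[tr, ch, ] <- butterBandpass(d[tr, ch, ], bandsTab$low[b],
                                       bandsTab$high[b], fs, order)
    out[[b]] <- TrialSet(fd, fs, trials@labels, trials@t0,
                         trials@channelNames)
  }
  names(out) <- sprintf("%g-%g", bandsTab$low, bandsTab$high)
  attr(out, "bands") <- bandsTab
  out
}

spdSubset <- function(spd, idx) {
  new("SPDSet",
      covs = lapply(spd@covs, function(a) a[idx, , , drop = FALSE]),
      bands = spd@bands, labels = spd@labels[idx])
}

# Per-fold fitting on training trials only: tangent bases, MI weights,
# penalized selection. Returns the selected columns, the fitted
# classifier and diagnostics. Test data never enter this function.
fitPipelineFold <- function(spdTrain, cfg, foldSeed) {
  labels <- spdTrain@labels
  bases <- lapply(spdTrain@covs, function(a) fitTangentBasis(a))
  fmTr <- buildFeatureMatrix(spdTrain, bases)
  Xtr <- featureValues(fmTr)
  keep <- which(apply(Xtr, 2L, stats::sd) > 1e-12)
  Xtr <- Xtr[, keep, drop = FALSE]
  classes <- sort(unique(labels))
  I <- miScores(Xtr, labels, cfg$nBins)
  aw <- adaptiveWeights(I, cfg$r)
  selectOne <- function(yBin) {
    l1 <- cfg$lambda1
    if (is.null(l1)) {
      std <- standardizeColumns(Xtr)
      ycd <- codeResponse(yBin)$y
      l1 <- cfg$lambda1Frac *
        2 * max(abs(crossprod(std$X, ycd)) / aw$alpha)
    }
    fit <- fitMipfLasso(Xtr, yBin, alpha = aw,
                        config = solverConfig(lambda1 = l1,
                                              lambda2 = cfg$lambda2,
                                              variant = cfg$variant))
    fit
  }
  if (length(classes) == 2L) {
    fit <- selectOne(labels)
    support <- fit@support
    lambda1 <- fit@lambda1
  } else {
    fits <- lapply(classes, function(cl) selectOne(as.integer(labels == cl)))
    support <- sort(unique(unlist(lapply(fits, slot, "support"))))
    lambda1 <- fits[[1L]]@lambda1
    fit <- fits[[1L]]
  }
  if (!length(support))
    support <- order(I, decreasing = TRUE)[seq_len(min(10L, ncol(Xtr)))]
  clf <- trainClassifier(Xtr[, support, drop = FALSE], labels,
                         seed = foldSeed)
  list(bases = bases, keep = keep, support = support, fit = fit,
       lambda1 = lambda1, mi = I, classifier = clf)
}

#' Run the full decoding pipeline with cross-validated evaluation
#'
#' Executes window extraction, the band-pass filter bank, per-band
#' covariance estimation, tangent-space mapping, mutual-information
#' weight construction, MIPF-LASSO feature selection and RBF-SVM
#' classification under stratified k-fold cross-validation. All
#' data-dependent fitting (tangent bases, MI weights, selection,
#' classifier) happens inside training folds only; test trials are only
#' projected and scored. Multi-class labels use one-vs-rest selection
#' (union of supports), a natively multi-class SVM, and macro-averaged
#' F1/G-mean.
#'
#' @param config a [pipelineConfig()].
#' @return an [EvalReport-class].
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]
  ts <- if (!is.null(config$data)) config$data else
    genTwoClassTrials(config$trialSpec)
  say("input: %d trials x %d channels x %d samples @ %g Hz",
      nTrials(ts), nChannels(ts), nSamples(ts), samplingRate(ts))
  if (!is.null(config$window)) {
    ts <- extractWindow(ts, config$window)
    say("window [%g, %g): %d samples", config$window$t_start,
        config$window$t_end, nSamples(ts))
  }
  bandList <- if (!is.null(config$bands)) {
    filterBandsTable(ts, as.data.frame(config$bands), config$filterOrder)
  } else {
    filterBank(ts, config$bank)
  }
  say("filter bank: %d bands (%.2f s)", length(bandList),
      proc.time()[["elapsed"]] - t0)
  spd <- trialCovariances(bandList, config$shrinkage)
  labels <- trialLabels(spd)
  fold <- stratifiedFolds(labels, config$folds, config$seed)
  classes <- sort(unique(labels))
  perFold <- data.frame()
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, pred = classes))
  for (f in seq_len(config$folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L)
      stop(sprintf("fold %d training set has a single class", f))
    model <- fitPipelineFold(spdSubset(spd, which(tr)), config,
                             foldSeed = config$seed * 1000L + f)
    fmTe <- buildFeatureMatrix(spdSubset(spd, which(!tr)), model$bases)
    Xte <- featureValues(fmTe)[, model$keep, drop = FALSE]
    pred <- predict(model$classifier,
                    Xte[, model$support, drop = FALSE])
    yte <- labels[!tr]
    m <- macroMetrics(yte, as.integer(as.character(pred)))
    perFold <- rbind(perFold,
                     data.frame(fold = f, accuracy = m[["accuracy"]],
                                f1 = m[["f1"]], gmean = m[["gmean"]],
                                nSelected = length(model$support),
                                lambda1 = model$lambda1))
    tab <- table(factor(yte, levels = classes),
                 factor(as.integer(as.character(pred)), levels = classes))
    confusion <- confusion + matrix(as.integer(tab), length(classes),
                                    dimnames = dimnames(confusion))
    say("fold %d: accuracy %.3f, %d features (%.2f s)", f,
        m[["accuracy"]], length(model$support),
        proc.time()[["elapsed"]] - t0)
  }
  sds <- c(accuracy = stats::sd(perFold$accuracy),
           f1 = stats::sd(perFold$f1),
           gmean = stats::sd(perFold$gmean))
  cfgEcho <- config
  cfgEcho$data <- NULL  # don't carry the raw array in the report
  new("EvalReport",
      accuracy = mean(perFold$accuracy), f1 = mean(perFold$f1),
      gmean = mean(perFold$gmean), perFold = perFold, sd = sds,
      confusion = confusion, config = unclass(cfgEcho))
}
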