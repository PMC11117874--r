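# Stratified fold assignment: within each class, indices are shuffled
# and dealt round-robin, so folds are balanced to within one trial.
stratifiedFolds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop("k_folds must be >= 2")
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated tuning of the MIPF-LASSO penalties
#'
#' Stratified k-fold cross-validation over a `(lambda1, lambda2)` grid.
#' The score is, per held-out fold, either the accuracy of an RBF-SVM
#' trained on the selected features (`scoring = "accuracy"`, for
#' classification responses) or the held-out mean squared error of an
#' ordinary least-squares refit on the selected features
#' (`scoring = "mse"`). Ties are broken toward larger
#' `lambda1`, then larger `lambda2` (the sparser, more regularized
#' model). Deterministic given `seed`.
#'
#' @param X design matrix or [FeatureMatrix-class].
#' @param y response (class labels for `"accuracy"` scoring).
#' @param alpha adaptive weight vector (default all 1).
#' @param lambda1Grid,lambda2Grid nonempty penalty grids.
#' @param kFolds number of folds (`>= 2`).
#' @param seed integer seed controlling the fold split.
#' @param scoring `"accuracy"` or `"mse"`.
#' @param rule `"min"` (default) picks the best mean score outright;
#'   `"1se"` picks the most regularized grid point whose mean score is
#'   within one standard error of the best.
#' @param config base [solverConfig()]; its lambdas are overridden by
#'   the grid point.
#' @return list with `lambda1`, `lambda2`, and `cvTable` (one row per
#'   grid point with the mean fold score).
#' @export
tuneMipfLasso <- function(X, y, alpha = NULL,
                          lambda1Grid, lambda2Grid = 0,
                          kFolds = 5L, seed = 1L,
                          scoring = c("accuracy", "mse"),
                          rule = c("min", "1se"),
                          config = solverConfig(variant = "mipf")) {
  scoring <- match.arg(scoring)
  rule <- match.arg(rule)
  if (!length(lambda1Grid) || !length(lambda2Grid))
    stop("penalty grids must be nonempty")
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- response(X)
    X <- featureValues(X)
  }
  n <- nrow(X)
  stopifnot(length(y) == n)
  strat <- if (scoring == "accuracy") y else rep(1L, n)
  fold <- stratifiedFolds(strat, kFolds, seed)
  if (scoring == "accuracy") {
    for (f in seq_len(kFolds)) {
      if (length(unique(y[fold != f])) < 2L)
        stop(sprintf("fold %d training set has a single class", f))
    }
  }
  lambda1Grid <- sort(lambda1Grid, decreasing = TRUE)
  lambda2Grid <- sort(lambda2Grid)
  grid <- expand.grid(lambda1 = lambda1Grid, lambda2 = lambda2Grid)
  scores <- matrix(NA_real_, nrow(grid), kFolds)
  sizes <- matrix(NA_real_, nrow(grid), kFolds)
  for (f in seq_len(kFolds)) {
    tr <- fold != f
    for (l2i in seq_along(lambda2Grid)) {
      warm <- NULL
      for (l1i in seq_along(lambda1Grid)) {
        g <- (l2i - 1L) * length(lambda1Grid) + l1i
        cfg <- config
        cfg$lambda1 <- grid$lambda1[g]
        cfg$lambda2 <- grid$lambda2[g]
        fit <- fitMipfLasso(X[tr, , drop = FALSE], y[tr], alpha,
                            config = cfg, beta0 = warm)
        warm <- fit@betaStar
        sizes[g, f] <- length(fit@support)
        scores[g, f] <- if (scoring == "mse") {
          -scoreRefitMSE(X, y, tr, fit@support)
        } else {
          scoreWithSVM(X, y, tr, fit@support, seed)
        }
      }
    }
  }
  cvTable <- cbind(grid,
                   score = rowMeans(scores),
                   meanSupport = rowMeans(sizes))
  if (scoring == "mse") cvTable$score <- -cvTable$score
  best <- bestGridPoint(grid, scores, rule)
  list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
       cvTable = cvTable, scoring = scoring, rule = rule)
}

# "min": highest mean score; ties (within 1e-12) go to larger lambda1,
# then larger lambda2. "1se": among points within one standard error of
# the best mean, the one with largest lambda1 then lambda2.
bestGridPoint <- function(grid, scores, rule = "min") {
  meanScore <- rowMeans(scores)
  margin <- if (rule == "1se") {
    b <- which.max(meanScore)
    stats::sd(scores[b, ]) / sqrt(ncol(scores))
  } else 0
  top <- which(meanScore >= max(meanScore) - margin - 1e-12)
  top <- top[order(grid$lambda1[top], grid$lambda2[top],
                   decreasing = TRUE)]
  top[1L]
}

# Held-out MSE of an ordinary least-squares refit on the selected
# columns (the regression analogue of refitting the classifier on the
# selected features, and free of the L1 shrinkage bias). An empty
# support predicts the training mean.
scoreRefitMSE <- function(X, y, tr, support) {
  yte <- y[!tr]
  if (!length(support)) return(mean((yte - mean(y[tr]))^2))
  Xs <- X[, support, drop = FALSE]
  colnames(Xs) <- sprintf("f%d", seq_along(support))
  df <- data.frame(y = y[tr], Xs[tr, , drop = FALSE])
  fit <- stats::lm(y ~ ., data = df)
  pred <- stats::predict(fit, as.data.frame(Xs[!tr, , drop = FALSE]))
  mean((yte - pred)^2)
}

# Held-out accuracy of an RBF-SVM on the selected columns; an empty
# support falls back to majority-class prediction.
scoreWithSVM <- function(X, y, tr, support, seed) {
  yte <- y[!tr]
  if (!length(support)) {
    maj <- names(which.max(table(y[tr])))
    return(mean(as.character(yte) == maj))
  }
  Xtr <- X[tr, support, drop = FALSE]
  Xte <- X[!tr, support, drop = FALSE]
  clf <- withSeed(seed, e1071::svm(Xtr, factor(y[tr]), kernel = "radial",
                                   cost = 1, gamma = 1 / ncol(Xtr),
                                   scale = FALSE))
  mean(as.character(stats::predict(clf, Xte)) == as.character(yte))
}
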