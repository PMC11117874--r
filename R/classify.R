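#' Train an RBF-kernel SVM with inner-CV hyperparameter selection
#'
#' Fits a max-margin classifier with a radial-basis kernel; the
#' regularization strength (`cost`) and kernel width (`gamma`) are
#' chosen by stratified inner cross-validation over a small grid.
#' Features are standardized with training statistics stored in the
#' model. Deterministic given `seed`.
#'
#' @param X numeric feature matrix (rows = trials).
#' @param labels class labels (at least 2 classes present).
#' @param seed integer seed controlling the inner folds.
#' @param costGrid candidate `cost` values.
#' @param gammaGrid candidate `gamma` values; default
#'   `c(0.5, 1, 2) / ncol(X)`.
#' @param innerFolds folds of the inner CV.
#' @return a list of class `"MipfClassifier"` with the fitted svm, the
#'   chosen hyperparameters, the inner-CV accuracy and the feature
#'   scaling.
#' @export
trainClassifier <- function(X, labels, seed = 1L,
                            costGrid = c(1, 10, 100),
                            gammaGrid = NULL, innerFolds = 3L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite")
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("training set contains a single class")
  if (is.null(gammaGrid)) gammaGrid <- c(0.5, 1, 2) / ncol(X)
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  grid <- expand.grid(cost = costGrid, gamma = gammaGrid)
  fold <- stratifiedFolds(as.integer(labels), innerFolds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(innerFolds), function(f) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      m <- e1071::svm(Xs[tr, , drop = FALSE], labels[tr],
                      kernel = "radial", cost = grid$cost[g],
                      gamma = grid$gamma[g], scale = FALSE)
      mean(stats::predict(m, Xs[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)  # ties: first grid point, fixed ordering
  model <- e1071::svm(Xs, labels, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(list(model = model, cost = grid$cost[best],
                 gamma = grid$gamma[best], cvAccuracy = acc[best],
                 center = ctr, scale = sds),
            class = "MipfClassifier")
}

#' Predict classes with a trained classifier
#' @param object a `"MipfClassifier"` from [trainClassifier()].
#' @param newdata feature matrix on the original scale.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.MipfClassifier <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, "/")
  stats::predict(object$model, Xs)
}
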