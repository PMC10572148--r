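# Base learners --------------------------------------------------------------
#
# Five classifiers share one fit/predict contract: fit on a numeric feature
# matrix plus 0/1 label vector, predict a probability of the positive class.
# Concentrations are log(1+x)-transformed upstream and z-scaled with
# statistics fit on the training fold (see feature_matrix / scale_features);
# the scaling mainly stabilizes the SVM and logistic fits, tree models are
# unaffected.

BASE_LEARNERS <- c("logistic", "random_forest", "naive_bayes", "svm", "xgboost")
MODEL_NAMES <- c(BASE_LEARNERS, "stacking")

#' Default hyperparameters for the base learners
#'
#' Modest fixed settings chosen so that a full 255-panel sweep runs at desk
#' scale: 300 trees for the random forest, 60 boosting rounds of depth-3
#' trees (eta 0.3) for XGBoost, an RBF kernel with cost 1 for the SVM.
#' Each entry can be replaced, or turned into a list of candidate settings
#' for grid tuning (see [tune_learner()]).
#'
#' @return Named list of per-learner parameter lists.
#' @export
default_params <- function() {
  list(
    logistic = list(),
    random_forest = list(num.trees = 300),
    naive_bayes = list(laplace = 0),
    svm = list(kernel = "radial", cost = 1),
    xgboost = list(nrounds = 60, max_depth = 3, eta = 0.3)
  )
}

#' Fit a single base learner
#'
#' @param name One of `"logistic"`, `"random_forest"`, `"naive_bayes"`,
#'   `"svm"`, `"xgboost"`.
#' @param x Numeric feature matrix (rows = patients).
#' @param y Binary 0/1 labels (1 = MPE).
#' @param seed Integer seed controlling any stochastic component of the fit.
#' @param params Learner hyperparameters; defaults from [default_params()].
#' @return Object of class `base_fit`; score new data with
#'   [predict_prob()].
#' @export
fit_base_learner <- function(name, x, y, seed = 1L,
                             params = default_params()[[name]]) {
  name <- match.arg(name, BASE_LEARNERS)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- check_binary_labels(rep(0, length(y)), y)
  set.seed(derive_seed(seed, paste0("fit-", name)))
  df <- as.data.frame(x)
  fit <- switch(name,
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())),
    random_forest = ranger::ranger(
      x = df, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num.trees %||% 300,
      seed = derive_seed(seed, "ranger"), num.threads = 1),
    naive_bayes = e1071::naiveBayes(
      x = df, y = factor(y, levels = c(0, 1)),
      laplace = params$laplace %||% 0),
    svm = e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      kernel = params$kernel %||% "radial", cost = params$cost %||% 1,
      scale = FALSE),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds %||% 60, verbose = 0)
  )
  structure(list(name = name, fit = fit, columns = colnames(x)),
            class = "base_fit")
}

#' Predicted positive-class probability
#'
#' @param object A `base_fit` or `stacking_fit`.
#' @param x Numeric feature matrix with the training columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(object, x) UseMethod("predict_prob")

#' @export
predict_prob.base_fit <- function(object, x) {
  stopifnot(is.matrix(x), identical(colnames(x), object$columns))
  df <- as.data.frame(x)
  p <- switch(object$name,
    logistic = stats::predict(object$fit, newdata = df, type = "response"),
    random_forest = stats::predict(object$fit, data = df)$predictions[, "1"],
    naive_bayes = stats::predict(object$fit, newdata = df, type = "raw")[, "1"],
    svm = attr(stats::predict(object$fit, newdata = x, probability = TRUE),
               "probabilities")[, "1"],
    xgboost = stats::predict(object$fit, newdata = x)
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Select hyperparameters by inner cross-validated AUC
#'
#' Evaluates each candidate parameter set with stratified k-fold
#' cross-validation on the training data and returns the set with the best
#' pooled out-of-fold AUC (first candidate wins ties).  With a single
#' candidate (the default grids) no cross-validation is run.
#'
#' @inheritParams fit_base_learner
#' @param grid List of candidate parameter lists.
#' @param k Inner folds.
#' @return The selected parameter list.
#' @export
tune_learner <- function(name, x, y, grid, k = 3, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (length(grid) == 1L) return(grid[[1]])
  folds <- stratified_folds(y, k, derive_seed(seed, paste0("tune-", name)))
  auc <- vapply(grid, function(params) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      idx <- folds == f
      fit <- fit_base_learner(name, x[!idx, , drop = FALSE], y[!idx],
                              seed = seed, params = params)
      oof[idx] <- predict_prob(fit, x[idx, , drop = FALSE])
    }
    compute_auc(oof, y)
  }, numeric(1))
  grid[[which.max(auc)]]
}

#' Stratified fold assignment
#'
#' Shuffles each class separately and deals its members round-robin over the
#' `k` folds, so every fold holds both classes whenever each class has at
#' least `k` members.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  stopifnot(k >= 2, length(y) >= k)
  if (k == length(y)) return(seq_along(y))  # leave-one-out
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
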