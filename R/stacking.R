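# Stacked ensemble -----------------------------------------------------------
#
# The stacking model learns a logistic-regression meta-learner on the
# out-of-fold predicted probabilities of the five base learners, so the
# meta-learner never sees a prediction made by a model that was trained on
# the same patient.  The final base learners are refit on the full training
# data for use at prediction time.

#' Fit the stacked ensemble
#'
#' @param x Numeric feature matrix (training data).
#' @param y Binary 0/1 labels (1 = positive/MPE).
#' @param inner_folds Number of stratified inner folds used to build the
#'   out-of-fold meta-features (>= 2).
#' @param seed Integer seed; drives the inner split and every base fit.
#' @param params Per-learner hyperparameters ([default_params()]).
#' @return Object of class `stacking_fit`; score new data with
#'   [predict_prob()].
#' @export
fit_stacking <- function(x, y, inner_folds = 3, seed = 1L,
                         params = default_params()) {
  stopifnot(is.matrix(x), nrow(x) == length(y), inner_folds >= 2)
  y <- check_binary_labels(rep(0, length(y)), y)
  folds <- stratified_folds(y, inner_folds, derive_seed(seed, "stack-inner"))
  for (f in seq_len(inner_folds)) {
    if (length(unique(y[folds != f])) < 2L) {
      stop("a class is absent from an inner training fold; ",
           "use fewer folds or more data")
    }
  }
  meta <- matrix(NA_real_, nrow(x), length(BASE_LEARNERS),
                 dimnames = list(NULL, BASE_LEARNERS))
  for (f in seq_len(inner_folds)) {
    idx <- folds == f
    for (nm in BASE_LEARNERS) {
      fit <- fit_base_learner(nm, x[!idx, , drop = FALSE], y[!idx],
                              seed = derive_seed(seed, paste0("inner", f)),
                              params = params[[nm]])
      meta[idx, nm] <- predict_prob(fit, x[idx, , drop = FALSE])
    }
  }
  meta_df <- as.data.frame(meta)
  meta_fit <- suppressWarnings(
    stats::glm(y ~ ., data = cbind(meta_df, y = y), family = stats::binomial()))
  base_full <- lapply(stats::setNames(BASE_LEARNERS, BASE_LEARNERS),
                      function(nm) fit_base_learner(
                        nm, x, y, seed = derive_seed(seed, "full"),
                        params = params[[nm]]))
  structure(list(meta_fit = meta_fit, base_fits = base_full,
                 columns = colnames(x), inner_folds = inner_folds,
                 seed = seed),
            class = "stacking_fit")
}

#' @export
predict_prob.stacking_fit <- function(object, x) {
  stopifnot(is.matrix(x), identical(colnames(x), object$columns))
  meta <- vapply(object$base_fits, predict_prob, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) meta <- matrix(meta, 1, dimnames = list(NULL, names(object$base_fits)))
  p <- stats::predict(object$meta_fit, newdata = as.data.frame(meta),
                      type = "response")
  unname(pmin(pmax(as.numeric(p), 0), 1))
}
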