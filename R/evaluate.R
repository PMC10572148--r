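# Cross-validated panel evaluation -------------------------------------------

#' Build the feature matrix for a marker panel
#'
#' Features are the log(1+x)-transformed concentrations of the panel's
#' markers (columns in canonical marker order), age in years, and a male
#' indicator; the label is 1 for MPE.  Scaling is deliberately not applied
#' here: z-scaling statistics are fit inside each training fold (see
#' [cross_validated_evaluate()]) to avoid leaking test-fold information.
#'
#' @param cohort Cohort data frame.
#' @param panel Character vector of marker ids (non-empty subset of the 8).
#' @return List with `x` (numeric matrix) and `y` (0/1 integer labels).
#' @export
feature_matrix <- function(cohort, panel) {
  validate_cohort(cohort)
  panel <- validate_panel(panel)
  x <- cbind(log1p(as.matrix(cohort[panel])),
             age = cohort$age,
             male = as.numeric(cohort$gender == "male"))
  colnames(x) <- c(panel, "age", "male")
  list(x = x, y = as.integer(cohort$group == "MPE"))
}

# Per-column z-scaling with statistics from the training rows only.
scale_features <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  s <- apply(x_train, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, s, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, s, "/"))
}

# Fit any of the six models on a (scaled) training matrix.
fit_model <- function(model, x, y, seed, params = default_params(),
                      inner_folds = 3) {
  model <- match.arg(model, MODEL_NAMES)
  if (model == "stacking") {
    fit_stacking(x, y, inner_folds = inner_folds, seed = seed, params = params)
  } else {
    fit_base_learner(model, x, y, seed = seed, params = params[[model]])
  }
}

#' Cross-validated evaluation of one (panel, model) pair
#'
#' Stratified k-fold cross-validation: each patient receives exactly one
#' out-of-fold predicted probability from a model that never saw them in
#' training; the out-of-fold scores are pooled over all patients and a
#' single AUC plus sensitivity/specificity are computed on the pooled
#' vector.  Features are z-scaled with statistics fit on each training fold.
#'
#' @param cohort Cohort data frame.
#' @param panel Marker panel (character vector or `+`-joined string).
#' @param model One of `"logistic"`, `"random_forest"`, `"naive_bayes"`,
#'   `"svm"`, `"xgboost"`, `"stacking"`.
#' @param k Number of outer folds (default 3; `k = n` gives leave-one-out).
#' @param seed Integer master seed.
#' @param threshold Probability threshold for sensitivity/specificity
#'   (default 0.5), or `"youden"` for the Youden-optimal threshold on the
#'   pooled out-of-fold scores.
#' @param params Hyperparameters ([default_params()]); each entry may be a
#'   list of candidates, tuned by inner cross-validated AUC per training
#'   fold.
#' @param inner_folds Inner folds for stacking meta-features (and tuning).
#' @return One-row data frame: `panel`, `model`, `auc`, `sensitivity`,
#'   `specificity`, `threshold`, `k`, `seed`; the pooled out-of-fold scores
#'   are attached as attribute `"oof"`.
#' @export
cross_validated_evaluate <- function(cohort, panel, model, k = 3, seed = 1L,
                                     threshold = 0.5,
                                     params = default_params(),
                                     inner_folds = 3) {
  if (is.character(panel) && length(panel) == 1L && grepl("+", panel, fixed = TRUE)) {
    panel <- parse_panel(panel)
  }
  fm <- feature_matrix(cohort, panel)
  stopifnot(k >= 2, min(table(fm$y)) >= if (k == length(fm$y)) 2 else k)
  folds <- stratified_folds(fm$y, k, derive_seed(seed, "outer"))
  oof <- rep(NA_real_, length(fm$y))
  for (f in sort(unique(folds))) {
    idx <- folds == f
    sc <- scale_features(fm$x[!idx, , drop = FALSE], fm$x[idx, , drop = FALSE])
    fold_seed <- derive_seed(seed, paste0("outer-fold", f))
    fold_params <- resolve_params(model, sc$train, fm$y[!idx], params,
                                  inner_folds, fold_seed)
    fit <- fit_model(model, sc$train, fm$y[!idx], seed = fold_seed,
                     params = fold_params, inner_folds = inner_folds)
    oof[idx] <- predict_prob(fit, sc$test)
  }
  thr <- if (identical(threshold, "youden")) {
    youden_threshold(oof, fm$y)
  } else threshold
  ss <- sens_spec(oof, fm$y, thr)
  rec <- data.frame(panel = panel_string(panel), model = model,
                    auc = compute_auc(oof, fm$y),
                    sensitivity = unname(ss["sensitivity"]),
                    specificity = unname(ss["specificity"]),
                    threshold = thr, k = k, seed = seed)
  attr(rec, "oof") <- oof
  rec
}

# Expand any grid entries (lists of candidate lists) into a single chosen
# parameter set per learner for this training fold.
resolve_params <- function(model, x, y, params, inner_folds, seed) {
  learners <- if (model == "stacking") BASE_LEARNERS else model
  out <- params
  for (nm in learners) {
    p <- params[[nm]]
    if (is.list(p) && length(p) && all(vapply(p, is.list, logical(1)))) {
      out[[nm]] <- tune_learner(nm, x, y, grid = p, k = inner_folds,
                                seed = seed)
    }
  }
  out
}

#' Evaluate many panels, optionally resumable
#'
#' Runs [cross_validated_evaluate()] for every (panel, model) combination.
#' Each combination derives its own seed from the master seed and the panel
#' string, so results do not depend on evaluation order.  When `out_csv` is
#' given, records are appended as they complete and combinations already
#' present in the file are skipped, making an interrupted run resumable with
#' an identical final file.
#'
#' @param cohort Cohort data frame.
#' @param panels List of marker panels (default: all 255).
#' @param models Character vector of model names (default `"stacking"`).
#' @inheritParams cross_validated_evaluate
#' @param out_csv Optional path for incremental output.
#' @param quiet Suppress per-panel progress messages.
#' @return Data frame of performance records (one row per panel x model).
#' @export
evaluate_panels <- function(cohort, panels = enumerate_panels(),
                            models = "stacking", k = 3, seed = 1L,
                            threshold = 0.5, params = default_params(),
                            out_csv = NULL, quiet = FALSE) {
  stopifnot(all(models %in% MODEL_NAMES))
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
  }
  rows <- if (is.null(done)) list() else list(done)
  for (panel in panels) {
    ps <- panel_string(panel)
    for (model in models) {
      if (!is.null(done) &&
          any(done$panel == ps & done$model == model)) next
      rec <- cross_validated_evaluate(
        cohort, panel, model, k = k,
        seed = derive_seed(seed, paste0(ps, "|", model)),
        threshold = threshold, params = params)
      attr(rec, "oof") <- NULL
      if (!quiet) message(sprintf("%-60s %-13s AUC %.3f", ps, model, rec$auc))
      if (!is.null(out_csv)) {
        utils::write.table(rec, out_csv, sep = ",", row.names = FALSE,
                           col.names = !file.exists(out_csv), append = file.exists(out_csv))
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
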