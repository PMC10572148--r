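# Cohort specification -------------------------------------------------------
#
# A cohort spec holds everything the simulator needs: two group blocks (MPE,
# BPE) with sample size, age moments, exact gender counts and per-marker
# (mean, sd) pairs, plus an 8x8 latent correlation matrix for the Gaussian
# copula and a default seed.

#' Moment-match a lognormal to a target mean and standard deviation
#'
#' Returns the `(mu, sigma)` parameters of the lognormal distribution whose
#' mean and standard deviation equal the given values:
#' `sigma^2 = log(1 + sd^2 / mean^2)`, `mu = log(mean) - sigma^2 / 2`.
#' Marker concentrations are strictly positive with standard deviations that
#' typically exceed the mean several-fold, so a heavy right-skewed positive
#' family is required; the lognormal is the simplest such family that can be
#' matched in closed form.
#'
#' @param mean Target mean, strictly positive.
#' @param sd Target standard deviation, non-negative. `sd = 0` yields the
#'   degenerate point mass at `mean` (`sigma = 0`).
#' @return Named numeric vector `c(mu =, sigma =)`.
#' @export
#' @examples
#' lognormal_params_from_moments(16.80, 105.81)
lognormal_params_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(sd), length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0) stop("mean must be strictly positive")
  if (!is.finite(sd) || sd < 0) stop("sd must be non-negative")
  sigma2 <- log1p((sd / mean)^2)
  c(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Construct a group specification
#'
#' @param label `"MPE"` or `"BPE"`.
#' @param n Number of patients.
#' @param age_mean,age_sd Age moments in years.
#' @param male,female Exact gender counts; must sum to `n`.
#' @param marker_moments Data frame with columns `marker`, `mean`, `sd`
#'   covering all eight markers (CEA in ng/mL, CA markers in U/mL).
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n, age_mean, age_sd, male, female, marker_moments) {
  stopifnot(label %in% c("MPE", "BPE"), n > 0, male >= 0, female >= 0)
  if (male + female != n) stop("male + female must equal n")
  stopifnot(is.data.frame(marker_moments),
            all(c("marker", "mean", "sd") %in% names(marker_moments)))
  if (!setequal(marker_moments$marker, marker_ids())) {
    stop("marker_moments must cover exactly the 8 markers")
  }
  if (any(marker_moments$mean <= 0)) stop("all marker means must be > 0")
  if (any(marker_moments$sd < 0)) stop("all marker sds must be >= 0")
  mm <- marker_moments[match(marker_ids("canonical"), marker_moments$marker), ]
  rownames(mm) <- NULL
  structure(list(label = label, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 male = as.integer(male), female = as.integer(female),
                 marker_moments = mm),
            class = "group_spec")
}

#' Default latent correlation matrix for the marker copula
#'
#' The study data are unavailable and no correlation structure is reported,
#' so the default encodes a plausible clinical pattern: the same analyte
#' measured in the two fluids is moderately correlated (0.4), distinct
#' analytes within one fluid weakly so (0.2), and cross-fluid cross-analyte
#' pairs weakest (0.1).  The matrix is configurable and no exact result in
#' the package depends on it.
#'
#' @param same_analyte,same_fluid,otherwise Latent correlations for the three
#'   pair classes.
#' @return 8x8 positive-semidefinite correlation matrix with dimnames.
#' @export
default_marker_correlation <- function(same_analyte = 0.4, same_fluid = 0.2,
                                       otherwise = 0.1) {
  ids <- marker_ids("canonical")
  an <- marker_analyte(ids); fl <- marker_fluid(ids)
  m <- matrix(otherwise, 8, 8, dimnames = list(ids, ids))
  m[outer(fl, fl, "==")] <- same_fluid
  m[outer(an, an, "==")] <- same_analyte
  diag(m) <- 1
  m
}

#' Construct a cohort specification
#'
#' @param mpe,bpe [group_spec()] objects for the two groups.
#' @param marker_correlation 8x8 symmetric PSD latent correlation matrix.
#' @param seed Default integer seed for generation.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(mpe, bpe,
                        marker_correlation = default_marker_correlation(),
                        seed = 1L) {
  stopifnot(inherits(mpe, "group_spec"), inherits(bpe, "group_spec"),
            mpe$label == "MPE", bpe$label == "BPE")
  validate_correlation(marker_correlation)
  structure(list(mpe = mpe, bpe = bpe,
                 marker_correlation = marker_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

validate_correlation <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(8L, 8L))) {
    stop("marker_correlation must be an 8x8 matrix")
  }
  if (max(abs(m - t(m))) > 1e-12) stop("marker_correlation must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-12) stop("correlation diagonal must be 1")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("marker_correlation is not positive semi-definite")
  invisible(m)
}

#' Built-in cohort specification matching the study's descriptive table
#'
#' Group sizes 111 (MPE) / 208 (BPE); ages 60.94 +/- 11.96 and
#' 49.78 +/- 19.02 years; gender 59/52 and 148/60 (male/female); and the
#' sixteen published per-group marker mean/sd pairs.
#'
#' @param marker_correlation Latent correlation matrix; defaults to
#'   [default_marker_correlation()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(marker_correlation = default_marker_correlation()) {
  mm <- function(...) {
    x <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(marker = marker_ids("csv"), mean = x[, 1], sd = x[, 2])
  }
  # per-group moments, rows in csv marker order:
  # PE.CEA, PE.CA19-9, PE.CA125, PE.CA15-3, PB.CEA, PB.CA19-9, PB.CA125, PB.CA15-3
  mpe_mm <- mm(967.15, 2307.31,
               2000.31, 4200.90,
               1807.16, 2473.70,
               99.97, 199.45,
               98.16, 254.14,
               628.56, 2312.09,
               257.72, 502.10,
               38.79, 47.97)
  bpe_mm <- mm(16.80, 105.81,
               5.74, 12.94,
               715.22, 796.83,
               7.48, 7.80,
               2.12, 1.74,
               13.88, 40.28,
               155.21, 147.49,
               12.01, 9.21)
  cohort_spec(
    mpe = group_spec("MPE", 111, 60.94, 11.96, male = 59, female = 52,
                     marker_moments = mpe_mm),
    bpe = group_spec("BPE", 208, 49.78, 19.02, male = 148, female = 60,
                     marker_moments = bpe_mm),
    marker_correlation = marker_correlation
  )
}

#' Scale a cohort specification to new group sizes
#'
#' Keeps all moments and the gender proportions (rounded to exact counts) but
#' replaces the group sizes; used for large-sample moment-recovery checks.
#'
#' @param spec A `cohort_spec`.
#' @param n_mpe,n_bpe New group sizes.
#' @return A `cohort_spec`.
#' @export
scale_cohort_spec <- function(spec, n_mpe, n_bpe) {
  rescale <- function(g, n) {
    male <- round(n * g$male / g$n)
    group_spec(g$label, n, g$age_mean, g$age_sd, male, n - male,
               g$marker_moments)
  }
  cohort_spec(rescale(spec$mpe, n_mpe), rescale(spec$bpe, n_bpe),
              spec$marker_correlation, spec$seed)
}
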