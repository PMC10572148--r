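# Synthetic cohort generation ------------------------------------------------

#' Derive a reproducible child seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed; stage- or
#' fold-specific seeds are derived deterministically from (seed, label) so
#' that evaluation order and resumption do not change results.
#'
#' @param seed Non-negative integer master seed.
#' @param label Character tag naming the consumer.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) %% 97)
  as.integer((seed + 7919 * h) %% (.Machine$integer.max - 1L))
}

#' Generate a synthetic pleural-effusion cohort
#'
#' Draws `spec$mpe$n + spec$bpe$n` patients.  Ages come from a group-specific
#' normal truncated to `[18, 100]` (resampling on violation); gender is
#' assigned as exact counts (a random permutation of the specified
#' male/female totals, reproducing the descriptive-table margins exactly);
#' the eight marker concentrations come from a Gaussian copula with the
#' spec's latent correlation and lognormal margins moment-matched per group
#' via [lognormal_params_from_moments()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical `(spec, seed)` yields a byte-identical
#'   table. Defaults to `spec$seed`.
#' @return Data frame with columns `patient_id`, `group`, `age`, `gender`
#'   and the eight marker columns (csv order). `group` is `"MPE"`/`"BPE"`.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_spec(), seed = 7)
#' table(coh$group)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_correlation(spec$marker_correlation)
  set.seed(derive_seed(seed, "cohort"))
  blocks <- lapply(list(spec$mpe, spec$bpe), generate_group,
                   correlation = spec$marker_correlation)
  out <- do.call(rbind, blocks)
  out$patient_id <- sprintf("P%04d", seq_len(nrow(out)))
  out[, c("patient_id", "group", "age", "gender", marker_ids("csv"))]
}

generate_group <- function(g, correlation) {
  age <- rnorm_truncated(g$n, g$age_mean, g$age_sd, 18, 100)
  gender <- sample(rep(c("male", "female"), c(g$male, g$female)))
  # latent Gaussian draws with the specified correlation, then lognormal
  # margins through the probability integral transform
  ids <- marker_ids("canonical")
  L <- chol_psd(correlation)
  z <- matrix(rnorm(g$n * 8), g$n, 8) %*% L
  u <- pnorm(z)
  conc <- matrix(NA_real_, g$n, 8, dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    row <- g$marker_moments[g$marker_moments$marker == ids[j], ]
    p <- lognormal_params_from_moments(row$mean, row$sd)
    conc[, j] <- if (p["sigma"] == 0) rep(row$mean, g$n) else
      qlnorm(u[, j], meanlog = p["mu"], sdlog = p["sigma"])
  }
  cbind(data.frame(group = g$label, age = age, gender = gender),
        as.data.frame(conc[, marker_ids("csv"), drop = FALSE]))
}

# Upper-triangular factor that tolerates semi-definite matrices.
chol_psd <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(vals)) %*% t(e$vectors))
}

rnorm_truncated <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Read / write the cohort CSV
#'
#' The on-disk format is a UTF-8, LF-terminated CSV with header
#' `patient_id,group,age,gender,PE.CEA,PE.CA19-9,PE.CA125,PE.CA15-3,PB.CEA,PB.CA19-9,PB.CA125,PB.CA15-3`.
#'
#' @param cohort Cohort data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort_csv()` returns the validated cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  con <- file(path, open = "wb")  # binary mode forces LF on all platforms
  on.exit(close(con))
  writeLines(paste(names(cohort), collapse = ","), con, sep = "\n")
  num <- vapply(cohort, is.numeric, logical(1))
  body <- cohort
  body[num] <- lapply(body[num], function(x) format(x, digits = 15, trim = TRUE,
                                                   scientific = FALSE))
  writeLines(do.call(paste, c(unname(body), sep = ",")), con, sep = "\n")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  expected <- c("patient_id", "group", "age", "gender", marker_ids("csv"))
  if (!identical(names(cohort), expected)) {
    stop("cohort columns must be exactly: ", paste(expected, collapse = ","))
  }
  if (anyNA(cohort)) stop("cohort contains missing cells")
  if (!all(cohort$group %in% c("MPE", "BPE"))) stop("group must be MPE or BPE")
  if (!all(cohort$gender %in% c("male", "female"))) {
    stop("gender must be male or female")
  }
  if (any(as.matrix(cohort[marker_ids("csv")]) <= 0)) {
    stop("all marker concentrations must be strictly positive")
  }
  invisible(cohort)
}
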