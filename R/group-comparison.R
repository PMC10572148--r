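# Group comparison (descriptive-table methodology) ---------------------------
#
# Continuous variables: two-sided Mann-Whitney U.  Categorical variables:
# Pearson chi-square without continuity correction when all expected counts
# are >= 5, otherwise Fisher's exact test (2x2 only).  Alpha = 0.05
# throughout, no multiplicity adjustment.

# Largest number of label assignments we will enumerate for an exact
# tied-sample Mann-Whitney p-value.
MW_EXACT_MAX_COMB <- 2e5

#' Two-sided Mann-Whitney U comparison of two samples
#'
#' The U statistic counts pairs `(x_i, y_j)` with `x_i > y_j`, ties counted
#' one half.  For groups of at most 20 each the p-value is exact: via the
#' null U distribution (`stats::pwilcox`) when there are no ties, or by
#' complete enumeration of label assignments when there are (feasible up to
#' `choose(m+n, m) <= 2e5`).  Larger samples use the tie-corrected normal
#' approximation without continuity correction; the `method` field records
#' which path fired.
#'
#' @param x,y Non-empty numeric samples for the two groups.
#' @return A `comparison_result` list with fields `variable`, `test`,
#'   `statistic` (U for `x` over `y`), `p_value`, `method`, and per-group
#'   `summary` (mean, sd, n).
#' @export
compare_continuous <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  m <- length(x); n <- length(y)
  u <- u_statistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (m <= 20 && n <= 20 && !ties) {
    # pwilcox gives P(U <= u); two-sided p doubles the smaller tail
    lo <- pwilcox(u, m, n)
    hi <- 1 - pwilcox(u - 1, m, n)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else if (m <= 20 && n <= 20 && choose(m + n, m) <= MW_EXACT_MAX_COMB) {
    p <- mw_exact_permutation_p(x, y)
    method <- "exact-permutation"
  } else {
    z <- mw_z_tie_corrected(x, y, u)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation-tie-corrected"
  }
  comparison_result("", "mann-whitney", u, p, method = method,
                    summary = list(
                      group_a = c(mean = mean(x), sd = sd(x), n = m),
                      group_b = c(mean = mean(y), sd = sd(y), n = n)))
}

# U for x over y via midranks: U = R_x - m(m+1)/2.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-sided p by enumerating every assignment of the pooled values to
# the two groups; rejection region defined by |U - mn/2|.
mw_exact_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  obs <- abs(u_statistic(x, y) - m * length(y) / 2)
  idx <- utils::combn(length(pooled), m)
  stat <- apply(idx, 2, function(i) {
    abs(u_statistic(pooled[i], pooled[-i]) - m * length(y) / 2)
  })
  mean(stat >= obs - 1e-9)
}

mw_z_tie_corrected <- function(x, y, u) {
  m <- length(x); n <- length(y); N <- m + n
  t <- table(c(x, y))
  correction <- sum(t^3 - t) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - correction)
  (u - m * n / 2) / sqrt(sigma2)
}

#' Compare a categorical variable between groups
#'
#' @param counts A 2-by-k contingency matrix (groups in rows).  Pearson
#'   chi-square without continuity correction is used when every expected
#'   count is at least 5; otherwise Fisher's exact test for 2x2 tables.  A
#'   wider table with a small expected count is an error asking for category
#'   merging.
#' @return A `comparison_result` with `test` one of `"chi-square"`,
#'   `"fisher"`.
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must have exactly 2 rows (groups)")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("every margin must have at least one positive count")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(counts, correct = FALSE)
    res <- comparison_result("", "chi-square", unname(ht$statistic),
                             ht$p.value, method = "pearson-no-continuity",
                             summary = list(counts = counts))
  } else if (ncol(counts) == 2L) {
    ht <- stats::fisher.test(counts)
    res <- comparison_result("", "fisher", NA_real_, ht$p.value,
                             method = "fisher-exact",
                             summary = list(counts = counts))
  } else {
    stop("expected count < 5 in a 2x", ncol(counts),
         " table; merge sparse categories and retry")
  }
  res
}

comparison_result <- function(variable, test, statistic, p_value, method,
                              summary) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(variable = variable, test = test, statistic = statistic,
                 p_value = min(p_value, 1), method = method,
                 summary = summary),
            class = "comparison_result")
}

#' Group-comparison report for a cohort
#'
#' Runs the descriptive-table methodology over a cohort: Mann-Whitney for
#' age and each of the eight markers, chi-square/Fisher for gender, MPE vs
#' BPE, two-sided.
#'
#' @param cohort A cohort data frame ([generate_cohort()] /
#'   [read_cohort_csv()]).
#' @return Data frame with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, `mpe_summary`, `bpe_summary` (formatted
#'   `"mean (sd)"` for continuous variables, `"male/female"` counts for
#'   gender), `significant` at alpha 0.05, and `method`.
#' @export
table1_report <- function(cohort) {
  validate_cohort(cohort)
  if (length(unique(cohort$group)) < 2L) {
    stop("cohort must contain both MPE and BPE patients")
  }
  mpe <- cohort[cohort$group == "MPE", ]
  bpe <- cohort[cohort$group == "BPE", ]
  fmt <- function(v) sprintf("%.2f (%.2f)", mean(v), sd(v))

  rows <- list()
  cont_vars <- c("age", marker_ids("csv"))
  for (v in cont_vars) {
    r <- compare_continuous(mpe[[v]], bpe[[v]])
    rows[[v]] <- data.frame(variable = v, test = r$test,
                            statistic = r$statistic, p_value = r$p_value,
                            mpe_summary = fmt(mpe[[v]]),
                            bpe_summary = fmt(bpe[[v]]),
                            method = r$method)
  }
  tab <- rbind(table(factor(mpe$gender, c("male", "female"))),
               table(factor(bpe$gender, c("male", "female"))))
  rg <- compare_categorical(tab)
  rows$gender <- data.frame(variable = "gender", test = rg$test,
                            statistic = rg$statistic, p_value = rg$p_value,
                            mpe_summary = paste0(tab[1, 1], "/", tab[1, 2]),
                            bpe_summary = paste0(tab[2, 1], "/", tab[2, 2]),
                            method = rg$method)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$p_value < 0.05
  out
}

#' Render a group-comparison report as an aligned text table
#'
#' @param report Output of [table1_report()].
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
format_table1 <- function(report) {
  p <- ifelse(report$p_value < 0.001, "<0.001", sprintf("%.3f", report$p_value))
  m <- cbind(Variable = report$variable, MPE = report$mpe_summary,
             BPE = report$bpe_summary, `p-Value` = p)
  widths <- apply(rbind(colnames(m), m), 2, function(col) max(nchar(col)))
  line <- function(row) paste(mapply(formatC, row, width = widths,
                                     flag = "-"), collapse = "  ")
  c(line(colnames(m)), apply(m, 1, line))
}
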