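# Mann-Whitney / chi-square / Fisher comparison layer.

test_that("tied identical samples give U at its mean and exact p of 1", {
  r <- compare_continuous(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)  # midranks: 3 wins + 3 half-ties
  expect_equal(r$p_value, 1)
  expect_match(r$method, "exact")
})

test_that("complete separation gives the extreme U", {
  expect_equal(compare_continuous(c(1, 2), c(10, 20))$statistic, 0)
  expect_equal(compare_continuous(c(10, 20), c(1, 2))$statistic, 4)
})

test_that("exact p-values agree with full label-assignment enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    # half the draws from a small integer grid to force ties
    if (rep %% 2 == 0) {
      x <- sample(1:4, m, replace = TRUE); y <- sample(1:4, n, replace = TRUE)
    } else {
      x <- rnorm(m); y <- rnorm(n, 0.8)
    }
    expect_equal(compare_continuous(x, y)$p_value,
                 mw_enumeration_oracle(x, y), tolerance = 1e-12,
                 info = sprintf("rep %d", rep))
  }
})

test_that("large-sample path matches the tie-corrected normal approximation", {
  set.seed(5)
  x <- round(rnorm(50, 0, 2)); y <- round(rnorm(60, 0.5, 2))  # many ties
  r <- compare_continuous(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_match(r$method, "normal-approximation")
})

test_that("test size is honoured under the null", {
  set.seed(77)
  reject <- replicate(1000, {
    compare_continuous(rnorm(200), rnorm(200))$p_value < 0.05
  })
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rlnorm(15); y <- rlnorm(18, 0.5)
  base <- compare_continuous(x, y)$p_value
  for (f in list(log, sqrt, function(v) v^3, function(v) 5 * v + 2)) {
    expect_equal(compare_continuous(f(x), f(y))$p_value, base,
                 tolerance = 1e-12)
  }
})

test_that("categorical routing follows the expected-count rule", {
  # the study's gender margin: chi-square path, significant
  r <- compare_categorical(rbind(c(59, 52), c(148, 60)))
  expect_equal(r$test, "chi-square")
  expect_lt(r$p_value, 0.05)

  r0 <- compare_categorical(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  rf <- compare_categorical(rbind(c(1, 9), c(8, 2)))
  expect_equal(rf$test, "fisher")
  expect_equal(rf$p_value,
               fisher_hypergeom_oracle(rbind(c(1, 9), c(8, 2))),
               tolerance = 1e-7)

  expect_error(compare_categorical(rbind(c(1, 2, 30), c(2, 1, 40))), "merge")
  expect_error(compare_categorical(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("chi-square is invariant to row and column swaps", {
  tab <- rbind(c(30, 45), c(60, 25))
  base <- compare_categorical(tab)$statistic
  expect_equal(compare_categorical(tab[2:1, ])$statistic, base)
  expect_equal(compare_categorical(tab[, 2:1])$statistic, base)
})

test_that("Fisher and chi-square agree on large balanced tables", {
  tab <- rbind(c(520, 480), c(500, 510))
  p_chi <- stats::chisq.test(tab, correct = FALSE)$p.value
  p_fis <- stats::fisher.test(tab)$p.value
  expect_lt(abs(p_chi - p_fis), 0.02)
})

test_that("the cohort report covers all variables with exact toy statistics", {
  coh <- toy_cohort()
  rep <- table1_report(coh)
  expect_setequal(rep$variable, c("age", "gender", marker_ids("csv")))
  # exact U from brute force for every continuous variable
  mpe <- coh[coh$group == "MPE", ]; bpe <- coh[coh$group == "BPE", ]
  for (v in c("age", marker_ids("csv"))) {
    r <- rank(c(mpe[[v]], bpe[[v]]))
    u <- sum(r[1:4]) - 4 * 5 / 2
    expect_equal(rep$statistic[rep$variable == v], u)
    expect_equal(rep$p_value[rep$variable == v],
                 mw_enumeration_oracle(mpe[[v]], bpe[[v]]), tolerance = 1e-12)
  }
  expect_match(rep$mpe_summary[rep$variable == "age"],
               "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}\\)$")
  lines <- format_table1(rep)
  expect_length(lines, nrow(rep) + 1)
  expect_error(table1_report(coh[coh$group == "MPE", ]), "both")
})

test_that("the synthetic cohort separates the median-shifted markers", {
  # Moment-matched lognormal margins preserve each group's mean and sd but
  # not its median; for PB.CA125 the two groups' implied log-means nearly
  # coincide (4.77 vs 4.72), so a rank test has almost no power there even
  # though the means differ by ~100 U/mL.  The other seven markers separate
  # essentially always at n = 111/208.
  spec <- default_cohort_spec()
  shifted <- setdiff(marker_ids("csv"), "PB.CA125")
  hits <- sapply(1:100, function(s) {
    coh <- generate_cohort(spec, seed = 1000 + s)
    rep <- table1_report(coh)
    all(rep$significant[rep$variable %in% shifted])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("shuffled group labels give a null rejection rate near alpha", {
  spec <- default_cohort_spec()
  coh <- generate_cohort(spec, seed = 500)
  set.seed(9)
  pvals <- replicate(60, {
    shuffled <- coh
    shuffled$group <- sample(shuffled$group)
    rep <- table1_report(shuffled)
    rep$p_value[rep$variable %in% marker_ids("csv")]
  })
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.10)  # 480 null tests; alpha = 0.05
  expect_gt(mean(pvals), 0.35)  # roughly uniform, not clustered near 0
})
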