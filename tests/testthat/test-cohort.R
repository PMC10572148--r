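# Cohort synthesis: moment matching, copula structure, determinism.

test_that("lognormal moment matching has the stated closed forms", {
  p <- lognormal_params_from_moments(5, 0)
  expect_equal(unname(p), c(log(5), 0))
  p <- lognormal_params_from_moments(1, 1)
  expect_equal(unname(p["sigma"])^2, log(2))
  expect_equal(unname(p["mu"]), -log(2) / 2)
  expect_error(lognormal_params_from_moments(0, 1), "positive")
  expect_error(lognormal_params_from_moments(-3, 1), "positive")
})

test_that("moment-matched lognormal has exactly the target mean and sd", {
  # closed-form identity: E X = exp(mu + s^2/2), Var X = (e^{s^2}-1) e^{2mu+s^2}
  for (m in c(0.5, 16.80, 967.15)) {
    for (s in c(0.1, 105.81, 2307.31)) {
      p <- lognormal_params_from_moments(m, s)
      mu <- p["mu"]; s2 <- p["sigma"]^2
      expect_equal(unname(exp(mu + s2 / 2)), m, tolerance = 1e-12)
      expect_equal(unname(sqrt(expm1(s2) * exp(2 * mu + s2))), s,
                   tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo draws reproduce a heavy-tailed target within 3 SE", {
  # target: the benign-group pleural-fluid CEA cell, cv ~ 6.3
  m <- 16.80; s <- 105.81; n <- 1e6
  p <- lognormal_params_from_moments(m, s)
  set.seed(1234)
  x <- rlnorm(n, p["mu"], p["sigma"])
  expect_lt(abs(mean(x) - m), 3 * s / sqrt(n))
  # asymptotic SE of the sample sd from the theoretical fourth moment
  raw <- function(k) exp(k * p["mu"] + k^2 * p["sigma"]^2 / 2)
  mu4 <- raw(4) - 4 * raw(3) * m + 6 * raw(2) * m^2 - 3 * m^4
  se_sd <- sqrt((mu4 - s^4) / n) / (2 * s)
  expect_lt(abs(sd(x) - s), 3 * se_sd)
})

test_that("the built-in spec reproduces the study's descriptive table", {
  spec <- default_cohort_spec()
  expect_equal(spec$mpe$n, 111L)
  expect_equal(spec$bpe$n, 208L)
  expect_equal(c(spec$mpe$male, spec$mpe$female), c(59L, 52L))
  expect_equal(c(spec$bpe$male, spec$bpe$female), c(148L, 60L))
  expect_equal(c(spec$mpe$age_mean, spec$mpe$age_sd), c(60.94, 11.96))
  expect_equal(c(spec$bpe$age_mean, spec$bpe$age_sd), c(49.78, 19.02))
  mm <- spec$mpe$marker_moments
  expect_equal(unlist(mm[mm$marker == "PB.CA15-3", c("mean", "sd")],
                      use.names = FALSE), c(38.79, 47.97))
  bm <- spec$bpe$marker_moments
  expect_equal(unlist(bm[bm$marker == "PE.CEA", c("mean", "sd")],
                      use.names = FALSE), c(16.80, 105.81))
  # spec self-consistency: PSD correlation, counts add up
  ev <- eigen(spec$marker_correlation, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(spec$mpe$male + spec$mpe$female, spec$mpe$n)
})

test_that("generation is deterministic and respects counts and support", {
  spec <- default_cohort_spec()
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(a, generate_cohort(spec, seed = 8)))

  expect_equal(nrow(a), 319)
  expect_equal(as.vector(table(a$group)[c("MPE", "BPE")]), c(111, 208))
  tab <- table(a$group, a$gender)
  expect_equal(tab["MPE", "male"], 59)
  expect_equal(tab["BPE", "female"], 60)
  expect_true(all(as.matrix(a[marker_ids("csv")]) > 0))
  expect_true(all(a$age >= 18 & a$age <= 100))
})

test_that("identity latent correlation yields near-zero Spearman correlations", {
  spec <- scale_cohort_spec(
    cohort_spec(default_cohort_spec()$mpe, default_cohort_spec()$bpe,
                marker_correlation = diag(8)),
    5000, 5000)
  coh <- generate_cohort(spec, seed = 11)
  for (grp in c("MPE", "BPE")) {
    x <- as.matrix(coh[coh$group == grp, marker_ids("csv")])
    rho <- cor(x, method = "spearman")
    expect_lt(max(abs(rho[upper.tri(rho)])), 0.05)
  }
})

test_that("non-PSD correlation and malformed specs are rejected", {
  bad <- default_marker_correlation()
  bad[1, 2] <- bad[2, 1] <- 2  # breaks positive semi-definiteness
  expect_error(cohort_spec(default_cohort_spec()$mpe,
                           default_cohort_spec()$bpe,
                           marker_correlation = bad),
               "positive semi-definite")
  expect_error(group_spec("MPE", 10, 60, 10, male = 4, female = 5,
                          default_cohort_spec()$mpe$marker_moments),
               "male \\+ female")
})

test_that("separation sanity: pleural-fluid CEA alone discriminates strongly", {
  spec <- scale_cohort_spec(default_cohort_spec(), 5000, 5000)
  coh <- generate_cohort(spec, seed = 3)
  auc <- compute_auc(coh$PE.CEA, as.integer(coh$group == "MPE"))
  expect_gt(auc, 0.75)
})

test_that("cohort CSV round-trips and rejects schema violations", {
  coh <- generate_cohort(default_cohort_spec(), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  again <- read_cohort_csv(f)
  expect_equal(again$PE.CEA, coh$PE.CEA, tolerance = 1e-12)
  expect_identical(names(again), names(coh))

  broken <- coh
  broken$PE.CEA[1] <- -1
  expect_error(write_cohort_csv(broken, f), "positive")
})
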