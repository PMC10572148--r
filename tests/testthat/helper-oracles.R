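# Independent oracles and small fixtures shared across tests.  Everything
# here is deliberately brute-force and must stay independent of the package
# implementations it checks.

# O(n^2) pair-counting AUC: concordant pairs + half ties over all
# (positive, negative) pairs.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group sizes (m, n); rejection region |U - mn/2|.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  u_of <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - m * (m + 1) / 2
  }
  obs <- abs(u_of(x, y) - m * n / 2)
  idx <- utils::combn(m + n, m)
  stats <- apply(idx, 2, function(i) abs(u_of(pooled[i], pooled[-i]) - m * n / 2))
  mean(stats >= obs - 1e-9)
}

# Two-sided Fisher p for a 2x2 table as the sum of hypergeometric point
# probabilities no larger than the observed one.
fisher_hypergeom_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

# Tiny deterministic ten-patient cohort used for exact-statistic checks.
toy_cohort <- function() {
  markers <- marker_ids("csv")
  set.seed(42)
  conc <- matrix(round(rlnorm(10 * 8, meanlog = 2, sdlog = 1), 2), 10, 8,
                 dimnames = list(NULL, markers))
  conc[1:4, "PE.CEA"] <- c(120.5, 80.2, 200.1, 55.3)  # MPE block higher
  data.frame(patient_id = sprintf("P%04d", 1:10),
             group = rep(c("MPE", "BPE"), c(4, 6)),
             age = c(61, 70, 58, 66, 45, 50, 39, 62, 48, 55),
             gender = rep(c("male", "female"), 5),
             as.data.frame(conc), check.names = FALSE)
}

# Larger linearly-separable-ish fixture for model tests: one informative
# feature plus noise, both classes guaranteed present.
toy_model_cohort <- function(n = 60, shift = 3, seed = 99) {
  spec <- scale_cohort_spec(default_cohort_spec(), ceiling(n / 2),
                            floor(n / 2))
  generate_cohort(spec, seed = seed)
}
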