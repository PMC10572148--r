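# C-score framework: regularization, sweep, quadrants, recommendations.

test_that("min-max regularization hits 0 and 1 and preserves order", {
  lad <- load_table2()
  reg <- regularize_costs(lad$cost)
  expect_equal(reg[which.min(lad$cost)], 0)
  expect_equal(reg[which.max(lad$cost)], 1)
  expect_true(all(diff(reg) > 0))
  expect_equal(reg[lad$rung == "C9"], (281 - 56.5) / (617 - 56.5),
               tolerance = 1e-12)
  expect_error(regularize_costs(c(5, 5, 5)), "degenerate")
})

test_that("the comprehensive score follows its defining formula and limits", {
  expect_equal(c_score(0.937, 1.0, 0.99), 0.92763, tolerance = 1e-12)
  expect_equal(round_half_away(c_score(0.937, 1.0, 0.99), 3), 0.928)
  expect_equal(c_score(0.8, 0.3, 1), 0.8)     # w = 1: accuracy only
  expect_equal(c_score(0.8, 0, 0), 1)         # w = 0, cheapest panel
  expect_error(c_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(c_score(0.9, 0.5, -0.1), "\\[0, 1\\]")
})

test_that("reported rounding is half away from zero", {
  expect_equal(round_half_away(0.9345, 3), 0.935)
  expect_equal(round_half_away(0.9025, 3), 0.903)
  expect_equal(round_half_away(-0.0005, 3), -0.001)
  expect_equal(round(0.9345, 3), 0.934)  # base round differs here (half-even)
})

test_that("the published weight-sweep extremes are reproduced exactly", {
  lad <- load_table2()
  sweep <- sweep_w(lad)
  ex <- sweep_extremes(sweep)
  for (w in c(0, 0.2, 0.4, 0.6, 0.8)) {
    expect_equal(ex$argmax[ex$w == w], "C1")
    expect_equal(ex$argmin[ex$w == w], "C20")
  }
  expect_equal(ex$argmax[ex$w == 0.90], "C4")
  expect_equal(ex$argmin[ex$w == 0.90], "C17")
  expect_equal(ex$argmax[ex$w == 0.95], "C7")
  expect_equal(ex$argmin[ex$w == 0.95], "C17")
  expect_equal(ex$argmax[ex$w == 0.99], "C9")
  expect_equal(ex$argmin[ex$w == 0.99], "C2")

  s99 <- sweep[sweep$w == 0.99, ]
  expect_equal(round_half_away(s99$c_score[s99$rung == "C20"], 3), 0.928)
  expect_equal(round_half_away(s99$c_score[s99$rung == "C1"], 3), 0.903)
  # invariant: the identity holds to numerical precision at every (w, rung)
  expect_lt(max(abs(sweep$c_score -
                    (sweep$w * sweep$auc +
                     (1 - sweep$w) * (1 - sweep$regularized_cost)))), 1e-12)
})

test_that("sweep extremes match a brute-force scan at every weight", {
  lad <- load_table2()
  grid <- c(default_w_grid(), 0.87, 1 / 3)
  sweep <- sweep_w(lad, grid)
  reg <- regularize_costs(lad$cost)
  for (w in grid) {
    s <- w * lad$auc + (1 - w) * (1 - reg)
    block <- sweep[sweep$w == w, ]
    best <- which(s == max(s)); best <- best[which.min(lad$cost[best])]
    worst <- which(s == min(s)); worst <- worst[which.min(lad$cost[worst])]
    expect_equal(block$rung[block$is_argmax], lad$rung[best])
    expect_equal(block$rung[block$is_argmin], lad$rung[worst])
  }
})

test_that("c_score is affine in w and decreasing in cost at fixed AUC", {
  lad <- load_table2()
  reg <- regularize_costs(lad$cost)
  # affine: value at midpoint weight equals midpoint of endpoint values
  s0 <- c_score(lad$auc, reg, 0.2); s1 <- c_score(lad$auc, reg, 0.8)
  expect_equal(c_score(lad$auc, reg, 0.5), (s0 + s1) / 2, tolerance = 1e-12)
  expect_true(all(c_score(0.9, sort(reg), 0.7) ==
                  cummin(c_score(0.9, sort(reg), 0.7))))
})

test_that("the cheapest rung never regains the argmax once lost", {
  lad <- load_table2()
  sweep <- sweep_w(lad, seq(0, 1, by = 0.001))
  ex <- sweep_extremes(sweep)
  cheap_is_best <- ex$argmax == "C1"
  lost_at <- which(!cheap_is_best)[1]
  expect_true(all(!cheap_is_best[lost_at:length(cheap_is_best)]))
  # and the argmax cost path is weakly non-decreasing in w overall
  cost_of <- lad$cost[match(ex$argmax, lad$rung)]
  expect_gte(min(diff(cost_of)), 0)
  expect_equal(unique(ex$argmax), c("C1", "C4", "C7", "C9"))
})

test_that("median-split quadrants match the published segmentation", {
  lad <- load_table2()
  q <- quadrant_segmentation(lad)
  expect_equal(attr(q, "median_cost"), 322.25)
  expect_equal(attr(q, "median_auc"), 0.9345, tolerance = 1e-12)
  expect_equal(round_half_away(attr(q, "median_auc"), 3), 0.935)
  for (r in c("C7", "C9", "C10")) {
    expect_equal(q$quadrant[q$rung == r], "high-AUC/low-cost")
  }
  expect_equal(q$quadrant[q$rung == "C2"], "low-AUC/low-cost")
  expect_equal(q$quadrant[q$rung == "C17"], "low-AUC/high-cost")
})

test_that("two-rung ladders split one-below-one-above, ties landing low", {
  lad <- load_table2()[c(1, 20), ]
  q <- quadrant_segmentation(lad)
  # the interpolated median lies strictly between two distinct values,
  # so exactly one rung is below each median
  expect_equal(sum(q$cost > attr(q, "median_cost")), 1)
  expect_equal(sum(q$auc > attr(q, "median_auc")), 1)
  # with equal AUCs both rungs sit on the AUC median: the tie rule sends
  # both to the low-AUC side and reports them
  tied <- data.frame(rung = c("A", "B"), panel = c("PE.CEA", "PB.CEA"),
                     cost = c(10, 20), auc = c(0.9, 0.9))
  qt <- quadrant_segmentation(tied)
  expect_true(all(startsWith(qt$quadrant, "low-AUC")))
  expect_setequal(attr(qt, "median_ties"), c("A", "B"))
})

test_that("anchor-marker flags recover the published outlier rungs", {
  lad <- load_table2()
  expect_setequal(flag_missing_anchor(lad, "PE.CEA"),
                  c("C2", "C5", "C8", "C11", "C14", "C17"))
  # an anchor present everywhere flags nothing
  expect_length(flag_missing_anchor(lad[lad$rung %in% c("C1", "C3", "C4"), ],
                                    "PE.CEA"), 0)
  expect_equal(flag_missing_anchor(lad[lad$rung == "C2", ], "PE.CEA"), "C2")
})

test_that("persona recommendations map to the published choices", {
  sweep <- sweep_w(load_table2())
  recs <- recommend(sweep)
  expect_equal(recs$rung[recs$persona == "budget"], "C1")
  expect_equal(recs$panel[recs$persona == "budget"], "PE.CEA")
  expect_equal(recs$rung[recs$persona == "balanced"], "C7")
  expect_equal(recs$rung[recs$persona == "accuracy_first"], "C9")
  expect_error(recommend(sweep, c(oddball = 0.123)), "not in the computed grid")
})

test_that("a sweep round-trips through CSV at full precision", {
  sweep <- sweep_w(load_table2())
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sweep, f)
  again <- read_sweep_csv(f)
  expect_lt(max(abs(again$c_score - sweep$c_score)), 1e-12)
  expect_lt(max(abs(again$regularized_cost - sweep$regularized_cost)), 1e-12)
  expect_identical(again$rung, sweep$rung)
  expect_identical(again$is_argmax, sweep$is_argmax)
})
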