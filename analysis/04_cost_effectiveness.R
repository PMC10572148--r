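#!/usr/bin/env Rscript
# Stage 4 — cost-effectiveness analysis.
#
# Two runs of the C-score framework:
#   (a) replay mode on the shipped published twenty-rung ladder, which
#       reproduces the published arithmetic exactly (argmax/argmin rungs,
#       medians, anchor-marker outliers, persona recommendations) without
#       touching any random state; outputs under results/replay/.
#   (b) the synthetic end-to-end run on the records from stage 03, if
#       present; outputs under results/synthetic/.

library(mpecost)

report <- function(out, label) {
  cat(sprintf("\n== %s ==\n", label))
  ex <- out$extremes
  for (w in c(0.5, 0.9, 0.95, 0.99)) {
    row <- ex[abs(ex$w - w) < 1e-9, ]
    cat(sprintf("w = %-4g best %-4s worst %-4s\n", w, row$argmax, row$argmin))
  }
  cat(sprintf("median cost %g RMB, median AUC %.3f\n",
              attr(out$quadrants, "median_cost"),
              round_half_away(attr(out$quadrants, "median_auc"), 3)))
  cat("panels missing the anchor marker PE.CEA:",
      paste(out$flags, collapse = ", "), "\n")
  print(out$recommendations[c("persona", "w", "rung", "panel", "cost", "auc")])
}

replay_cfg <- pipeline_config(seed = 1, out_dir = file.path("results", "replay"))
report(run_ce(replay_cfg, replay = TRUE), "replay of the published ladder")

records_csv <- file.path("results", "records.csv")
if (file.exists(records_csv)) {
  syn_cfg <- pipeline_config(seed = 1, out_dir = file.path("results", "synthetic"))
  report(run_ce(syn_cfg, records = records_csv),
         "synthetic cohort, stacking model")
} else {
  cat("\n(results/records.csv not found - run analysis/03 first for the",
      "synthetic ladder)\n")
}
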