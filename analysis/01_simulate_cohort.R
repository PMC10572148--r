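#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the synthetic pleural-effusion cohort (111 MPE / 208 BPE, ages,
# gender and eight moment-matched tumor-marker concentrations) and writes
# results/cohort.csv plus a provenance manifest.  Everything downstream
# (stages 02-04) reads this file.

library(mpecost)

cfg <- pipeline_config(seed = 1, out_dir = "results")
cohort <- run_simulate(cfg)

cat(sprintf("Wrote %s: %d patients (%d MPE / %d BPE)\n",
            file.path(cfg$out_dir, "cohort.csv"), nrow(cohort),
            sum(cohort$group == "MPE"), sum(cohort$group == "BPE")))
cat("Marker concentration ranges (ng/mL or U/mL):\n")
print(vapply(cohort[marker_ids("csv")], range, numeric(2)))
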