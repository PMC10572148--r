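---
title: "Methods: stacked-ensemble diagnosis of malignant pleural effusion and the C-score cost-effectiveness framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacking and the C-score framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpecost)
```

## The problem

Distinguishing malignant from benign pleural effusion (MPE vs BPE) from
tumor-marker concentrations is a standard diagnostic task: four analytes —
CEA (ng/mL) and the carbohydrate antigens CA19-9, CA125 and CA15-3 (U/mL) —
are each assayed in pleural effusion fluid (PE) and peripheral blood (PB),
giving eight markers and therefore $2^8 - 1 = 255$ candidate marker panels.
Every additional assay costs money, so the clinically interesting question
is not only *which panel discriminates best* but *which panel is worth its
price*. This package implements that whole analysis: a synthetic cohort
generator (the original patient-level data are not deposited), the stacked
diagnostic model, exhaustive panel evaluation with an additive cost model,
and a weighted composite score that makes the accuracy/cost trade-off
explicit.

## Synthetic cohort generator

`default_cohort_spec()` encodes the published cohort composition: 111 MPE
and 208 BPE patients; ages $60.94 \pm 11.96$ vs $49.78 \pm 19.02$ years;
gender margins 59/52 and 148/60 (male/female); and a per-group mean and
standard deviation for each of the eight markers. `generate_cohort()` draws
from it as follows.

**Marker margins.** Concentrations are strictly positive and the published
standard deviations exceed the means several-fold in most cells (e.g.
benign-group pleural CEA: mean 16.80, sd 105.81), which rules out normal
margins. We use lognormal margins moment-matched in closed form:
$\sigma^2 = \ln(1 + s^2/m^2)$, $\mu = \ln m - \sigma^2/2$, so the simulated
mean and sd equal the targets exactly in expectation.

**Dependence.** The markers are coupled through a Gaussian copula. No
correlation structure is published, so the default latent correlation is a
configurable plausibility choice — 0.4 between the same analyte in the two
fluids, 0.2 between different analytes within one fluid, 0.1 otherwise —
values typical of reported tumor-marker co-elevation in effusion studies.
No exact result in the package depends on this matrix, and the tests verify
that an identity matrix yields pairwise Spearman correlations within
$\pm 0.05$ of zero at $n = 10^4$.

**Demographics.** Ages are normal, truncated to $[18, 100]$ by resampling
(the benign group's sd of 19.02 would otherwise produce impossible ages).
Gender is assigned as exact counts — a random permutation of the specified
male/female totals — so the simulated margins reproduce the published ones
exactly rather than in expectation. Recruitment region is deliberately
omitted: it was not significant in the original analysis and was excluded
from model construction there too.

**Determinism.** One master seed determines every byte of output.
Stage- and fold-level seeds are derived from it with `derive_seed()`, so
panel evaluation order, resumption after interruption, and parallel
restructuring cannot change results.

### What the generator does and does not emulate

It reproduces group sizes, gender margins, age moments, marker means/sds,
positivity and heavy right skew. It does **not** reproduce the unknown true
marker distributions, assay detection limits or censoring, site effects, or
the real correlation structure. Two consequences matter when reading test
results:

* Matching two moments fixes a lognormal completely, including its median.
  For PB.CA125 the implied log-means of the two groups nearly coincide
  (4.77 vs 4.72) although the arithmetic means differ by ~100 U/mL, so a
  rank test has essentially no power for that marker in simulation — the
  package's descriptive report flags seven of the eight markers, not eight,
  as the published table does on real data. This is a property of the
  available summary statistics, not of the test implementation.
* The synthetic groups are somewhat *more* separable overall than the real
  ones (cross-validated AUCs near 0.99 for the full panel vs a published
  0.937), because eight near-independent heavy-tailed markers with large
  mean ratios carry more joint information than eight strongly correlated
  real assays. Synthetic-benchmark tests therefore check distribution-level
  properties (stacking keeps pace with its best base learner; permuted
  labels collapse to chance; the single best marker stays discriminative)
  rather than the published AUC values, which cannot be reproduced without
  the original cohort.

## Group comparison

`table1_report()` mirrors the descriptive methodology: two-sided
Mann-Whitney U for continuous variables, Pearson chi-square without
continuity correction for categorical ones, switching to Fisher's exact
test when any expected count drops below 5 (the Cochran criterion; the
original report names both tests without stating its rule). The U statistic
uses midranks; p-values are exact for groups of at most 20 each — via the
null U distribution when tie-free, by complete enumeration of label
assignments when tied (up to $\binom{m+n}{m} \le 2\times 10^5$) — and use
the tie-corrected normal approximation without continuity correction
otherwise. Each result records which path fired, since the original
report's choice is unstated. No multiplicity adjustment is applied,
matching the source methodology.

## Diagnostic models

`feature_matrix()` builds per-patient features: $\log(1+x)$-transformed
concentrations for the panel's markers, age, and a male indicator, with
MPE = 1 as the positive class. Z-scaling statistics are fit inside each
training fold — never on pooled data — which stabilizes the SVM and
logistic fits; tree models are indifferent.

Five base learners (logistic regression, random forest, naive Bayes, an
RBF SVM with Platt-calibrated probabilities, and gradient-boosted trees)
feed a **stacked ensemble**: `fit_stacking()` collects each base learner's
*out-of-fold* predicted probabilities from a stratified inner 3-fold split
of the training data, fits a logistic meta-learner on those five columns,
and refits the base learners on the full training data for prediction.
Out-of-fold construction is what prevents the meta-learner from rewarding
base learners that memorize: no meta-feature is ever produced by a model
that saw the patient.

`cross_validated_evaluate()` wraps any of the six models in stratified
3-fold cross-validation (the published protocol), pools the out-of-fold
scores over all patients, and computes one AUC and one
sensitivity/specificity pair on the pooled vector. Pooling, rather than
per-fold averaging, is the most common reading of "the AUC of the
validation cohort" and is recorded as such. The AUC is the Mann-Whitney
probability estimate (ties counted half), verified in the tests against an
$O(n^2)$ pair-counting oracle and against pROC.

Design choices the source leaves open, fixed here and recorded in every
record: the sensitivity/specificity threshold is 0.5 on predicted
probability (a Youden-optimal option exists but is off by default);
hyperparameters are modest fixed settings (300 trees, 60 boosting rounds of
depth 3, RBF cost 1) chosen so a full 255-panel sweep runs in minutes on
one CPU — the inner-CV grid-tuning machinery (`tune_learner()`) is
implemented and tested, and any learner's entry in `default_params()` can
be replaced by a list of candidates to enable it.

## Panel pricing and the best-per-cost ladder

The cost model is additive: a panel costs the sum of its members' unit
prices. Published pricing has two degrees of freedom — one CEA price and
one shared CA price, identical across the two fluids — and the defaults
(CEA 56.5 RMB, CA 84.0 RMB) are back-solved from the two cheapest published
panel costs; they reproduce all twenty published combination costs exactly,
and the map $(a, b) \mapsto 56.5a + 84b$ over the valid (CEA count, CA
count) pairs is verified injective, which is why 255 panels collapse to
exactly 20 distinct costs. `build_ladder()` keeps, per distinct cost, the
panel with the best AUC (ties: fewer markers, then lexicographic order) and
labels the rungs C1–C20 by increasing cost. The shipped
`inst/extdata/table2.csv` transcribes the published ladder for replay mode,
which exercises the entire cost-effectiveness stage with no random state
and no model code.

## The C-score

With costs min–max–regularized to $[0,1]$ over the ladder being scored,

$$\mathrm{C\text{-}score} = w \cdot \mathrm{AUC} + (1 - w)\,(1 - \mathrm{regularized(cost)})$$

trades accuracy against cost through the weight $w \in [0,1]$. Under the
default prices the regularization population is immaterial: the ladder and
the full 255-panel set share the same extremes (56.5 and 617 RMB).
`sweep_w()` scores every rung over a weight grid (default
$\{0, 0.1, \dots, 0.9, 0.95, 0.99, 1\}$, stored as exact literals so grid
lookups are never bitten by floating-point accumulation); argmax/argmin
ties break toward the cheaper rung and are logged — relevant because two
rungs differ by under $5\times10^{-4}$ near $w = 0.95$ on the replay
ladder. Reported scores are rounded half-away-from-zero to 3 decimals
(matching the published 0.928/0.903 convention); full precision is kept
internally and round-trips through the CSV writers to $10^{-12}$.

On the replay ladder the sweep reproduces the published structure exactly:
the cheapest rung C1 (PE.CEA alone) is optimal for every $w \le 0.8$, C4
takes over at $w = 0.90$, C7 at $0.95$, and the highest-AUC rung C9 at
$0.99$, while the worst rung moves from C20 (most expensive) to C17 and C2
(the expensive and cheap rungs lacking PE.CEA). `quadrant_segmentation()`
splits rungs at the median cost (322.25 RMB) and median AUC (0.9345,
printed 0.935); C7/C9/C10 land in the high-AUC/low-cost quadrant, and
`flag_missing_anchor()` identifies C2, C5, C8, C11, C14, C17 — exactly the
rungs whose panels omit PE.CEA — as the low-AUC outliers.
`recommend()` maps personas to rungs: budget ($w=0.5$) → C1, balanced
($w=0.95$) → C7, accuracy-first ($w=0.99$) → C9.

## Numerical and testing notes

* Problem sizes used by the test suite: moment recovery at $2\times10^4$
  patients per group; copula checks at $10^4$; model properties on the
  319-patient cohort over 20 independent replicates; oracle equivalence of
  the AUC on 1000 random instances up to $n = 200$; exact Mann-Whitney
  against full enumeration up to 8 per group. These sizes make the checks
  sharp while keeping a full run at desk scale.
* The permuted-label null uses one permutation per cohort replicate;
  pooled-CV AUC under the null is known to sit slightly below 0.5 (each
  fold's model anti-learns its training noise), which the chance band
  accommodates.
* Degenerate inputs fail loudly: empty panels, single-class folds,
  non-positive means, non-PSD correlation matrices, all-equal costs for
  min–max scaling, and persona weights outside the computed grid are all
  errors, not silent fixes.

## Limitations

The generator cannot stand in for the unavailable clinical cohort: absolute
synthetic AUCs are optimistic, PB.CA125's rank-test behaviour differs from
the real data for the reasons above, and the latent correlation is a
configurable assumption. The cost model covers assay list prices only — no
insurance tiers, patient experience, downstream treatment costs or
QALY-style modelling. Conclusions about *which published rung is optimal at
which $w$* come from the replay ladder and are exact; conclusions about
*model behaviour on real patients* require the original or a comparable
cohort in `read_cohort_csv()` format.
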