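---
title: "Evaluating multi-modal AI screening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-modal AI screening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Women with dense breasts are poorly served by mammography alone: dense
fibroglandular tissue masks soft-tissue lesions. Supplemental automated 3D
breast ultrasound (ABUS) recovers some of that sensitivity, and AI detection
systems now produce a continuous per-exam suspicion score for each modality.
The question this package operationalizes is whether combining the two AI
scores at the case level improves standalone detection performance, and how
the combined system compares with radiologists reading one modality each.

Three analysis arms are compared throughout: the mammography score (`dm`),
the ultrasound score (`abus`), and their weighted fusion (`fused`). Ground
truth is three-valued — malignant, biopsy-proven benign, normal — and only
malignant cases count as positive; benign and normal are pooled as negative.
Everything is case-level: no lesion locations, no image data.

## The fusion model

Both scores are first min–max normalized to [0, 1] over the analyzed cohort,
then averaged with complementary weights:

$$ s_\text{fused} = w \, \tilde s_\text{dm} + (1-w)\, \tilde s_\text{abus},
\qquad w \in \{0.01, 0.02, \dots, 0.99\}. $$

`weight_sweep()` evaluates the empirical AUC of the fused score at every
grid weight and selects the argmax. Three choices here were genuinely open:

* **Normalization scale.** The min and max are taken over the full analyzed
  cohort. Commercial scores often live on a nominal 1–100 scale; if fixed
  bounds are preferred, `minmax_normalize(range = c(1, 100))` and the
  `range_dm`/`range_abus` arguments of `weight_sweep()` support them. The
  cohort-wide default is the package's primary convention. Since min–max
  maps are strictly increasing, the choice never affects AUCs — only the
  numeric scale of the fused score and hence reported thresholds.
* **Grid step.** 0.01 across the stated 0.01–0.99 range. A finer step
  cannot change the selected AUC by more than the granularity of the
  empirical AUC itself at these sample sizes.
* **Ties in the argmax.** Exact AUC ties across weights are broken toward
  the weight closest to 0.5, then toward the smaller weight — a symmetric,
  documented default (two identical modalities select exactly 0.5).

The selection is **in-sample**: the same cohort supplies the normalization
scale, the AUC profile, and the argmax. That mirrors how such an analysis is
run on a single study cohort, and it means the optimal fused AUC can never
fall below either single-modality AUC on that cohort (an exact property of
the argmax, asserted in the tests). As an honest complement, the test suite
also refits the weight on an independent training replicate and evaluates on
a fresh cohort; with the default calibration the held-out fused arm beats
both singles in at least 90% of 200 simulations at n = 430.

## ROC machinery

* **AUC** is the Mann–Whitney statistic with ties counted half, computed by
  midranks in O(n log n). It equals the trapezoidal area under the
  empirical ROC to 1e-10 (tested), and is invariant under strictly
  increasing transforms.
* **Empirical ROC** places one operating point per distinct score value
  (call positive at score ≥ threshold) plus the two trivial endpoints.
* **DeLong variance and paired test.** The structural-components estimator:
  placement values for each positive (fraction of negatives below it) and
  each negative; `var = S10/m + S01/n`, covariance from the paired
  components, and `z = (AUC_a − AUC_b)/sqrt(var_a + var_b − 2 cov)` with a
  two-sided normal p-value. Midranks handle ties throughout. When the
  variance of the difference is zero and the AUCs agree (one score a rank
  transform of the other), z is defined as 0 and p as 1. The implementation
  is cross-checked in the tests against pROC on the same data and validated
  against a Monte-Carlo variance (5000 cohorts of n = 60, agreement within
  15%) and a simulated equal-AUC null (type-I error within 3 binomial
  standard errors of 0.05 at 2000 replicates).
* **Youden operating points.** `max_youden()` maximizes
  J = sensitivity + specificity − 1; exact ties prefer the
  higher-specificity point, then the lower threshold — in screening, the
  more conservative recall boundary. A degenerate endpoints-only curve
  returns a flagged J = 0 point with a warning.
* **Bootstrap.** Percentile intervals from case-level resampling with
  replacement, stratified by truth class (default 2000 replicates, level
  0.95). Stratification keeps every replicate's class composition fixed,
  which both matches the fixed-composition design and makes the interval
  estimable even with few positives. Percentile intervals can in principle
  fail to bracket the point estimate in extreme skew; bounds are reported
  as computed. Metric failures on a replicate (possible only without
  stratification) trigger a redraw, and redraws are counted in the result.

## Simulated readers and combination rules

Readers assign ordinal BI-RADS categories 1 < 2 < 3 < 4a < 4b < 4c < 5. A
case is *recalled* when its category reaches a threshold; the default
threshold is category 3, consistent with the low specificities typical of
enriched observer studies (a "probably benign" call already triggers workup
when readers know cancers are over-represented). Every reported strategy
names its threshold.

* **Either-recall double reading**: the pair recalls if either reader does
  (element-wise OR). Commutative and idempotent; relative to each single
  reader it can only add recalls, so sensitivity never decreases and
  specificity never increases (asserted exactly).
* **Four-reader majority panel**: the consensus BI-RADS category is the one
  held by a strict majority (3 of 4); a 2–2 split between two categories
  resolves to the more suspicious of the two modes
  (screening-conservative); a lone 2-vote mode wins over two singletons;
  with four distinct categories the more suspicious member of the median
  pair is assigned. The consensus is always one of the four inputs and is
  invariant to reader order — verified exhaustively over all 7⁴ = 2401 vote
  patterns. "Majority voting" on ordinal categories is under-determined;
  these tie rules are the package's documented resolution. Whether to vote
  on categories and then threshold (the default) or to threshold each
  reader and then take a majority of recalls is also ambiguous;
  `evaluate_strategy(vote_on = "recall")` exposes the alternative without
  claiming either order matches any particular prior study.

Sensitivity is the recalled fraction of malignant cases and specificity the
non-recalled fraction of benign + normal pooled, both exact fractions with
class-size denominators; CIs use the same stratified bootstrap.

## The synthetic cohort generator

The generator exists so the full pipeline is testable without clinical
data; its defaults define the package's reference study conditions.

* **Composition**: 42 malignant / 114 benign / 274 normal (430 cases), with
  an enriched observer subcohort of all malignant plus a seeded sample of
  30 benign and 80 normal (152 cases) — roughly two normals per cancer and
  a benign sample near 20% of the full cohort.
* **Scores**: class-conditional bivariate Gaussians per modality — the
  standard binormal ROC model, chosen because it admits the closed-form
  mixture AUC `analytic_auc()` used as an oracle. Defaults (sd 1
  throughout): malignant means 1.49 (dm) and 1.54 (abus), benign 0.4 on
  both, normal 0, within-class correlation ρ = 0.35. The malignant means
  were solved once, analytically, so the mixture AUCs under the default
  composition are 0.832 (dm) and 0.841 (abus) — the single-modality
  performance regime these analyses target; ρ = 0.35 is a realistic
  moderate agreement between modalities that leaves them complementary.
  Benign sits above normal because biopsied benign lesions draw suspicion
  that normals do not.
* **Readers**: class-conditional category distributions. The default four
  readers are calibrated so their exact recall masses at threshold 3
  reproduce sensitivities 77.8/79.2/94.2/85.4% and specificities
  45.4/57.1/22.1/37.9% (two mammography readers, two ultrasound readers —
  the ultrasound readers trading specificity for sensitivity). The shape of
  the distribution within the recalled and non-recalled blocks is a fixed
  convention (suspicion-escalating for malignant, decaying for others);
  only the block totals are calibrated. Benign and normal share a
  distribution by default, so pooled specificity equals the per-class
  target exactly.
* **Randomness**: one RNG stream per (table, seed); each reader column uses
  its own sub-stream keyed by the reader's position, so appending a reader
  never changes earlier columns. In `run_study()` every random component
  derives from the single config seed by fixed offsets (cohort: seed;
  readers: seed+1; bootstrap: seed+2 onward; subcohort sampling: seed+3),
  making full runs byte-identical and each component independently
  reproducible.

What the generator does **not** emulate: the empirical shape of real AI
score distributions (unknown; Gaussian is a stand-in, not inferred truth),
lesion-level or location information, reader correlation across cases or
between readers (draws are conditionally independent given truth), density
strata, and any reader–AI interaction. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under the binormal
model — not that any particular clinical performance figure transfers to
real cohorts.

## Numerical choices and degenerate inputs

* Ties: midranks everywhere (AUC, DeLong, ROC points collapse ties).
* Constant score vectors make min–max normalization undefined: an error
  naming the modality.
* Single-class inputs (no malignant, or no negatives) are refused by every
  ROC operation with an error naming the missing class, and `run_study()`
  refuses such cohorts before computing anything.
* DeLong components require at least two cases per class.
* All thresholds are score-valued; ±Inf endpoints close every ROC curve.

## Problem sizes

The test suite validates at sizes chosen to make Monte-Carlo bounds sharp
while keeping the default run quick: moment convergence at 10,000 cases per
class, AUC-vs-closed-form recovery at 500–1500 per class with 3
standard-error bands, DeLong variance against 5000 simulated cohorts of
n = 60, the equal-AUC null at 2000 replicates of n = 200, bootstrap
coverage over 120 cohorts of n = 200 with 400 replicates each, held-out
fusion dominance over 200 cohort pairs at n = 430, and exhaustive
enumeration (2401 patterns) for the panel rule.

## Limitations

The evaluation is strictly standalone and case-level; it says nothing about
reader–AI interaction, localization accuracy, or workload. The in-sample
weight selection reports an optimistically biased fused AUC by
construction — the held-out property test quantifies the direction of that
concern under the default calibration, but a real deployment would fix the
weight on independent data. Bootstrap intervals are percentile-method only;
no BCa correction is applied.
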