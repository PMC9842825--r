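# mmroc

Evaluation tools for **multi-modal AI in breast cancer screening**: late
(score-level) fusion of continuous suspicion scores from digital mammography
(DM) and automated 3D breast ultrasound (ABUS), compared arm-against-arm with
empirical ROC analysis and benchmarked against simulated radiologist reading
strategies.

The package is aimed at biostatisticians and imaging researchers who need a
reproducible, fully testable implementation of this evaluation pipeline —
including a synthetic cohort generator, so every stage runs without access to
clinical data.

## What it computes

**Score fusion.** Each modality's continuous score is min–max normalized to
[0, 1] over the analyzed cohort, then fused per case as

    s_fused = w · s_dm + (1 − w) · s_abus,   w ∈ {0.01, 0.02, …, 0.99}

and the weight maximizing the empirical AUC is selected (ties break toward
0.5). Only malignant cases count as positive; benign and normal cases are
pooled as negative.

**ROC machinery.** The AUC is the Mann–Whitney statistic (ties counted half,
computed by midranks); its variance and the paired comparison of two arms on
the same cases use the DeLong structural-components estimator,

    var(AUC) = S₁₀/m + S₀₁/n,   z = (AUC_a − AUC_b)/√(v_a + v_b − 2c_ab),

with a two-sided normal p-value. Operating points are summarized by the
maximum Youden index J = sensitivity + specificity − 1. Confidence intervals
come from a class-stratified percentile bootstrap.

**Reader strategies.** Simulated readers assign ordinal BI-RADS categories
(1 < 2 < 3 < 4a < 4b < 4c < 5) from class-conditional profiles. Strategies:
single reader, either-recall double reading (recalled if either reader
recalls), and a four-reader panel whose consensus BI-RADS category is formed
by majority vote and then thresholded.

**Synthetic cohorts.** Class-conditional bivariate Gaussian scores per
modality with configurable inter-modality correlation, plus calibrated
ordinal readers. The default composition is 42 malignant / 114 benign /
274 normal (430 cases), with an enriched observer subcohort of all 42
malignant plus 30 benign and 80 normal (152 cases).

## Worked example

```r
library(mmroc)

cfg <- study_config(cohort = cohort_config(42, 114, 274),
                    n_replicates = 500, seed = 7)
report <- run_study(cfg)

tidy(report)      # per-arm AUC with bootstrap CIs
#> # A tibble: 3 × 5
#>   arm     auc lower upper level
#>   <chr> <dbl> <dbl> <dbl> <dbl>
#> 1 dm    0.867 0.819 0.916  0.95
#> 2 abus  0.888 0.846 0.929  0.95
#> 3 fused 0.924 0.886 0.955  0.95

glance(report)
#> # A tibble: 1 × 8
#>   n_cases auc_dm auc_abus auc_fused optimal_weight_dm optimal_weight_abus
#> 1     430  0.867    0.888     0.924              0.43                0.57
#> # p_fused_vs_dm 0.0055, p_fused_vs_abus 0.0024
```

On this simulated cohort the fused arm's AUC (0.924) exceeds both single
modalities, the selected weights are 0.43/0.57, and the DeLong paired tests
reject equality against either single arm (p = 0.0055 and 0.0024). The
maximum-Youden operating points per arm are in `report$youden`, the full
weight/AUC sweep in `tidy(report$fusion)`, and the reader strategy table
(single readers, either-recall pairs, the 4-reader panel, each with
bootstrap CIs) in `report$readers`. `autoplot(report$fusion)` and
`plot_study_roc(report)` draw the sweep profile and the ROC overlay with
reader operating points; `render_report(report, "out/")` writes the full
set of delimited tables and a plain-text summary.

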