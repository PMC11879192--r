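# dyssync

Left-ventricular (LV) mechanical dyssynchrony — the discoordinate
contraction pattern typical of left bundle branch block (LBBB) — is what
cardiac resynchronization therapy is meant to correct, and quantifying it
from imaging is an open clinical problem. `dyssync` computes two
complementary dyssynchrony indices from segmental circumferential strain
curves measured in a single mid-ventricular short-axis slice (e.g. by CMR
feature tracking), and provides the statistical machinery used to evaluate
how well such indices separate LBBB from normally activated ventricles.

The package is aimed at imaging researchers who already have segmental
strain curves (the feature-tracking step itself is out of scope) and want a
tested, reproducible implementation of the indices and of the comparison
statistics, plus a synthetic cohort generator so the whole pipeline can be
exercised without patient data.

## The indices

Both indices work on Lagrangian circumferential strain (% of end-diastolic
length; shortening negative) of the six mid-ventricular AHA segments
(anteroseptal, anterior, anterolateral, inferolateral, inferior,
inferoseptal, in circumferential order), with per-subject annotations of the
end-diastolic reference frame and aortic valve opening (AVO) and closure
(AVC).

**CURE** (circumferential uniformity ratio estimate). Per timeframe *t* the
strain across the six ordered segments is Fourier transformed in space;
with zero-order power S₀(t) (uniform deformation) and first-order power
S₁(t) (one-cycle spatial pattern, e.g. septum stretching while the lateral
wall shortens):

    CURE = (1/n) Σₜ S₀(t) / (S₀(t) + S₁(t))

CURE is 1 for perfectly synchronous (spatially uniform) contraction and 0
for pure first-harmonic dyssynchrony.

**SSI** (systolic stretch index). The sum of lateral-wall systolic
pre-stretch (SPS: cumulative stretch of the anterolateral and inferolateral
segments between end-diastole and AVO) and septal rebound stretch (SRS:
cumulative septal stretch after early systolic shortening and before AVC):

    SSI = (SPS_antlat + SPS_inflat)/2 + (SRS_antsept + SRS_infsept)/2   [%]

The statistics layer reproduces the standard evaluation machinery:
median (IQR) group comparison with the Wilcoxon rank-sum test, univariable
logistic odds ratios on clinical reporting scales (per 1% SSI increase, per
0.10 CURE decrease), ROC analysis with Youden-index cutoffs, paired
stratified-bootstrap comparison of two AUCs (percentile CIs, 4000
replicates by default), and intraclass correlation (ICC(2,1)/ICC(3,1)) with
the standard error of measurement.

## Worked example

```r
library(dyssync)

cohort <- generate_cohort(synth_params(n_lbbb = 44, n_control = 36, seed = 42))
idx <- compute_indices(cohort)

group_compare(idx, "ssi")
#> <group_comparison> ssi
#>   LBBB     n=44  10 (9.7-11)
#>   control  n=36  0.25 (0.076-0.48)
#>   Wilcoxon rank-sum, normal approximation with continuity correction: U = 1584, p = 1.93e-14

roc_analysis(idx, "cure", n_boot = 2000, seed = 42)
#> <roc_result> cure
#>   AUC 0.964 (95% CI 0.923-0.994), direction: lower values indicate LBBB
#>   Youden cutoff 0.8622: sensitivity 0.886, specificity 0.944
```

The synthetic LBBB-like arm (44 subjects) has a median SSI of ~10% — the
4% lateral pre-stretch plus 6% septal rebound the generator injects — while
controls sit near 0% (noise only), and low CURE values flag LBBB (the
Youden cutoff here is CURE < 0.86). `plot_strain_curves()`,
`plot_index_distributions()` and `autoplot()` on a ROC result visualise the
curves, the group distributions and the ROC curve; `tidy()`/`glance()`
return tibble summaries of every fitted object; `run_end_to_end()` writes a
fully reproducible report bundle for a seeded configuration.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it generates the default synthetic cohort (44 LBBB-like vs 36 control
subjects) with the given seed, computes CURE/SSI for every subject, runs
the full statistical comparison (rank tests, ROC, paired bootstrap AUC
contrast with 4000 replicates, odds ratios), prints the summary tables, and
writes the JSON summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
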