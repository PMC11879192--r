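---
title: "Quantifying LV mechanical dyssynchrony from segmental circumferential strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LV mechanical dyssynchrony from segmental circumferential strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyssync)
```

## The measurement problem

In left bundle branch block (LBBB) the septum is activated early and the
lateral wall late. Mechanically this produces a characteristic strain
signature in a mid-ventricular short-axis slice: the septum shortens before
ejection while the lateral wall is passively stretched, then during ejection
the late-activated lateral wall contracts and re-stretches the septum
("septal rebound stretch"). Quantifying this discoordination matters because
it is the substrate cardiac resynchronization therapy corrects.

`dyssync` implements two indices over segmental Lagrangian circumferential
strain (in %, shortening negative, referenced to an end-diastolic frame) of
the six mid-ventricular AHA segments, plus the statistics used to evaluate
them. Strain extraction from images is explicitly out of scope: the
package's input boundary is the strain curves themselves, with per-subject
frame annotations of end-diastole (ED), aortic valve opening (AVO) and
closure (AVC). Valve events are treated as annotations (as when read
visually from cine images) and are never estimated from strain.

## The data model

A cohort is two tidy tables. `strain`: one row per subject, segment and
frame (`subject_id, group, segment, frame, strain_pct`); `events`: one row
per subject (`ed_frame, avo_frame, avc_frame`). Frame indices are 0-based
everywhere, including the on-disk formats (long CSV with an `events.csv`
sidecar, or a single JSON file). Invariants enforced at load: exactly six
segments in the fixed circumferential order, a contiguous common frame grid,
strain exactly zero at `ed_frame` (to 1e-9), `0 ≤ ed ≤ avo < avc < n`, and
strain within −100…300%. Because tools differ in their end-diastolic
reference conventions, `read_cohort(re_reference = TRUE)` can re-zero curves
at `ed_frame` on load; by default a non-zero ED strain is a format error, so
silent convention mismatches cannot slip through.

## CURE

Per timeframe $t$, the six circumferentially ordered segment strains are
discrete-Fourier transformed in space. With $S_0(t)$ and $S_1(t)$ the
zero- and first-order terms,

$$\mathrm{CURE} \;=\; \frac{1}{n}\sum_{t=1}^{n}
  \frac{S_0(t)}{S_0(t)+S_1(t)} \in [0, 1],$$

1 meaning perfect synchrony (spatially uniform strain at every frame) and 0
perfect dyssynchrony (pure first spatial harmonic, the septum-vs-lateral
pattern). Numerical conventions the literature leaves open, fixed here and
recorded in each result's metadata:

* **Power vs magnitude.** $S_0, S_1$ are squared DFT coefficient magnitudes
  (power), following the original derivation of the index;
  `power = "magnitude"` is available for sensitivity analysis.
* **One-sided first-order term.** $S_1 = |X_1|^2$ only. For real strain the
  two-sided convention multiplies $S_1$ by a constant, changing CURE's
  numeric value but never the ordering of subjects.
* **Per-frame averaging.** The ratio is formed per frame and averaged over
  $n$ frames (the reading under which $n$ counts timeframes); the pooled
  alternative $\sum_t S_0 / \sum_t (S_0 + S_1)$ is available as
  `pooling = "pooled"`.
* **Degenerate frames.** A frame with $S_0 + S_1 = 0$ (all-zero strain, e.g.
  the ED reference frame itself) is spatially uniform, and contributes 1 to
  the average rather than 0/0.
* **Single slice.** Multi-slice averaging collapses to the one
  mid-ventricular slice that is the package's scope.

CURE is invariant to circular rotation of the segment ordering and to
scaling of the whole strain matrix — both tested properties, as is exact
agreement with a literal-summation DFT oracle.

## SPS, SRS and SSI

Stretch is accumulated as positive consecutive-frame strain increments
$\max(0, s_{i+1} - s_i)$ inside a frame window, with no sub-frame
interpolation (the temporal resolution of the input is the resolution of
the answer; window endpoints are inclusive):

* **SPS** (systolic pre-stretch): window ED→AVO on the anterolateral and
  inferolateral segments; all positive increments count.
* **SRS** (septal rebound stretch): window ED→AVC on the anteroseptal and
  inferoseptal segments; increments count only strictly after the first
  negative increment in the window — the operational reading of stretch
  "following early systolic shortening". Stretch before any shortening is
  pre-stretch, not rebound, and contributes nothing.

$$\mathrm{SSI} = \tfrac{1}{2}(\mathrm{SPS}_{antlat} + \mathrm{SPS}_{inflat})
 + \tfrac{1}{2}(\mathrm{SRS}_{antsept} + \mathrm{SRS}_{infsept})$$

SSI is non-negative, zero exactly when no qualifying stretch exists, and
positively homogeneous (scaling strain by $c>0$ scales SSI by $c$) — all
tested against brute-force enumeration oracles.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without patient
data. It emulates the qualitative mechanics that distinguish the groups,
not any real cohort's distributions — no parameter is calibrated to
reproduce published medians or AUCs.

Waveforms are piecewise raised-cosine curves through phenotype knots
(smooth, zero slope at knots, exactly 0 at the ED frame). Controls shorten
monotonically to their peak at AVC and relax back. LBBB-like septal
segments shorten early to a partial dip at AVO (40% of peak strain), stretch
by exactly `lbbb_rebound_amp_pct` to an apex mid-ejection, then re-shorten;
lateral segments stretch to `lbbb_prestretch_amp_pct` at AVO and reach peak
shortening `lbbb_lateral_delay_frac` of a cycle late. An additive design
(control base + stretch bumps) was tried first and rejected: against the
steep systolic base slope a 6% rebound bump yields well under 1% of
measurable rebound stretch, so the generator would not express its own
stated effect sizes. With the knot construction, noise-free SPS and SRS
equal the stated amplitudes exactly, which makes the generator's defaults
directly interpretable and the index pipeline testable against known truth
(noise-free controls have SSI exactly 0). When all LBBB effect sizes are
zero the LBBB code path is the control construction, so a zero-effect arm
is a true null.

Defaults describe a plausible clinical CMR setting, chosen once: 24
frames/cycle (typical cine temporal resolution); arm sizes 44 LBBB-like vs
36 controls (familiar scale for such cohorts); AVO and AVC at 15% and 45%
of the cycle; mean peak strain −15% with 2% SD (between segment/subject);
rebound 6%, pre-stretch 4%, lateral delay 12% of a cycle; additive Gaussian
frame noise 0.5% (curves re-zeroed at ED after noise so the invariant
survives). A single seeded RNG stream is threaded through subjects in a
fixed order, making cohorts bit-reproducible.

What a green test on synthetic data does **not** establish: real
feature-tracking curves have correlated (not white) noise, variable
waveform morphology, imperfect valve-timing annotation and
vendor-dependent strain amplitudes. The generator supports verifying the
*machinery* (definitions, directionality, statistical calibration), not
clinical performance claims.

## Statistical pipeline

* **Group comparison**: median (IQR; linear-interpolation quantiles) per
  group, two-sided Wilcoxon rank-sum test — exact when combined $n \le 30$
  without ties, else normal approximation with continuity/tie correction.
  The unpaired rank-sum form is the correct test for two independent
  groups, even though reports in this literature sometimes label it
  "signed-rank" (a paired test); the choice is deliberate and documented.
* **Odds ratios**: single-predictor logistic MLE, reported per clinical
  unit (per +1% SSI; per −0.10 CURE, i.e. $\exp(-0.10\,\beta)$), Wald 95%
  CIs transformed to the same scale. Perfect separation raises an explicit
  error rather than reporting a meaningless huge OR; `run_full_analysis()`
  records such an OR as "not estimable (perfect separation)" — which the
  default synthetic world triggers for SSI, since 44 subjects at SSI ≈ 10%
  never overlap 36 controls at ≈ 0.4%.
* **ROC**: AUC via the Mann–Whitney identity (ties ½), direction chosen so
  AUC ≥ 0.5 and recorded; Youden cutoff by exhaustive midpoint search, ties
  broken toward the highest specificity (deterministic, favours the
  screening reading); stratified bootstrap percentile CI.
* **Paired AUC contrast**: subjects resampled with replacement within each
  group, both AUCs recomputed on the same resample, $\Delta = A_a - A_b$;
  percentile CI from 4000 replicates by default; two-sided bootstrap p as
  $2\min(P(\Delta\le 0), P(\Delta\ge 0))$ with the +1 small-sample
  correction. Index orientation is a *fixed argument*
  (`direction_a/direction_b`), not re-estimated from the data: a
  data-driven flip folds the bootstrap distribution at 0.5 and distorts
  interval coverage exactly in the null case. `run_full_analysis()` passes
  each index's known orientation (SSI rises with dyssynchrony, CURE falls).
* **Reliability**: ICC from two-way ANOVA mean squares — ICC(2,1), absolute
  agreement, random raters (inter-rater) and ICC(3,1), consistency, fixed
  raters (intra-rater) — with F-based (Shrout–Fleiss / McGraw–Wong) 95%
  CIs; SEM $= \sqrt{MS_{error}}$, the form consistent with those models.
* **No multiplicity correction** is applied, matching standard practice for
  this kind of two-index evaluation; two-sided $p < 0.05$ is the nominal
  criterion.

All bootstrap machinery is seeded; `run_end_to_end()` derives every
sub-stage seed from the single top-level seed so identical configurations
yield byte-identical report bundles (manifests record configuration and
package version but no timestamps or output paths).

## Numerical and degenerate-input choices

* Stretch windows with fewer than two frames sum to 0; inverted windows are
  contract errors.
* An all-identical index column yields AUC 0.5 with an explicit degeneracy
  warning.
* Zero between-subject variance makes the ICC degenerate — an error, not a
  number. Perfect within-subject agreement ($MS_e = 0$) returns ICC with a
  collapsed CI and SEM 0.
* Constant input to Spearman correlation is an explicit error (rho
  undefined).
* Quantiles everywhere are type 7 (linear interpolation), so printed
  "median (IQR)" strings are reproducible across tools.

## Limitations

The package deliberately stops at the strain-curve boundary: no image
registration, no contour handling, no valve-event detection, no multi-slice
CURE aggregation, and no covariate-adjusted ROC analysis. The synthetic
generator is a stated world for testing machinery, not a cardiac
electromechanics model; conclusions about real cohorts require real strain
data read through `read_cohort()`.
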