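---
title: "IVIM and ADC fitting with whole-lesion vs single-section ROI reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVIM and ADC fitting with whole-lesion vs single-section ROI reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimroi)
```

## The problem

Quantitative diffusion-weighted MRI (DWI) of thyroid nodules aims to
separate benign from malignant lesions without biopsy. Two methodological
questions dominate: which quantity to measure (mono-exponential ADC versus
the intravoxel incoherent motion decomposition), and how to delineate the
lesion — a whole-lesion (W-L) 3D region of interest traced slice by slice,
cysts and necrosis included, or small single-section (S-S) round/oval ROIs
of 20–60 pixels placed in the most solid part. The delineation choice
drives reproducibility: two readers, or one reader weeks apart, will
disagree more where the ROI samples less of the lesion.

`ivimroi` implements the full analysis chain for this setting — signal
models, constrained fitting, ROI aggregation, agreement statistics, and
diagnostic ROC analysis — and, because the underlying patient images of
the motivating two-reader study are not public, a synthetic nodule phantom
whose statistical structure emulates that study, so that every stage is
testable end to end.

## Signal models

For b-values $b$ (s/mm²) the IVIM model describes the normalized signal as
two exponential compartments:

$$\frac{S_b}{S_0} = (1-f)\,e^{-bD} + f\,e^{-bD^*},$$

with $D$ the true (slow) diffusion coefficient, $D^*$ the perfusion-related
pseudo-diffusion coefficient, and $f$ the perfusion fraction. Some printed
versions of this equation omit the $f$ on the fast term; that form is
internally inconsistent with $f$'s definition (the signal would not be 1 at
$b=0$), so the package uses the standard weighted form above.

The mono-exponential ADC is defined through
$\ln S_b = \ln S_0 - b\,\mathrm{ADC}$ and is computed from two-point pairs
$(0, 600)$ and $(0, 990)$ s/mm² (ADC600, ADC990). Because perfusion
contributes to the low-b part of the decay, the two-point ADC of a perfused
voxel always exceeds its $D$; this bracketing is property-tested.

The default acquisition scheme is the eight-b-value protocol
$b = 0, 20, 50, 100, 200, 400, 600, 990$ s/mm², dense at low b to condition
the fast compartment.

## Constrained fitting

`fit_ivim()` performs bounded nonlinear least squares (Levenberg–Marquardt,
via minpack.lm) on the full bi-exponential with $S_0$ fixed to the $b=0$
measurement. Constraints: $0 < D < 0.01$ mm²/s, $D^* > D$, $0 \le f \le 1$.
The $D^* > D$ ordering is encoded exactly by fitting
$\theta = (D, f, \Delta)$ with $D^* = D + \Delta$, $\Delta > 0$, so the
constraint is a box and the optimizer never visits invalid parameter
combinations.

The upper bound on $D^*$ is 0.1 mm²/s rather than sharing $D$'s 0.01
ceiling. Reported pseudo-diffusion coefficients in thyroid tissue sit
around $11 \times 10^{-3}$ mm²/s — just *above* 0.01 — so a shared 0.01
bound would truncate real values; a tissue constraint that excludes the
tissue's own typical values cannot be the operative one. (In detail, the
implemented $\Delta$ box keeps $D^*$ below $\approx 0.1$ for all
attainable $D$.)

Starting values come from a segmented estimate: a log-linear fit over the
high-b points ($b \ge 200$ s/mm², configurable) yields initial $D$ and
$1-f$; the positive low-b residuals yield an initial $D^*$. All three
parameters are then refit jointly, so no b-value cutoff enters the final
estimate — the split only seeds the optimizer. An optional seeded
multistart guards against local minima; on noiseless model-generated
decays a single segmented start recovers parameters to better than 0.1%
(this is a test invariant on a grid of 100 random parameter triples).

Numerical choices: convergence tolerance $10^{-12}$ on the residual norm;
non-convergence is flagged in the result, never returned as silent `NA`;
voxels outside the fitting mask carry `NA` as the missing-value sentinel
and are excluded from every ROI summary.

## The synthetic cohort

`generate_cohort()` builds the default study: 24 benign and 22 malignant
ellipsoidal nodules on a $32 \times 32 \times 8$ grid of
$1.5 \times 1.5 \times 5$ mm voxels (semi-axes 13, 10, 8 mm — a ~3 cm
nodule, matching the reported mean diameters). Per-nodule mean parameters
are drawn from truncated normal group distributions whose defaults are the
published whole-lesion group values: benign
$D = 1.24 \pm 0.35$, $f = 37.95 \pm 10.05\,\%$, $D^* = 10.95 \pm 2.55$;
malignant $D = 0.69 \pm 0.13$, $f = 29.36 \pm 5.69\,\%$,
$D^* = 11.54 \pm 1.87$ ($D$, $D^*$ in $10^{-3}$ mm²/s). Normal draws are
justified by the study's own Shapiro–Wilk results.

Within a nodule, voxel parameters are the drawn mean plus a spatially
correlated Gaussian texture (smoothed white noise, correlation length
$\approx 2.5$ voxels in-plane), re-centred over the nodule so the drawn
triple is the *exact* nodule mean. Texture SDs default to
$0.35 \times 10^{-3}$ (D), 10 percentage points (f) and
$4 \times 10^{-3}$ ($D^*$): the published per-delineation SDs are larger
for S-S than W-L measurements by roughly these magnitudes once S-S
sampling attenuation is accounted for, and $D^*$ (perfusion) is the most
spatially heterogeneous quantity. Spatial correlation is essential: with
independent voxel noise a 40-pixel ROI mean would average texture away and
single-section sampling variability — the phenomenon under study — would
vanish.

An optional cystic/necrotic subregion (default 5% of nodule volume, a
contiguous blob at a random interior focus) carries free-water-like
parameters ($D = 2.8 \times 10^{-3}$, $f = 5\%$,
$D^* = 12 \times 10^{-3}$); it is included by W-L ROIs and avoided by S-S
placement, as in the delineation protocols. The default fraction is small
because the emulated study found *no* significant paired W-L vs S-S
differences — a large cystic compartment would contradict that. The
surrounding parenchyma gets plausible thyroid values
($D = 1.4 \times 10^{-3}$, $f = 25\%$, $D^* = 9 \times 10^{-3}$).

Noise is Rician, $|S + n_1 + i n_2|$ with $n_{1,2} \sim N(0, \sigma)$,
$\sigma = 0.01\,S_0$ by default (SNR 100 at $b=0$). This emulates a
4-average reduced-FOV acquisition after magnitude averaging; at
substantially lower SNR the voxelwise $D^*$ estimate acquires a strong
upward skew-bias that the published measured distributions do not show
(their measured means match their group-level means almost exactly), so
higher noise would *mis*-emulate the study. The Rician mean bias at the
$b=0$ signal is below 1% for SNR ≥ 20, verified against the analytic
Rician mean.

### Observer model

Each (observer, session) delineation jitters the true W-L mask by
per-slice morphological dilation/erosion with random integer radius up to
`boundary_jitter` (default 1.5 mm ≈ 1 voxel), and places two S-S ROIs —
random ellipses trimmed to 20–60 pixels — in the solid compartment of two
tumour-containing slices, redrawing slice choice, position, size and shape
independently per delineation. A jitter that would empty a slice is
redrawn, and a slice that resists 10 redraws is kept unperturbed rather
than silently dropped. The study design is mirrored as three delineations:
reader 1 session 1, reader 2 sessions 1 and 2; intraobserver agreement
uses reader 2's two sessions, interobserver agreement uses the two
readers' first sessions.

### What the phantom does not model

No anatomically realistic thyroid geometry, no partial-volume physics, no
eddy-current/motion/susceptibility artefacts, no T2 or noise-floor effects
specific to the $b = 990$ image. The last point matters when comparing
markers: in real data ADC990 suffers most from acquisition effects at the
highest b-value, whereas in this phantom ADC990 is as clean as ADC600.
Since per-nodule $D$ and $f$ are drawn independently and both discriminate
the groups, ADC990 — which mixes them — is structurally at least as
discriminative as $D$ here, slightly *reversing* the real study's ranking
in which $D$ and ADC600 led and ADC990 trailed. Passing or failing an
AUC-ranking check on this cohort therefore reflects the phantom's scope,
not the fitter or the statistics.

## ROI aggregation

`summarize_roi()` takes the arithmetic mean of each voxelwise map over the
masked, non-missing voxels (permutation-invariant, bounded by the voxel
range). The two S-S ROIs of a delineation are combined by the unweighted
mean of their means (`aggregate_ss()`), with a pixel-weighted option,
since the emulated protocol reports one S-S value per nodule without
stating weights. Both "fit every voxel then average" and "average the ROI
signal then fit" are provided (`roi_fit_mode()`): they agree exactly on
homogeneous ROIs and differ by a Jensen gap on heterogeneous ones; the
pipeline default is fit-then-average, matching the pixel-by-pixel mapping
described in the emulated study. ADC600/ADC990 are recorded for W-L ROIs
only, as in that protocol.

## Agreement statistics

`icc21()` implements ICC(2,1) — two-way random effects, absolute
agreement, single measures — the standard model for test-retest and
inter-rater agreement when raters are a random sample and systematic
offsets should count against agreement. The study never names its ICC
model; ICC(2,1) is the defensible default for this design. From the
two-way ANOVA mean squares,

$$\mathrm{ICC}(2,1)
  = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the 95% CI by the McGraw–Wong F-distribution method. Identical data
(zero total variance) yields a defined ICC of 1 with a warning, not `NaN`.
The implementation is property-tested against an independent
`aov()`-based decomposition and against a second implementation
(pingouin's ICC(A,1)) on a frozen table. Interpretation bands follow the
conventional closed two-decimal cutpoints (0.00–0.20 poor, 0.21–0.40 fair,
0.41–0.60 moderate, 0.61–0.80 good, 0.81–1.00 excellent); note that
published prose sometimes labels values inconsistently with this table
(e.g. calling 0.51 "fair") — the package follows the table.

Bland–Altman limits of agreement are $\bar d \pm 1.96\,s_d$; the 1.96
multiplier is fixed (95% limits). `format_loa()` renders the conventional
"low-high" span at 2 decimals. The distribution battery
(`repeated_measure_tests()`) runs Shapiro–Wilk per delineation, Levene's
test (one-way ANOVA on absolute deviations from group means) and one-way
ANOVA across the repeated delineations.

## Diagnostics

Malignant is the positive class; for $D$, $f$ and ADC low values indicate
malignancy, so scores are negated internally to keep AUC ≥ 0.5 while
cutoffs are reported on the original marker scale. The AUC is the
normalized Mann–Whitney statistic (ties counted ½), its variance and the
correlated-AUC z-test follow DeLong's placement-value construction (the
covariance is algebraically identical to the grouped delete-one jackknife,
which the tests exploit as an oracle), and the 95% CI is the normal
approximation truncated to [0, 1]. The Youden-optimal cutoff maximizes
$J = \text{sens} + \text{spec} - 1$ over observed values; ties break
toward higher sensitivity, then the lower threshold. Confusion-derived
rates (sensitivity, specificity, PPV, NPV, accuracy) are percentages; a
zero PPV/NPV denominator is flagged undefined rather than crashing.
`logistic_combine()` fits a maximum-likelihood logistic model on several
markers, uses the linear predictor as combined score (ROC is invariant to
the monotone link) and flags perfect separation as non-convergence.
Pairwise DeLong comparisons are reported with raw and Bonferroni-adjusted
p-values — the simplest defensible reading of "adjusted P value used for
multiple comparisons".

## The pipeline

```{r, eval = FALSE}
res <- run_study(study_config(seed = 1, out_dir = "results"))
res$agreement$icc       # ICC table by parameter, method, comparison
res$diagnostics$table   # per-marker AUC, Youden cutoff, sens/spec/...
```

`run_study()` is deterministic given configuration and seed (every
stochastic routine takes an explicit derived sub-seed and restores the
caller's RNG state); identical runs produce byte-identical CSV reports.
The report bundle mirrors the emulated study's table structure:
distribution table, ICC table, Bland–Altman table, method-comparison
table, group-comparison table, diagnostic table, pairwise AUC comparisons,
plus a cohort manifest, a serialized configuration and a provenance
record. `fit_only()` covers the file-based route (NIfTI volume + bval +
mask NIfTIs); b-values may arrive in any file order and are canonically
re-sorted together with the 4th dimension.

Problem sizes: the default cohort (46 nodules, ~600 fitted voxels per
nodule including the jittered-mask union) takes ~20 s per replicate on one
core; the test suite's qualitative-reproduction check runs 20 seeded
replicates, and its degenerate zero-noise/zero-jitter conservation run
uses the full-size cohort.

## Known limitations

* The voxelwise $D^*$ estimate is skew-biased upward under noise (a
  well-known IVIM behaviour); the phantom's default SNR keeps this small,
  but at low SNR ROI means of $D^*$ should be interpreted cautiously.
* Texture SDs are a modeling knob: the emulated study publishes no
  within-nodule heterogeneity statistics, so they were set from the
  S-S-minus-W-L SD excess of its printed distribution table, capped at
  physically plausible voxel-level values.
* In-sample diagnostics only: cutoffs and the logistic combination are
  evaluated on the data that chose them, as in the emulated analysis; no
  cross-validation is provided.
* The paired W-L vs S-S comparison can reach significance in the phantom
  when the cystic fraction is raised, because the cystic compartment
  shifts only the W-L mean; the default keeps this shift small.
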