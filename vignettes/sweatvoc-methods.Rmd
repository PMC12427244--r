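---
title: "Methods: dual-platform chemometrics for the sweat volatilome"
author: "sweatvoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-platform chemometrics for the sweat volatilome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analytical problem

Sweat carries a volatile organic compound (VOC) profile — the volatilome —
that reflects host and skin-microbiome metabolism. Two measurement
platforms see this profile very differently:

* **GC-MS** resolves individual compounds: each sample yields a peak table
  of (retention time, integrated peak area) pairs, consolidated across
  samples into a samples × retention-time feature matrix of positive,
  right-skewed abundances with missing entries where a compound was not
  detected.
* An **electronic nose** (here, a 14-channel MEMS metal-oxide array) sees
  the mixture as a whole: each sample is a multichannel transient acquired
  over a 1-minute ambient baseline followed by a 2-minute headspace
  exposure, summarized per sensor by the Max–Min response amplitude. Such
  arrays drift: the same odor measured at different points of a session
  produces shifted responses.

`sweatvoc` implements both arms as a single tested pipeline for binary
case/control discrimination (labels `CO`/`CRC` throughout, with `CRC` the
positive class), together with a synthetic-data module that emulates both
data types so that every stage can be exercised and calibrated without
instrument access.

# GC-MS arm

```
peak tables -> round/merge RT -> consolidate -> drop empty features ->
impute -> normalize -> Wilcoxon screen -> PCA or PLS-DA -> classifier -> CV
```

**Curation.** Retention times are rounded half-away-from-zero to one
decimal place (banker's rounding is rejected for cross-platform
reproducibility); peaks collapsing onto one rounded RT are merged, by
default summing their areas so total abundance is conserved (`max` is
available). Consolidation takes the sorted union of RTs; a sample without
a peak at some RT gets a *missing* entry, not a zero — absence of
detection is not evidence of absence, and is handled by imputation.
Features with no observed positive value are removed. Division by the
internal-standard (limonene) area is implemented
(`normalizeToInternalStandard`) but off by default: the internal standard
is treated as a comparability check unless the user opts into quantitative
correction.

**Imputation.** `imputeMovingAverage` replaces each missing cell by the
mean of observed values in a centered window (default size 3) of rows of
the same column, in stored sample order — the natural analogue of
moving-average smoothing for a matrix whose rows follow acquisition order.
The window truncates at the edges; a fully missing window falls back to
the column mean. All replacements are computed from the original observed
entries, so imputation is order-independent and idempotent. Imputation
runs once, upstream of cross-validation: it is unsupervised, strictly
within-column, and uses no label information.

**Normalization.** Seven per-feature transforms are available — min–max,
z-score, quantile (rank averaging, midrank ties), Pareto, autoscaling,
log, square root — all fitted on training data and applied to held-out
data without touching its statistics. Autoscaling is the default, and
z-score/autoscale are the same transform under this package's single
convention (population standard deviation, floored at 1e-12 so constant
features map to zero). The log offset of 1 engages only when zeros are
present; raw peak areas are orders of magnitude above 1, so it is
numerically immaterial.

**Feature screening.** Each feature is tested with a two-sample Wilcoxon
rank-sum test (midranks; exact enumeration when both groups together hold
at most 12 tie-free values, otherwise the normal approximation with
tie-corrected variance and continuity correction). Features with raw
p < 0.05 are kept — deliberately without multiple-testing correction, to
mirror the raw-p screening practice this pipeline reproduces; a
Benjamini–Hochberg option exists (`adjust = "BH"`). If *no* feature
clears the threshold (taken literally: zero features), the 13
highest-variance features are kept instead, with the variance ranking
computed on the pre-scaling matrix (after autoscaling all variances are
~1 and the ranking would be meaningless).

**Projection.** PCA is a plain SVD of the column-centered matrix with
explained-variance ratios from squared singular values. PLS-DA is NIPALS
PLS1 against the centered 0/1 class code: per component
`w ∝ X'y` (unit norm), `t = Xw`, `p = X't/t't`, `q = y't/t't`, deflating
both `X` and `y`. A two-column dummy response would be redundant for two
classes. Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SS_a\, w_{ja}^2}{\sum_a SS_a}},
\qquad SS_a = q_a^2\, t_a^\top t_a,$$

so squared VIPs always sum to the number of features in the fitted model.
Because the mean square of VIP over the fitted features is exactly 1, VIP
magnitudes depend on the feature universe (13 selected features vs 187
curated ones give different scales); `sweatvoc` computes VIPs over the
selected set that the model was fitted on and reports that universe in
its outputs. The significance threshold is surfaced as a parameter
defaulting to 0.1 (the convention in the originating analysis), with the
caveat that 1.0 is the usual cutoff in the wider literature. All
component signs follow a fixed convention (largest-magnitude loading or
weight positive) so scores and plots are bit-for-bit reproducible.

**Group separation.** `permanovaTest` computes the distance-partitioned
pseudo-F on Euclidean distances with seeded label permutations
(999 by default); the p-value uses the `(1 + #{F* >= F}) / (1 + nPerm)`
convention. The pipeline quantifies separation on the reduced
(selected, normalized) matrix — the same view the score plots are drawn
from; on the full 187-feature matrix the statistic is diluted by the ~174
uninformative dimensions. The distance metric and permutation count are
surfaced as parameters since conventions differ.

# E-nose arm

```
transients -> phase segmentation -> Max-Min -> OSC -> autoscale -> PCA ->
classifier -> CV (a no-OSC ablation is always reported alongside)
```

**Features.** Phase boundaries are assigned by elapsed time (60 s
baseline, 120 s exposure by default), never by sample index, so irregular
sampling is safe; stabilization and purge stretches are parsed but
excluded. The per-sensor feature is max − min over the baseline+sample
window, capturing the baseline-to-plateau excursion (a sample-only window
is available by flag). No kinetic features (rise times, steady states)
are extracted — deliberately out of scope.

**Orthogonal signal correction.** `oscCorrect` implements the
NIPALS-style iterative variant: starting from the first principal
component score, orthogonalize the score against the centered class code,
regress the data on it for a unit weight vector (the inner PLS step), and
iterate to a relative score change below 1e-6; the converged
score–loading product is removed. Each removed training score has
|correlation| < 1e-6 with the class code by construction. Simpler
one-shot orthogonalization variants were rejected in favour of the
iterative correction. One component is removed by default; the count is
configurable.

A limitation worth stating plainly: OSC transfers to *held-out* data
through its stored weights alone (no labels are available there). When
the nuisance direction and the class-difference direction are strongly
collinear — exactly the drift-dominated regime simulated here — the
held-out projection removes the class signal along with the drift, so in
`honest` mode (transforms refitted inside each training fold) OSC cannot
help. The published-style procedure corrects the whole cohort with labels
first and then cross-validates only the classifier; `sweatvoc` exposes
both policies (below) and reports which one produced any given number.

# Classification and validation

LDA (pooled within-class covariance, ridge `1e-6 ×` mean diagonal),
L2-penalized logistic regression (IRLS to gradient norm < 1e-6), a linear
SVM (hinge loss, dual coordinate descent to projected-gradient tolerance
1e-4, deterministic sweep order), and k-NN (Euclidean, k = 5, vote ties
broken by smaller mean distance then by the negative class; scores are
CRC vote fractions) share one contract and one pipeline-level seed.
Stratified k-fold assignments (default k = 5) deal shuffled class members
round-robin with a rotating offset, so per-class counts *and* fold totals
differ by at most one.

Fold predictions are pooled into a single whole-cohort confusion matrix
(not averaged per fold), from which the panel — overall accuracy and
per-class sensitivity, specificity, precision, F1, with each class in
turn treated as positive — is computed at full precision and rounded to
one decimal only at the reporting layer. ROC curves sweep the unique
scores; AUC is the trapezoid area, identical to the normalized
Mann–Whitney statistic with half-credit ties.

**Leakage policy.** `mode = "honest"` (the default) refits every
transform — normalizer, feature screen, PCA/PLS-DA, OSC — inside each
training fold. `mode = "as_paper"` fits the transforms once on all
samples and cross-validates only the classifier, the common chemometric
practice whose optimism the honest mode exposes; on null data the honest
pipeline sits at chance while the paper-style one can stay above it.
Every result object records its mode and seed.

# The synthetic-data module

The generators define the study conditions under which the pipeline's
documented behavior is asserted; their defaults are fixed, not tuning
knobs.

**GC-MS generator.** 34 control vs 31 case samples over 187 retention
times (0.1-min grid). Thirteen planted features carry the group geometric
means of `defaultInformativeFeatures()` (log-fold changes from about 0.2
to 1.5); all other features share one lognormal distribution across
groups. Noise is multiplicative lognormal; missingness is completely at
random at rate 0.05 (no mechanism being specified by the data this
emulates, the simplest one is used). The default coefficient of variation
is 2.0: within-group variances for the planted features are not published
anywhere, so the free noise parameter was calibrated once so that the
synthetic cohort reproduces the *observed difficulty* of the real
analysis (cross-validated accuracies in the 70–90% band, supervised
projection clearly ahead of unsupervised, rather than everything
saturating at 100% as happens below CV ≈ 1). Biological peak-area CVs of
this order are commonplace in untargeted volatilomics. The
moderate-noise regime (CV = 0.5) remains in use in the test suite where
detection power at large n is the property under test.

**E-nose generator.** 35 + 33 recordings, 14 channels at 1 Hz, 60 s
baseline + 120 s exposure. Each channel is a fixed per-sensor baseline
level, plus a class-dependent plateau during exposure, plus a shared
linear drift whose slope is drawn once per recording from a half-normal
distribution (heated metal-oxide sensors drift monotonically within a
session; positivity also makes the noiseless amplitude exactly
`A + slope × span`), plus white noise (sd 0.15). The case/control
amplitude difference (~0.25 units, near-uniform across sensors with
±0.02 sensor-specific deviations) is deliberately almost collinear with
the drift direction, and the default drift scale (0.01 units/s, i.e.
~1.8 units over a recording) dwarfs it: the uncorrected pipeline is
drift-limited, as the instrument this emulates was, which is precisely
the condition OSC exists to fix. Linear within-recording drift is the
simplest structure OSC provably removes; adsorption kinetics, humidity
response and other sensor physics are intentionally not modelled.

What passing tests on these generators do and do not show: they verify
the pipeline's *relative* behavior (OSC ablation direction, supervised vs
unsupervised projection, null calibration, estimator correctness against
brute-force oracles) under a stylized data model. They cannot certify
absolute diagnostic performance on real sweat data, whose noise
structure, batch effects and biology the generators do not claim to
reproduce.

# Numerical choices and degenerate inputs

* Rank exhaustion in PLS truncates with a warning (score sum of squares
  below `1e-12 ×` total); a response orthogonal to X legitimately yields
  `q ≈ 0` rather than an error.
* OSC skips a component (leaving the data untouched) when the
  orthogonalized score is numerically zero — data with no
  class-orthogonal structure pass through unchanged; `nOsc = 0` is an
  exact identity.
* All-equal samples in the rank-sum test return p = 1 with a degeneracy
  flag; sd floors (1e-12) keep constant features finite everywhere.
* k-NN vote ties: smaller mean distance, then the negative (CO) class —
  fixed, documented, deterministic.
* Every stochastic step (simulation, fold shuffle, permutations) takes an
  explicit seed and restores the caller's RNG state.

# Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data
at the cohort sizes above: 20-seed medians for the pipeline-level
properties, 2000–10000 replicates for the rank-sum calibration, and
≤ 50-sample instances for the brute-force oracle comparisons — sizes
chosen so the full suite completes in minutes on a single core while
keeping the Monte-Carlo error well inside the asserted margins.

# Known limitations

* Binary classification only; no multi-class extension, no kernel SVM,
  no hyperparameter search, no class weighting (the emulated cohort is
  near-balanced).
* OSC with collinear drift and class signal does not transfer to
  label-free held-out data (see above); the ablation contrast is
  therefore reported under the paper-style policy.
* The GC-MS arm starts from integrated peak tables; raw chromatogram
  processing (peak detection, alignment, spectral identification) is out
  of scope.
* PERMANOVA is Euclidean-distance only, matching the feature spaces used
  here.
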