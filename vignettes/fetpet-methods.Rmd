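---
title: "Methods: phantom-validated FET-PET quantification, concordance and outcome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated FET-PET quantification, concordance and outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetpet)
```

This vignette is the package's account of its own methods: the models it
fits, the conventions it adopts where the field leaves room, what the
synthetic phantoms do and do not emulate, and the numerical choices that
affect results.

## SUV and SURmax

`to_suv()` implements the body-weight SUV convention: the voxel activity
concentration `C` (kBq/ml) divided by injected activity per body weight
(MBq/kg, numerically kBq/g under the 1 g/ml tissue-density convention),
so SUV is dimensionless. Lean-body-mass or body-surface-area variants are
deliberately not offered; SUVbw is the near-universal default for brain
PET and keeps the conversion a pure ratio. Inputs are assumed
decay-corrected to injection time (the DICOM norm). When they are not,
`decay_corrected = FALSE` rescales by `exp(ln 2 · Δt / T½)` with the ¹⁸F
half-life `T½ = 109.77` min; over exactly one half-life this doubles SUV,
which the tests assert.

`surmax()` requires the background reference region as an explicit mask
and refuses overlap with the tumor ROI. No automatic contralateral
mirroring is attempted: a deterministic, caller-controlled reference keeps
the operation testable and mirrors clinical practice, where the reference
is drawn manually in the contralateral hemisphere (or the unaffected
anterior/posterior brain for midline tumors). Hot non-tumor structures
(vessels, basal ganglia) are handled by exclusion from the ROI, not by any
intensity heuristic.

## Isocontours

`isocontours()` thresholds at `level/100 × SUVmax(ROI)` with an
*inclusive* `≥` comparison. The convention decisions:

- inclusive threshold, so the 100% contour is the argmax voxel set rather
  than empty;
- no connected-component pruning or hole-filling: satellite
  supra-threshold voxels inside the ROI are retained, making the contour a
  pure function of the image and threshold;
- volumes are voxel count × voxel volume, reported in ml ≡ cm³.

Because thresholds are relative to the in-ROI maximum, isocontour masks
are invariant to positive rescaling of the image; contours can therefore
be computed on raw activity or SUV interchangeably. Nesting
(I70 ⊆ I60 ⊆ I50 ⊆ I40) holds by construction and is property-tested on
random phantoms.

## Conformity

`conformity()` computes CI as voxel-count Jaccard and Dice alongside,
which satisfy `dice = 2·ci/(1+ci)` exactly; the suite checks both against
an independent set-operation oracle on random masks. `pct_increase` uses
MRIvol as the denominator: it answers "by how much would adding the PET
contour grow the treatment volume". At equal CI,
`best_matching_isocontour()` breaks ties toward the *smallest* level,
i.e. the largest contour — the conservative choice for target coverage.
Binary masks are resampled between grids by nearest neighbour
(`resample_to_grid()`), never linearly: interpolation would require a
second, arbitrary re-binarization threshold. Rigid registration itself is
out of scope; both images must already share a world frame through their
affines.

## The synthetic phantoms

The generators define the study conditions for every test; their defaults
were fixed once, before the validation suite was interpreted, and are as
follows.

**PET phantom** (`make_pet_phantom()`): uniform background (default
1 kBq/ml, a typical brain background relative to glioma hotspots of 3–12)
plus anisotropic Gaussian hotspots and i.i.d. Gaussian voxel noise clipped
at zero. This captures what the downstream statistics are sensitive to —
a focal maximum over background, smooth fall-off, max-statistic noise
bias — and deliberately omits scanner physics: point-spread blurring,
attenuation, scatter, reconstruction artefacts, and the spatial noise
correlation of real reconstructions. Consequences: phantom tests validate
the *computational* pipeline (thresholding, counting, overlap, model
fitting), not quantitative accuracy on real scanners; partial-volume
effects in particular are absent. Ground truth records the noise-free
peak and noise-free isocontour volumes; for an isotropic hotspot the
50% contour is the sphere of radius `σ√(2 ln 2)`, and the closed form
(`gaussian_isocontour_volume_ml()`) agrees with voxel counting to within
one voxel shell.

**Target masks** (`make_target_mask()`): a mask with a *planted*
conformity index against the level-% isocontour. Rather than searching
over erosions/dilations/shifts — whose discrete CI steps can straddle the
requested band — the mask is built directly: removing `r` interior voxels
and adding `r` exterior ring voxels gives Jaccard `(n−r)/(n+r)` exactly,
so `r = round(n(1−J)/(1+J))` lands within ±0.05 of any feasible target
for non-degenerate contours. The achieved index is re-verified by direct
voxel counting before the mask is returned, and unreachable targets
(empty or tiny contours, no room to grow) raise errors naming the level.

**Survival cohorts** (`make_survival_cohort()`): SUVmax uniform over a
range (default 1–8, spanning the uptake values reported for high-grade
glioma); event times log-logistic with shape β and scale
`scale_base · exp(−effect · 1[SUV > cutoff])` — the same family the
analysis fits, so parameter recovery is meaningful. Defaults β = 2 and
`scale_base` = 12 months give a 12-month low-group median with a
clinically plausible hazard shape. Censoring is independent uniform on
(0, c); c is solved numerically (integration + root finding) so the
expected censored fraction equals `censor_rate`, keeping censoring
non-informative by construction.

**Expression studies** (`make_expression_study()`): Gaussian log-scale
expression with planted genes carrying slope β on per-sample SUVmax, a
per-gene grade main effect scaled by `grade_confounding`, a per-patient
per-gene random intercept (sd 0.5) shared across timepoints, and residual
sd 1 (both in log-expression units, typical microarray scales). Grade is
derived from the patient's baseline-SUVmax tercile, so grade genuinely
confounds the SUVmax–expression relationship whenever the grade effect is
non-zero; per-sample SUVmax adds a small jitter (sd 0.3) around the
patient baseline so mixed-model slopes are identified both within and
between patients. Not emulated: probe-level artefacts, batch effects,
heavy-tailed expression, gene–gene correlation beyond the shared patient
intercepts — so passing tests demonstrate correct inference under the
stated model, not robustness to microarray pathology.

All generators take one explicit seed and touch no global state beyond
R's RNG inside the call; identical inputs give byte-identical outputs.

## Survival modelling

`fit_loglogistic()` fits the AFT parameterization
`S(t|x) = 1/(1 + (t/α(x))^β)`, `log α(x) = μ + xᵀθ`, via the censored
maximum likelihood (the log-logistic location-scale model on log-time;
α = exp(linear predictor), β = 1/scale). The reported per-covariate
effect is `exp(−θ)` — a time-ratio-based odds-ratio analogue oriented so
values above 1 mean worse (accelerated) survival; the orientation is
stated in the output rather than left implicit because parametric
survival software is inconsistent on sign conventions. `fit_coxph()`
maximizes the Breslow partial likelihood and reports hazard ratios; a
diverging coefficient (monotone likelihood) is surfaced as an error
suggesting penalization rather than a silently huge estimate.

`median_split()` and `scan_cutoffs()` both dichotomize with a strict
`suvmax > c` rule, so a subject exactly at the cutoff is "low". The scan
grid is the set of midpoints between consecutive distinct observed values
that leave at least `min_group` (default 5) subjects on each side:
midpoints make every distinct data partition reachable exactly once, and
the floor prevents degenerate fits in tiny tails. No multiplicity
correction is applied *inside* the scan — the optimal cutoff is by
definition the unadjusted minimum — but the full per-cutoff trace is
returned so users can correct afterwards, and the suite demonstrates the
inflation: on null cohorts the fixed-cutoff Wald test rejects at ~5%
while the scan minimum rejects at roughly half of all null cohorts.

A precision caveat, measured on the package's own generator: with
n = 120, a true cutoff of 3.0 and effect 0.8 on the log scale, the
minimum-p cutoff lands within one grid step (one data partition) of the
truth in only about half of replicates, with a median absolute error of
≈ 0.12–0.15 SUV units and a long tail; within-one-step recovery exceeds
90% only around effect 1.6. An independent per-cutoff likelihood
optimizer reproduces the scan's argmin exactly, so this is the
estimator's sampling behaviour, not an implementation artefact.
Minimum-p cutpoints should be reported with their trace, not as point
truths.

## Feature ranking

`assemble_features()` emits, per isocontour level, the seven
concordance-derived features (PET volume, intersection, union, CI, Dice,
added volume, percent increase) plus MRIvol, SUVmax and SURmax — 31 base
columns at the standard four levels — with a deterministic column order
and a z-scaled copy using the population sd; constant columns are flagged
and excluded from scaling.

`rank_features_by_grade()` runs grade-stratified 80% subsampling without
replacement (default 200 resamples) and fits a random-forest classifier
per resample, recording out-of-bag *permutation* importance — chosen over
impurity importance for its lower bias toward high-cardinality features.
Reported are the mean importance and the frequency each feature ranks
first. One behaviour to understand when reading null results: because
all resamples are 80% subsamples of a single dataset, a feature that is
chance-correlated with grade in that dataset dominates its own resamples.
Across independent null datasets the dominant feature changes (the suite
asserts this), but within one dataset the top frequency of a pure-noise
feature has a heavy right tail — measured over 30 null datasets of 30
patients × 19 features: median maximum frequency 0.28, but above 0.3 in
roughly a third of datasets. Resampled top-rank frequency is evidence of
*stability within a cohort*, not a calibrated error rate.

`compare_groups_ranksum()` uses exact enumeration when the combined
sample size is ≤ 12 with no ties (small-cohort comparisons are exact),
and the tie-corrected normal approximation otherwise; both paths can be
forced, and they agree to within 0.02 at the crossover size.

## Transcriptome association

`mad_filter()` ranks genes by raw MAD (no 1.4826 consistency factor —
scaling is monotone and cannot change a ranking) and keeps the top
`ceil(fraction · n)`; boundary ties break by gene id so the kept set is
deterministic. `associate_genes()` fits, per gene, OLS of expression on
per-sample SUVmax plus initial WHO grade as a numeric 2/3/4 covariate
(matching its ordinal use; a factor encoding is available via
`grade_as_factor`), with a two-sided t-test on the SUVmax coefficient,
Bonferroni over the tested genes, and Benjamini–Hochberg q-values.
Repeated blood timepoints enter as separate rows here — the within-patient
correlation this ignores is the reason the checkpoint-gene analysis
exists: `mixed_checkpoint_model()` adds a Gaussian per-patient random
intercept, fitted by REML, with a normal-approximation Wald p on the
slope. The same normal approximation is used in the single-timepoint OLS
fallback, so the degenerate case (zero between-patient variance) matches
OLS to numerical precision. With ~10–12 patients the normal
approximation on the mixed-model slope is mildly anti-conservative; the
suite measures its null rejection rate and finds it near nominal at the
study sizes used. Constant genes are excluded with a flag (they carry no
information and would produce 0/0 statistics) and do not count toward the
multiplicity burden; exact SUVmax–grade collinearity is an error, since
the adjusted coefficient is then unidentifiable.

## Pipeline

`run_pipeline()` chains phantom generation → SUV → isocontours →
concordance → features → survival → transcriptome from one JSON
configuration, validating the configuration (including the existence of
every referenced input path) before any computation. All tables are CSV
with '.' decimal and LF endings; the manifest records package version,
seeds, and MD5 hashes of every output, and contains no timestamps, so a
rerun with the same configuration is byte-identical end to end. Stage
failures abort with the stage name; later stages write nothing.

## Problem sizes

The validation suite was sized for single-CPU desk runs: mask-oracle
checks on grids up to 32³ (200 random pairs), 50 random phantoms for
nesting, n = 10,000 for log-logistic consistency (n = 50 against a
two-parameter grid-search oracle), 100 seeded cohorts of n = 120 for
cutoff-scan recovery, 200 null cohorts of n = 60 for calibration, a
2,000-gene null study and 10 replicate 1,000-gene studies for FDR
behaviour, and 200 forest resamples for feature-ranking recovery. The
full suite runs in roughly two minutes; the acceptance script in about
one.

## Known limitations

- No scanner physics in the phantoms (see above): real-data quantitative
  accuracy is out of validation scope.
- No SUVpeak/SUVmean metrics and no dynamic (time–activity) FET analysis.
- The minimum-p optimal cutoff is intrinsically imprecise at moderate
  effect sizes and its p-value is anti-conservative; both behaviours are
  quantified by the suite and should temper clinical interpretation.
- `associate_genes()` treats repeated timepoints as independent rows;
  only the checkpoint-gene models handle within-patient correlation.
- Registration, DICOM ingestion, pathway/cell-fraction inference and 2-D
  embeddings are out of scope; the feature matrix is exported for
  external tools.
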