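# fetpet

Quantitative analysis of amino-acid PET (¹⁸F-FET) in high-grade glioma, as
a tested, reusable R pipeline. The package is aimed at radiation-oncology
and imaging researchers who want to

- convert PET activity-concentration volumes to standardized uptake values
  (SUV) and extract tumor uptake metrics (SUVmax, SURmax),
- segment tumors as %SUVmax isocontours (I40–I70) and measure their volumes,
- quantify concordance between PET isocontours and MRI-based radiotherapy
  target volumes (GTV/CTV) with the conformity index and Dice coefficient,
  and identify the *best matching isocontour*,
- rank volumetric/uptake features by their ability to separate tumor
  grades (resampled random-forest permutation importance),
- stratify survival by SUVmax with median and minimal-p-value *optimal*
  cutoffs under log-logistic AFT and Cox PH models, and
- associate whole-blood transcriptomes with SUVmax, adjusted for tumor
  grade, with MAD gene filtering and Bonferroni/Benjamini–Hochberg control.

Clinical scans and microarray data are rarely shareable, so the package
ships a synthetic-phantom module (`phantom_spec()`, `make_pet_phantom()`,
`make_target_mask()`, `make_survival_cohort()`, `make_expression_study()`)
that generates every input with known ground truth; all validation runs
against these phantoms.

## The quantities at the core

- **SUV** (body-weight convention, tissue density 1 g/ml):
  `SUV(v) = C(v) / (A_inj / w)` with `C` the activity concentration in
  kBq/ml, `A_inj` the injected activity (MBq) and `w` body weight (kg).
  Optional decay correction `C · exp(ln2 · Δt / T½)`, `T½ = 109.77` min
  for ¹⁸F.
- **SURmax** = SUVmax(ROI) / mean SUV of a contralateral reference region.
- **Isocontour Ix** = voxels in the ROI with SUV ≥ x% · SUVmax (inclusive
  threshold; I70 ⊆ I60 ⊆ I50 ⊆ I40 by construction).
- **Conformity index** CI = |PETvol ∩ MRIvol| / |PETvol ∪ MRIvol|
  (Jaccard); **Dice** D = 2·CI/(1+CI). The best matching isocontour
  maximizes CI over levels.
- **Log-logistic AFT**: S(t|x) = 1/(1 + (t/α(x))^β), log α(x) = μ + xᵀθ;
  reported effect exp(−θ), oriented so values > 1 mean worse survival.
- **Optimal SUVmax cutoff**: the candidate split (midpoints of consecutive
  observed SUVmax values, ≥ `min_group` per side) minimizing the Wald
  p-value; the full p-trace is returned because the unadjusted minimum is
  anti-conservative.

## Worked example

```r
library(fetpet)

inj  <- injection_record(injected_activity_MBq = 180, body_weight_kg = 72,
                         injection_time = "2021-01-01T09:00:00",
                         acquisition_time = "2021-01-01T09:12:00")
spec <- phantom_spec(grid_shape = c(31, 31, 31), voxel_spacing_mm = c(1, 1, 1),
                     background_uptake = 1,
                     hotspots = list(list(center = c(16, 16, 16),
                                          sigma_mm = 5, amplitude = 9)),
                     noise_sd = 0.1, seed = 7)
ph  <- make_pet_phantom(spec, inj)
suv <- to_suv(ph$volume, inj)
roi <- pet_mask(array(TRUE, c(31, 31, 31)), c(1, 1, 1), role = "roi")

iso <- isocontours(suv, roi)
iso
#> <isocontour_set> SUVmax 3.999
#>   I40: 1.730 ml
#>   I50: 1.071 ml
#>   I60: 0.681 ml
#>   I70: 0.386 ml

mri <- make_target_mask(ph$volume, roi, level_pct = 40, target_ci = 0.31,
                        seed = 11)
best_matching_isocontour(iso, mri, patient = "phantom_01")
#> <concordance_table> phantom_01: best matching isocontour I40 (CI 0.310)
#>  level_pct petvol_ml mrivol_ml         ci      dice pct_increase is_best
#>         40     1.730      1.73 0.31010981 0.4734104     52.65896    TRUE
#>         50     1.071      1.73 0.22635727 0.3691539     32.02312   FALSE
#>         60     0.681      1.73 0.15580058 0.2695977     20.57803   FALSE
#>         70     0.386      1.73 0.09410548 0.1720227     11.79191   FALSE
```

The noise-free peak is background 1 + amplitude 9 = 10 kBq/ml, i.e. a true
SUVmax of 10/2.5 = 4.0 at 2.5 kBq/g dose-per-weight; the observed 3.999 is
the noisy voxel maximum. Isocontour volumes shrink with level, and the
planted conformity index 0.31 is recovered at the planted level 40.

Survival stratification on a synthetic cohort with a true cutoff at
SUVmax 3.0:

```r
cohort <- make_survival_cohort(n = 120, cutoff = 3, effect_log_scale = 0.8,
                               shape = 2, scale_base = 12, censor_rate = 0.2,
                               suv_range = c(1, 8), seed = 3)
scan_cutoffs(cohort, model = "loglogistic_aft", min_group = 5)
#> <cutoff_scan_result> loglogistic_aft: 111 candidates, optimal cutoff 3.02 (p = 1.71e-12), median 4.21
```

Here the scan lands next to the true cutoff; its precision is seed-dependent
(the minimum-p estimate concentrates only slowly with the effect size — see
the methods vignette), which is why the full per-cutoff p-trace is
returned rather than the optimum alone.

## Pipeline and command line

`run_pipeline(config, output_dir)` executes phantom → SUV → isocontours →
concordance → features → survival → transcriptome end-to-end from one JSON
configuration (see `inst/extdata/demo_config.json`), writing CSV tables
and a `manifest.json` with versions, seeds and MD5 hashes; identical
config and seed give byte-identical outputs. A thin CLI wrapper with
subcommands (`run`, `suv`, `contours`, `concord`, `survive`, `wbt`) is in
`inst/cli/fetpet.R`.

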