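# t2het

Quantifying **T2 heterogeneity** — the width of the distribution of T2
relaxation times within a brain region — from multi-echo MRI, and testing
its value as an early marker of microstructural change in ageing and
mild cognitive impairment.

## The problem

Quantitative T2 is sensitive to tissue microstructure, but early
neurodegenerative pathology pushes it in *both* directions: free water,
oedema and membrane breakdown prolong T2, while iron and dense protein
aggregates shorten it. Averaged over a region these effects can cancel,
leaving the mean ("midpoint") T2 unchanged even as tissue degrades. The
width of the regional T2 distribution should widen regardless of which
effect dominates locally, making it the more sensitive marker.

`t2het` implements that analysis end to end:

1. **T2 mapping** — voxelwise log-space mono-exponential fits to
   multi-echo series (CPMG 10-echo and TSE 3-echo presets; first-echo
   exclusion for CPMG): `compute_t2_map()`, `sum_of_echoes()`.
2. **ROI extraction** — capped, validity-filtered regional T2 samples
   ([30, 200] ms physiological window) and mask utilities:
   `extract_roi_samples()`, `combine_masks()`, `roi_volume()`.
3. **Distribution modelling** — maximum-likelihood fits of 18 candidate
   families with AIC selection; the log-logistic fit supplies the two
   biomarkers,
   `f(x | mu, sigma) = (1/sigma)(1/x) e^z / (1 + e^z)^2` with
   `z = (log x − mu)/sigma`: midpoint **T2mu** (log-median, log-ms) and
   heterogeneity **T2sigma** (shape): `fit_loglogistic_mle()`,
   `family_registry()`, `summarize_region()`.
4. **Cohort statistics** — per-study reference z-normalization, ANCOVA
   with age covariate (Type-III F, estimated marginal means,
   Sidak-corrected pairwise tests, Levene's test), follow-up-cognition
   regression with standardized betas, partial residuals, age
   regressions: `zscore_to_reference()`, `ancova_group()`,
   `followup_regression()`, `age_regression()`.
5. **Synthetic cohorts and phantoms** — log-logistic T2 fields in
   ellipsoidal ROIs, Rician-noise multi-echo images, demographics and
   longitudinal cognition with configurable group effects, so the whole
   chain is testable by parameter recovery without any imaging data:
   `cohort_spec()`, `render_t2_field()`, `simulate_multi_echo()`.

`run_pipeline()` chains the stages under one config with per-stage seeds,
checksummed outputs and incremental reruns. The numbered scripts in
`analysis/` are narrative drivers over the same functions and write their
tables to `results/`.

## Worked example

Simulate one subject's phantom at SNR 50, map T2, and recover the
regional distribution parameters:

```r
library(t2het)

truth   <- data.frame(region = "hippocampus", mu_true = 4.68, sigma_true = 0.112)
phantom <- phantom_spec(grid_shape = c(32, 32, 16), noise_sd = 20)  # SNR 50
field   <- render_t2_field(truth, phantom, seed = 1)
img     <- simulate_multi_echo(field$t2, phantom, seed = 2)
map     <- compute_t2_map(img)          # 10-echo train: first echo excluded
left    <- extract_roi_samples(map, field$masks$hippocampus$left,
                               region = "hippocampus", hemisphere = "left")
right   <- extract_roi_samples(map, field$masks$hippocampus$right,
                               region = "hippocampus", hemisphere = "right")
left
#> <ROI samples: hippocampus/left, n = 1010 kept (low 0, high 3, invalid 0), caps [30, 200] ms>
summarize_region(left, right, subject_id = "example")
#> <region T2 summary: example / NA>
#>   T2mu = 4.6772 log-ms (median 107.5 ms), T2sigma = 0.1163
#>   best family: loglogistic; hemispheres: left, right
```

The subject was generated with (mu, sigma) = (4.68, 0.112); after Rician
noise, voxelwise fitting and physiological capping, the refit recovers
(4.677, 0.116) from ~1000 voxels per hemisphere, and the AIC contest over
all 18 families picks the generating family. The heterogeneity estimate
runs slightly high at this ROI size because T2 estimation noise adds to
the true spread — the calibration experiments in the test suite quantify
this through the full pipeline.

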