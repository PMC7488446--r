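---
title: "Methods: modelling regional T2 heterogeneity from multi-echo MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling regional T2 heterogeneity from multi-echo MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(t2het)
```

## The measurement model

A multi-echo spin-echo acquisition samples the transverse-magnetization
decay of each voxel at a train of echo times. Under mono-exponential decay
the signal is

$$S(TE) = S_0 \, e^{-TE/T_2},$$

so regressing $\log S$ on $TE$ by unweighted least squares gives
$T_2 = -1/\mathrm{slope}$ per voxel (`log_linear_fit()`,
`compute_t2_map()`). Two acquisition presets are built in: a 10-echo CPMG
train (TE 12–120 ms in 12 ms steps) and a 3-echo TSE variant (TE 9.1, 72,
136 ms). For CPMG-like trains the first echo is excluded by default: its
signal pathway differs from the later echoes (stimulated-echo
contamination), which biases the log-linear fit. For short trains there is
no established convention; the package defaults to keeping all echoes when
fewer than ten are present and exposes `exclude_first` everywhere.

Voxels with a non-positive signal at any used echo, a non-negative fitted
slope, or fewer than two usable echoes are flagged invalid rather than
erroring; invalid voxels never reach the distribution fits. Nonpositive
signals invalidate the voxel (rather than dropping the echo) because a
partially observed echo train no longer estimates the same decay.

## The heterogeneity model

Within a region of interest, voxel T2 values are treated as draws from a
log-logistic distribution

$$f(x \mid \mu, \sigma) = \frac{1}{\sigma}\frac{1}{x}
  \frac{e^z}{(1+e^z)^2}, \qquad z = \frac{\log x - \mu}{\sigma},$$

whose log-median $\mu$ (log-ms) is the *midpoint* (T2$\mu$) and whose shape
$\sigma$ is the *heterogeneity* (T2$\sigma$) — the width of the subject's
regional T2 distribution. The scientific motivation is that early
neurodegenerative pathology mixes T2-prolonging processes (free water,
membrane breakdown) with T2-shortening ones (iron, dense protein
aggregates), so the distribution widens before its centre moves.

Fitting is by maximum likelihood on the raw voxel samples
(`fit_loglogistic_mle()`): BFGS on $(\mu, \log\sigma)$ with analytic
gradient, initialized at $\mu_0 = \mathrm{median}(\log x)$ and
$\sigma_0 = \mathrm{IQR}(\log x) / (2\ln 3)$ (the logistic quartile
identity), objective tolerance $10^{-8}$, at most 500 iterations.
Optimizing $\log\sigma$ enforces positivity. Zero-spread samples are
returned as degenerate, non-converged fits rather than errors. We fit raw
samples, not histogram bins: binning is presentational and discards
information.

Samples are restricted to the physiological window [30, 200] ms before
fitting: outside it, values reflect fit failure, CSF partial volume or
noise rather than tissue. *Capping* is implemented as exclusion
(truncation), not clipping — clipping would pile point masses on the
boundaries and corrupt the MLE. Boundary values are kept (closed
interval); this choice is arbitrary but fixed. No truncation correction is
applied to the likelihood (the untruncated family is fitted to the
truncated sample). This mirrors the conventional procedure but biases
$\hat\sigma$ slightly downward, more so for wider distributions — the
effect-recovery experiment quantifies the consequence (see below).

### Model selection

Eighteen candidate families are fitted per hemisphere and compared by AIC
($2k - 2\ell$; `family_registry()`, `select_best()`): log-logistic,
log-normal, logistic, normal, gamma, Weibull, exponential, Rayleigh,
inverse Gaussian, Birnbaum–Saunders, generalized extreme value,
generalized Pareto, Nakagami, Rician, t location-scale, uniform,
half-normal and beta-prime — a catalogue matching general-purpose
distribution-fitting tools. Closed-form MLEs are used where they exist;
the rest are numeric. Ties break toward fewer parameters, then registry
order. The modal winner across subjects and hemispheres
(`modal_best_family()`) documents which family describes the data best;
the reported metrics are always the log-logistic parameters, so the
headline analysis does not depend on the contest's outcome.

Hemispheres are fitted separately and combined by unweighted parameter
averaging (`summarize_region()`); voxel-count weighting and pooled-sample
fitting are available as options. Averaging was chosen as the default
because it is insensitive to hemisphere-size imbalance from mask
asymmetries.

## Cohort statistics

Metrics are z-scored to each study's reference (healthy-control) group —
mean and sample SD ($n-1$) within study, then pooled — so the reference
group has mean 0, SD 1 by construction (`zscore_to_reference()`). Group
comparisons use ANCOVA with age as the covariate (`ancova_group()`):
sum-to-zero group coding, Type-III F for the group factor from the
nested-model RSS comparison, estimated marginal means at the grand
covariate mean, pairwise t tests on the EMMs with pooled error variance
and Sidak correction ($p' = 1-(1-p)^m$, $m = 3$ group pairs), and classic
Levene's test (mean centre; Brown–Forsythe optional). Education, study and
sex are accepted as covariates but off by default, matching the reported
models. Pairwise tests use the pooled-variance form; Welch-type pairwise
tests under Sidak would be a defensible alternative but the pooled form is
what EMM-based contrasts imply.

Prediction of cognitive decline uses OLS of follow-up cognition on age,
baseline cognition and one structural marker in the MCI follow-up
subsample, with every variable standardized, reporting $R^2$, overall
$F(3, n-4)$ and standardized betas (`followup_regression()`). Which
variables the conventional "standardized beta" standardizes is ambiguous
in practice; standardizing all of them is the interpretation used here.
Added-variable structure is exposed via `partial_residuals()`
(Frisch–Waugh residual-on-residual pairs, standardized to SD 1). Age
associations in controls use simple OLS with two-tailed p
(`age_regression()`). ICV correction defaults to the ratio method, with
the regression-residual method as an option.

## The synthetic cohort and phantom generator

No imaging data ship with the package, so every stage is validated against
a generator that encodes the structure the analysis assumes:

* **Demographics** (`cohort_spec()`, `generate_cohort_table()`): default
  group sizes 97/49/10 (HC/MCI/AD), ages 69.3 ± 8.58, 72.2 ± 9.03,
  77.9 ± 9.94 years (truncated to [40, 100] by redraw), sex ratios
  46:51, 27:22, 2:8, two studies with the AD group in study 1 only.
* **Regional truth** (`region_params()`, `sample_subject_t2_params()`):
  $\mu$ and $\sigma$ are deterministic linear functions of group and age,
  centred at age 70 — baseline $\mu_0 = 4.68$, $\sigma_0 = 0.113$ with a
  $+0.001$/yr heterogeneity slope, so a 69-year-old control has
  $(\mu, \sigma) = (4.68, 0.112)$, matching the worked example the fits
  are tested against. Default offsets: MCI widens $\sigma$ by $0.02$; AD
  raises $\mu$ by $0.03$ (heterogeneity first, midpoint later — the
  pattern the marker is designed to detect). Determinism given (group,
  age) is deliberate: injected effects then equal group-mean differences
  *exactly*, which the effect-injection tests exploit. Idiosyncratic
  between-subject variation is represented at the observation level
  (`simulate_cohort_metrics()`, defaults $0.03$ for $\mu$, $0.023$ for
  $\sigma$, sized so the age trend explains roughly a tenth of the
  control-group heterogeneity variance). The volume-age slope defaults to
  zero and its sign is configurable — reported cohort estimates of that
  sign are contradictory, and the analysis does not depend on it.
* **Phantoms** (`phantom_spec()`, `render_t2_field()`,
  `simulate_multi_echo()`): in-ROI voxels draw T2 from the subject's
  log-logistic law by inverse CDF ($x = e^{\mu + \sigma\log(u/(1-u))}$,
  exact and seedable), redrawing outside (1, 1000) ms to avoid boundary
  point masses; ROIs are paired disjoint ellipsoids (the analysis is
  shape-agnostic, so anatomical realism buys nothing); background voxels
  take a fixed T2. Noise is Rician by default — magnitude MRI physics:
  $|S + n_1 + i\,n_2|$ with independent Gaussian channels — with Gaussian
  and noiseless modes for oracle tests. Default SNR $s_0/\mathrm{noise}$
  is 50.
* **Cognition** (`simulate_cognition()`): baseline is a group mean plus
  age trend and noise (group means 0, −4.08, −8.50 in HC-referenced
  units); follow-up is exactly linear in age, baseline and true regional
  $\sigma$, with configurable coefficients ($\beta_\sigma = -30$ per unit
  $\sigma$ by default, i.e. about $-0.6$ test units per 0.02 of
  heterogeneity) plus Gaussian error (SD 1).

What the generator does *not* emulate: anatomy, partial-volume mixing,
slice gaps, motion, reconstruction artefacts, or non-mono-exponential
decay (myelin water, exchange). Passing tests therefore demonstrate that
the estimation chain is correct and well calibrated *under its own
assumptions*, not that those assumptions hold in any given acquisition.

## Numerical choices and degenerate inputs

* Log-density of the log-logistic is computed via a softplus form,
  finite from $10^{-12}$ to $10^{12}$ ms.
* All generators are pure functions of (spec, seed); pipeline stages
  derive their seeds deterministically from one root seed.
* Empty masks, empty cohorts, zero-reference-SD studies, constant
  samples, rank-deficient designs and sub-minimal sample sizes all have
  defined behaviour (error or flagged degenerate fit), exercised in the
  test suite.
* The pipeline (`run_pipeline()`) caches stages by config-section hash
  and output checksums, so reruns are incremental and reproducibility is
  auditable from the manifest.

## Calibration experiments and problem sizes

The test suite runs four simulation studies, sized to be informative while
keeping a full run in minutes:

* **Parameter recovery**: $10^5$ draws at the two worked-example parameter
  pairs, refit by MLE (tolerances ±0.01 on $\mu$, ±0.005 on $\sigma$);
  consistency checked at $n = 10^2, 10^3, 10^4$ with 50 seeds each.
* **Model selection**: 100 seeded replicates of $n = 5000$ samples against
  distinguishable competitors; the generating family must win at least 95.
* **Type-I error**: 2000 null cohorts (all group deltas zero) at the
  subject level; the age-adjusted group F on heterogeneity must reject at
  5% ± 2%. This runs on the measured metric directly: z-normalizing to an
  *estimated* per-study reference first induces within-study dependence
  (the reference mean and SD are shared noise, and the AD group sits in
  one study only) that inflates the pooled ANCOVA's null rejection rate to
  roughly 11% under these conditions — a property of the published
  normalize-then-pool procedure worth knowing when interpreting borderline
  group effects.
* **Effect recovery**: 200 replicates of a 97 + 49 cohort with an injected
  MCI heterogeneity offset of 0.02, each subject measured through the full
  voxel pipeline (3000-voxel ROIs, 10-echo train, Rician SNR 50, caps,
  MLE). Detection power must reach 80% (empirically it is essentially
  100%), and the mean recovered group difference must land within 15% of
  the injected 0.02. The recovered raw difference runs a few percent low:
  cap truncation shrinks $\hat\sigma$ differentially for the wider MCI
  distributions, partially offset by the MCI group's older ages under the
  positive heterogeneity-age slope. The age-adjusted (EMM) difference
  isolates the truncation shrinkage alone.

## Known limitations

* Mono-exponential decay ignores multi-compartment T2 (myelin water) and
  stimulated-echo corrections; the estimator is the field-standard
  log-linear fit, not an EPG model.
* The untruncated-likelihood-on-truncated-sample convention biases
  $\hat\sigma$ downward by a few percent at default settings.
* Unweighted log-space OLS over-weights late, low-SNR echoes relative to
  an SNR-weighted fit.
* Hemisphere averaging, ratio ICV correction and all-variable
  standardization are conventions; the alternatives are implemented and
  selectable where the choice could matter.
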