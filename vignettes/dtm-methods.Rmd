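---
title: "Models and methods behind ebfdtm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ebfdtm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebfdtm)
```

This vignette documents the scientific and numerical choices inside
`ebfdtm`: the kinetic model, the priors and their truncation, the MCMC
machinery, the synthetic-cohort generator, and the design-search
conventions. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The linked one-compartment model

The dose-to-mother (DTM) technique administers a single oral dose of
deuterium oxide to the mother and follows saliva enrichment (mg D2O per
kg body water, above the pre-dose baseline) in mother and infant. We model
the pair as two linked well-mixed water pools:

* the mother eliminates D2O monoexponentially with rate constant `k_mm`
  (1/day) from her body-water volume `V_m` (kg); oral absorption is fast
  relative to the days-long sampling grid and is treated as instantaneous;
* the infant receives D2O only through breastmilk, at water clearance
  `CL_mb` (kg/day) acting on the maternal concentration, and eliminates it
  with rate constant `k_bb = CL_bo / V_b`, where `CL_bo` (kg/day) is the
  infant's total water clearance and `V_b` its body-water volume.

`V_b` is not fitted: infant total body water is close to 60% of weight, so
`V_b = 0.60 x` the mean of the study start/end weights (both the fraction
and the reference-weight choice are arguments). The resulting infant curve
is the classic two-exponential profile with a removable singularity at
`k_bb = k_mm`; the implementation switches to the analytic limit
`t exp(-k_mm t)` when `|k_bb - k_mm| < 1e-8` per day, and the tests verify
the two branches agree to relative error `1e-6` across the switch.

Non-milk water intake follows from a steady-state balance over the infant
pool — inflows (milk `CL_mb`, atmospheric absorption `R_a`, other sources
`Rs`) equal outflow `CL_bo` plus water retained in new tissue `R_g`:

    Rs = 1000 (CL_bo - CL_mb) + R_g - R_a     [g/day]

The factor 1000 converts kg of water to grams; negative `Rs` is reported
as-is and read as "effectively zero other-source intake". The two
ancillary rates are design-independent random inputs: by default `R_a` is
6.3% of the infant's water turnover and `R_g` is 73% (the water fraction
of tissue) of the observed weight change per day. In the classifier's
posterior-predictive step `R_a` is drawn log-normally (CV 0.25) around a
*size-based* turnover proxy (0.25/day per kg body water times `V_b`) and
`R_g` normally (SD 15 g/day) around the weight-change value. Sizing `R_a`
from the infant's size rather than from each `CL_bo` draw keeps the
ancillary draws independent of the design-dependent parameters, so their
dispersion — the floor on the dispersion of `Rs` no design can beat —
propagates into every Rs posterior, and `Rs` remains exactly linear in
the parameter draws.

## Residual error and priors

Observations carry combined error, `var(y | f) = f^2 s1^2 + s2^2`, with a
proportional and an additive component per assay group (isotope-ratio
mass spectrometry, IRMS, is more precise than Fourier-transform infrared
spectrometry, FTIR). An additive-only variant is available.

Three named prior regimes cover the four log-scale parameters
(`ln k_mm`, `ln V_m`, `ln CL_mb`, `ln CL_bo`), each specifying a normal
prior on the population typical value and a zero-truncated normal prior
on the between-subject SD (BSV):

* `low_information`: SD 1000 everywhere — the data drive everything;
* `informative`: tight on all four (typical values and BSVs);
* `mixed` (default): informative on `ln V_m` (3.45, SD 0.01; BSV 0.15,
  SD 0.01) and `ln k_mm` (−2.18, SD 0.01; BSV 0.18, SD 0.01), diffuse
  (0, SD 1000) on both clearances. The rationale: `V_m` and `k_mm` do not
  enter `Rs`, so pinning them lets a sparse design spend its information
  on the clearances that do.

For a pair fitted on its own, the individual-level prior is the
typical-value prior widened by the BSV: SD `sqrt(tv_sd^2 + bsv^2)`.

**Physiological truncation.** A normal prior with SD 1000 on a log scale
is only nominally proper. Late-sample designs admit a likelihood ridge on
which `CL_mb` and `CL_bo` grow together with their ratio fixed and the
infant curve unchanged; under an untruncated SD-1000 prior that ridge has
essentially unbounded extent and can dominate the posterior. The sampler
therefore restricts the support to coarse physiology
(`param_bounds()`: `k_mm` 0.02–0.7/day, `V_m` 10–100 kg, `CL_mb`
0.005–5 kg/day, `CL_bo` 0.01–5 kg/day — an infant cannot clear five
kilograms of water a day, a mother's body water is neither 5 nor 200 kg).
These bounds are far outside any plausible estimate and are arguments,
not constants.

## Samplers

The likelihood is a closed form, so no ODE solver is needed at run time;
the tests check the closed forms against adaptive ODE integration
(deSolve) to relative error below `1e-6` over a 100-point parameter grid
spanning the demographic ranges.

`fit_pair()` runs adaptive-covariance random-walk Metropolis per chain
(default 3 chains, 1000 warmup + 1000 kept draws): a global step size
tuned toward 30% acceptance by Robbins–Monro, and a proposal covariance
adapted Haario-style from the warmup trajectory. Starting values are
data-driven (terminal-slope regression for `k_mm`, first maternal sample
for `V_m`) with per-chain jitter of SD 0.4 on the log scale, so chains are
genuinely overdispersed. The contract is distributional, not algorithmic:
any sampler producing the same posterior would do.

`fit_population()` is Metropolis-within-Gibbs on the hierarchical model
(individual log-parameters normal around covariate-dependent population
means with BSV SDs `omega`; group-specific residual sigmas):

* per-pair block Metropolis updates of the four individual parameters
  (compiled; several sweeps per Gibbs iteration), with a *per-pair*
  proposal Cholesky factor adapted from the warmup trajectory — an
  isotropic proposal mixes far too slowly for pairs whose
  clearance posterior is an elongated ridge;
* exact conjugate normal draws for the covariate coefficient vectors;
* log-scale Metropolis for `omega` and the sigmas with adapted step sizes;
* two interweaving moves per parameter and iteration that are essential on
  sparse designs: a *recentering* move shifting an intercept and every
  pair's parameter jointly (the typical value and the individuals are
  strongly coupled in the centered parameterisation), and a *rescaling*
  move multiplying a BSV SD and all individual deviations by a common
  factor (with the exact Jacobian), which lets chains climb out of the
  `omega -> 0` funnel.

Convergence is gated per parameter by the classic multi-chain
Gelman–Rubin statistic with threshold `Rhat < 1.05`; the classic (rather
than split) form is used so that bit-identical chains score exactly 1.
A pair fails the stability flag if any of its four parameters fails the
gate; in design evaluation such pairs are excluded from the confusion
counts and reported through `stable_fraction` rather than being given a
label.

## Covariate models

Continuous covariates enter log-linearly,
`ln(theta_i) = ln(theta1) + theta2 ln(cov_i / cov_ref)`, and categorical
ones as `ln(theta_i) = ln(theta1) + cov_i ln(theta2)` with 0/1 coding.
The defaults tie mother weight to `V_m` and infant weight to `CL_bo`. The
reference covariate values default to the synthetic population's medians
(57 kg, 6.4 kg): the intercept is the typical value *at the reference*,
so when a prior regime pins a typical value the reference must be the
population's own centre for prior and data to cohere — centring at a
different weight silently re-interprets the informative prior and pushes
the conflict into the residual sigmas.

## The synthetic cohort

`generate_cohort()` emulates a multi-country DTM field study:

* anthropometrics are log-normal, matched to typical field medians and
  interquartile ranges (mother 57 kg, infant 6.3 kg at entry gaining
  ~0.2 kg over two weeks, age ~3.4 months); positive skewed quantities
  call for log-normal forms;
* a third of pairs are assayed by IRMS with doses below 30 g, the rest by
  FTIR with doses of 30 g or more (dose pools are arguments);
* individual parameters follow the covariate models above with normal
  log-scale BSV (defaults: 0.18 for `k_mm`, 0.15 for `V_m`, 0.15 for
  `CL_bo`); `CL_mb` inherits its dispersion from `CL_bo` and the target
  `Rs` through the water balance;
* true class is built in: EBF pairs draw a small true `Rs` (mean 15,
  SD 20 g/day, capped safely below the cutoff); non-EBF pairs receive a
  *milk-clearance deficit* solving the balance for `Rs` = cutoff + a
  log-normal margin (median 150 g/day, sdlog 0.5) — supplementation
  displaces breastmilk. The alternative mechanism (`clbo_inflate`) raises
  the infant's total clearance instead. A token milk flow of at least 5%
  of `CL_bo` is kept so heavily supplemented infants remain physiological;
  `true_rs` is recomputed after that floor so truth stays self-consistent;
* residual noise is combined-error with sigmas chosen from assay-precision
  reasoning (IRMS 4% + 1.5 mg/kg; FTIR 8% + 3 mg/kg; none are printed in
  the source material);
* records can be dropped missing-completely-at-random per day, and the
  country-stratified `split_cohort()` reproduces the model-building /
  design-evaluation split, with the calibration country exempt from
  holdout.

What the generator does *not* emulate: assay drift and inter-laboratory
calibration, circadian water flux, real dropout mechanisms that correlate
with visit burden, and any misspecification of the kinetic model itself —
the data are generated by the same closed forms the fit assumes. Passing
tests therefore demonstrate internal consistency of the pipeline and the
sampling-design logic, not robustness to model error in real field data.

## Design search conventions

Streamlined family A is any subset of the grid days (default 1–9, 13, 14)
with one to three paired samples. Family B (limited duration) is read as:
sampling window spanning at most `max_span` consecutive days (default 7)
*and* last sample no later than day 9 — the two constraints are combined
because duration-limited short protocols are meant to finish within the
first study week. Both bounds are arguments. Designs are enumerated
exhaustively in deterministic lexicographic order and labelled with the
"+"-joined notation (`"7+13"`).

Evaluation of a design: build the streamlined data set by resampling
pairs with replacement from the posterior-mean-imputed, fully balanced
table (duplicates get distinct working ids and keep their source
linkage), keep only the design's days, refit, classify, and score against
the reference classification — which is always computed from the
*un-imputed* full-design data, so imputation never touches the gold
standard. By default the refit is the hierarchical population model:
with one to three samples per pair the individual clearances are only
weakly identified on their own, and it is the population model — with the
regime's priors on typical values and BSVs — that keeps individual Rs
posteriors tight enough to classify; fully independent per-pair refits
remain available (`method = "independent"`). Residual sigmas are held
fixed during streamlined refits (normally at the reference fit's
estimates, see `estimated_residual()`): a two-point design carries almost
no information about the error model, and letting the sigmas drift only
destabilises the chains. Each design is evaluated once by default; an
`n_boot` argument reports the median over several bootstrap replicates
when damping bootstrap-composition noise matters.

`rank_and_validate()` lays the two data halves side by side with
`diff = evaluation - best` for both rates and sorts by the model-building
`min(sensitivity, specificity)`.

`information_profile()` defines the single-sample information density of
each clearance as the (analytic) partial derivative of the infant curve,
normalised to unit maximum; the `CL_mb` profile is proportional to the
curve itself because the curve is linear in `CL_mb`. Weighting by the
residual SD was considered and rejected: under combined error it pushes
the `CL_bo` argmax onto the grid boundary, which contradicts the premise
of an interior optimum.

## Problem sizes and numerical conventions

The test-suite and acceptance script run at desk scale by design: single
pairs and 4–100-pair cohorts, 2–3 chains of 400–1000 kept draws, a
60-pair cohort with ~33% non-EBF for the end-to-end design comparison,
and 10 replicates for the covariate-recovery coverage check. These sizes
were chosen so the full pipeline exercises every code path in minutes on
one core while keeping Monte-Carlo error well inside the asserted bands.

Boundary conventions: the classification threshold is strict
(`Pr = 0.9` exactly gives EBF), following the published rule's inequality;
the `>=` reading is available via `classifier_config(strict = FALSE)`.
The clearance-outlier rule is also strict (`CL_bo` exactly 40% of body
weight is retained) with a `1e-12`-relative guard against floating-point
ties. All randomness flows from a single integer seed through a
documented deterministic derivation (`seed * 7919 + k * 104729` modulo
`2^31 - 1`), so every stage is reproducible and independently seedable.

## Known limitations

* The structural model ignores isotope fractionation, exchangeable
  hydrogen pools, and delayed maternal absorption.
* Per-pair residual sigmas are never estimated from a single pair's data;
  they are population quantities.
* Rs posteriors from two-sample designs remain ridge-limited: designs
  whose samples all sit on the terminal phase cannot distinguish a fast
  infant turnover from a proportional rise in both clearances, which is
  exactly why chain-stability gating and the mixed prior matter.
* The hierarchical refit shares information across pairs; a cohort whose
  non-EBF pairs are few or extreme can shrink them toward the EBF
  majority, trading sensitivity near the cutoff — visible in the
  bootstrap-to-bootstrap spread of the operating characteristics.
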