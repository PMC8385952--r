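---
title: "Simulating exposure measurement error in two-pollutant mortality time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating exposure measurement error in two-pollutant mortality time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short-term air-pollution epidemiology regresses daily death counts on daily
ambient concentrations. Ambient monitors are an error-prone proxy for
personal exposure to outdoor-generated pollution, and when two correlated,
differently-mismeasured pollutants (here PM2.5 and NO2) enter the same
quasi-Poisson model, measurement error does two things at once: it
attenuates coefficients, and it *transfers* effect from the noisier
covariate to the cleaner one. `pollerrsim` implements a factorial
simulation study of this mechanism, with closed-form oracles that predict
the simulated biases independently.

## Data-generating model

**True exposures.** Each scenario draws `n_days = 1461` i.i.d. days of
`(A_NO2, A_PM2.5)` from a bivariate lognormal. Scenario inputs are
*natural-scale* means, SDs and correlation; `natural_to_log_params()`
converts them with the exact moment identities
`sigma_log^2 = log(1 + sd^2/mean^2)`,
`cov_log = log(1 + rho sd1 sd2/(mean1 mean2))`,
`mu_log = log(mean) - sigma_log^2/2` (computed with `log1p` so the
near-degenerate small-SD limit stays accurate). Three built-in areas span
different true-variance/error-variance ratios; Europe (PM2.5 21.1 ± 10.9
µg/m³, NO2 21.6 ± 8.9 ppb) has the least favourable ratio for NO2. The
series is deliberately free of autocorrelation, trend, seasonality and
confounders: the study isolates measurement-error bias, so anything else
that biases real time-series analyses is excluded by construction.

**Error structures.** Error SDs are level multipliers (0.1, 0.5, 1, 1.3)
on each area's "moderate" SD, and the two pollutants' daily errors are
drawn with cross-correlation `rho_error`. Because no empirical estimate of
the correlation between the two exposures' errors is available, the
default ties `rho_error` to the exposure correlation of the scenario — a
conservative interpolation — and every function accepts an explicit value.

- *Classical* (`C = A + delta`): independent additive noise; the textbook
  attenuating case.
- *Berkson*: the generator shrinks the true series toward its mean by the
  best-linear-predictor factor `lambda = sigma_C^2/(sigma_C^2 +
  sigma_delta^2)` and adds independent noise. Two variants are provided
  because the shrinkage formula in circulation sets `Var(delta*) =
  sigma_C^2 sigma_delta^2 / (sigma_C^2 + sigma_delta^2)`, which does *not*
  satisfy the defining Berkson condition `Cov(C, A - C) = 0`; the `strict`
  variant rescales `Var(delta*) = lambda (1 - lambda) sigma_A^2` so the
  condition holds exactly. `as_printed` is kept as the default for
  continuity with that formula, but only the strict variant behaves like
  Berkson error in the regressions (near-unbiased coefficients), and the
  package's Berkson-level acceptance checks use it for that reason.
- *Mixture*: a latent series `L` with `A = L + delta_b` and
  `C = L + delta_c`; the classical share of the total error variance is
  0.43 for PM2.5 and 0.33 for NO2 by default. `L` is a linear transform of
  the simulated lognormal chosen so `Cov(L) = Sigma_A - Sigma_delta_b`
  exactly, hence the *realized* true exposures keep the full scenario
  covariance (means, variances and cross-covariance). In two of the 144
  default cells (correlation 0.75, very-low PM error, high NO2 error) no
  such latent law exists; there the latent correlation is capped at the
  positive-definiteness boundary (0.999) and the realized exposure
  correlation falls slightly below nominal — preferable to silently
  redistributing variance in all other cells.
- *Multiplicative* (`C = A · eps`, mean-one lognormal `eps`): no canonical
  calibration of a constant-percent error exists, so it is configurable.
  The default matches the natural-scale SD of `C - A` to the scenario
  error SD at the exposure mean; the alternative `log_sd` calibration
  reads the natural-unit SD directly as a log-scale SD, an extreme
  contamination that almost eliminates the exposure signal.

Errors are i.i.d. across days (constant misclassification), and negative
`C` values under natural-scale additive error are retained: truncation
would distort the error moments, and the log-*link* regression uses
exposure as a linear covariate, so negative values are admissible. The
`additive_log` mode applies each construction on the log scale instead
(with variances calibrated so natural-scale error SDs match at the mean);
it is provided because percent-type errors are plausible for
concentration data, but the natural-scale mode is the default since the
scenario error SDs are specified in natural units.

**Mortality.** `log mu_t = beta_0 + beta_NO2 A_NO2 + beta_PM A_PM` with
defaults `beta_NO2 = 6e-4` per ppb and `beta_PM = 5.4e-4` per µg/m³
(≈ 0.6% and 0.54% excess mortality per 10 units — meta-analytic
magnitudes for all-cause mortality). Counts are negative binomial with
`theta = mu/(phi - 1)`, the unique size giving `Var(Y) = phi mu`, i.e.
exactly the quasi-Poisson variance the estimation model assumes
(`phi = 1.3`). The sometimes-quoted `theta = phi/(mu - 1)` is selectable
(`nb_theta = "printed"`) but produces variance far above `phi mu` at
realistic means and is not used. `beta_0` is calibrated so expected daily
deaths at mean exposure equal 130 (a plausible large-conurbation count);
relative bias, coverage and power are first-order invariant to it.
Crucially, mortality is generated from the *true* series only — under
mixture error, from the redefined `A = L + delta_b`.

## Estimation and summaries

`fit_quasipoisson()` is Poisson IRLS (via `stats::glm.fit`) with Pearson
dispersion scaling of the standard errors and Wald intervals
(`coef ± 1.96 se`) — the standard meaning of "allowing for
overdispersion" in this literature; it matches `glm(family =
quasipoisson())` to numerical precision (verified in the tests). Each
replicate gets up to six fits: {two-pollutant, single-NO2, single-PM} ×
{true, error-prone}, all on the same counts. Non-converged fits are
excluded from aggregation with their count reported in the run manifest.

Summaries per scenario: mean coefficient ×10⁴, the mean model-based SE
(SE_W), the SD of estimates across replicates (SE_B), relative bias
`100 (mean beta-hat − beta)/beta` (undefined when the generating
coefficient is zero — the estimate itself is still reported), 95% CI
coverage of the generating value, and power at the 5% level. Pooling
across scenarios is replicate-weighted (identical to scenario-weighting
when replicate counts are equal, which the design guarantees); SE_B pools
by exact moment reconstruction. On correctly specified error-free fits
SE_W and SE_B agree within sampling noise, and coverage sits at 95% — both
are enforced in the test suite. Absolute SE magnitudes scale with the
baseline death count and overdispersion, so only their internal
consistency (not any particular printed magnitude) is meaningful here.

## Analytic oracles

For classical error the two-pollutant estimates converge to
`lambda beta` with reliability matrix `lambda = (Sigma_A +
Sigma_delta)^-1 Sigma_A`; its off-diagonal terms are the effect transfer.
Single-pollutant limits are `(Sigma_A beta)_i / (Sigma_A[i,i] +
Sigma_delta[i,i])`, and with no error at all the omitted-variable formula
`beta_i + beta_j Cov(A_j, A_i)/Var(A_i)` applies. The mixture case reduces
to the classical formula applied to `(Sigma_L, Sigma_delta_c)` because the
Berkson component is independent of `C`. These are linear-model limits
evaluated on the natural-scale lognormal covariances; with coefficients of
order 1e-3 per unit the log-link fit is locally linear and the tests
verify Monte-Carlo/oracle agreement within three empirical SEs. Note the
reliability matrix *premultiplies* the coefficient vector: transfer flows
from the noisier covariate toward the cleaner one, which the
errors-in-variables regression test checks explicitly.

## Reproducibility

Every replicate's seed is a pure integer hash of
`(master_seed, scenario_id, rep)`, so scenarios can be run in any order or
subset with bit-identical results; the run manifest records everything
needed to reproduce a run, and the test suite asserts byte-level equality
of repeated and reordered runs.

## Problem sizes

Defaults follow the full study design (1461 days, 1000 replicates,
144 scenarios). The test suite and the acceptance script scale replicates
down — 12–150 per scenario depending on the precision each check needs,
chosen so pooled Monte-Carlo standard errors stay well inside the stated
tolerances — and state the sizes in-line. A full 144 × 1000 mixture run is
a few hours on one CPU; `run_experiment(reps = ...)` scales linearly.

## Known limitations and open choices

- The correlation between the two pollutants' *errors* is not empirically
  identified; results for mixture and classical error move by several bias
  points across plausible `rho_error` values, which is why it is a
  first-class knob.
- The multiplicative-error magnitude is calibration-dependent by an order
  of magnitude; only qualitative statements (severe attenuation under
  aggressive calibrations) are robust.
- Single-pollutant inflation on error-free data is, by the
  omitted-variable formula, proportional to the exposure correlation and
  SD ratio; pooled over this grid (mean correlation 0.5) it is ≈ +65% for
  PM2.5, roughly twice some published reference magnitudes for comparable
  designs — those are consistent with an effective exposure correlation
  near 0.28, not with this grid's declared levels. The package follows its
  declared inputs and reports the discrepancy rather than recalibrating
  toward any particular published figure.
- The generator omits autocorrelation, seasonality, confounding,
  spatially-resolved error and >2 pollutants; passing tests therefore
  demonstrate the measurement-error mechanism in isolation, not the full
  error budget of a real time-series analysis.
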