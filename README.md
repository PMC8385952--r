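# pollerrsim

Monte-Carlo machinery for quantifying how exposure **measurement error**
biases **two-pollutant time-series mortality models** — the workhorse design
of short-term air-pollution epidemiology, where daily death counts are
regressed on daily PM2.5 and NO2 concentrations with an overdispersed
(quasi-)Poisson log-linear model.

Ambient monitors measure neither pollutant perfectly. When *both* error-prone
exposures enter the same regression, the bias is no longer simple
attenuation: part of the effect of the pollutant measured with more error
(typically NO2) is re-attributed to the better-measured co-pollutant
(**effect transfer**), which confounds any attempt to rank pollutants for
policy. `pollerrsim` simulates this mechanism end to end and quantifies the
resulting relative bias, confidence-interval coverage and power under a
factorial grid of plausible error scenarios.

## The model

For day *t* = 1, …, 1461 the package generates:

1. **True exposures** `A_t = (A_NO2, A_PM2.5)` from a bivariate lognormal
   with natural-scale means, SDs and correlation `rho` taken from one of
   three study areas (Europe, Eastern/Western North America), moment-matched
   exactly on the log scale.
2. **Error-prone exposures** `C_t` under one of four error structures:
   - *classical*: `C = A + delta`, `delta ⊥ A`;
   - *Berkson*: `C = mu_A + lambda (A − mu_A) + delta*` (best-linear-predictor
     shrinkage; a `strict` variant enforces `Cov(C, A − C) = 0` exactly);
   - *mixture*: a latent series `L` with `A = L + delta_b` (Berkson share)
     and `C = L + delta_c` (classical share: 43% for PM2.5, 33% for NO2 by
     default);
   - *multiplicative*: `C = A · eps`, `eps` mean-one lognormal.
   Error SDs per pollutant are level multipliers (0.1 / 0.5 / 1 / 1.3) on the
   area's "moderate" SD; the two pollutants' errors are correlated
   (`rho_error`, defaulting to the exposure correlation).
3. **Mortality** `Y_t ~ NB(mu_t, theta)` with
   `log mu_t = beta_0 + beta_NO2 A_NO2 + beta_PM A_PM` (defaults
   `beta_NO2 = 6e-4` per ppb, `beta_PM = 5.4e-4` per µg/m³) and
   `theta = mu/(phi − 1)` so that `Var(Y) = phi·mu` (`phi = 1.3`).

Single- and two-pollutant quasi-Poisson models are then fitted to the same
counts using the true and the error-prone series, and per-scenario
Monte-Carlo summaries (mean coefficient ×10⁴, model-based SE\_W, empirical
SE\_B, relative bias %, 95% coverage, power) are pooled across the
144-scenario grid (3 areas × 3 correlations × 4 × 4 error levels).

A closed-form **attenuation oracle** `lambda = (Sigma_A + Sigma_delta)⁻¹
Sigma_A` (probability limit `lambda · beta`) and the **omitted-variable-bias**
formula validate the pipeline independently in the test suite.

## Worked example

The core scenario: Europe, moderate exposure correlation (0.5), moderate
error SDs (5.2 µg/m³ PM2.5, 6.2 ppb NO2), additive mixture error,
200 replicates:

```r
library(pollerrsim)

grid <- build_grid(list(areas = "europe", rho_exposure = 0.5,
                        err_levels_pm = 1, err_levels_no2 = 1))
run <- run_experiment(grid, master_seed = 1, reps = 200)
s <- run$summaries
s[s$model_kind == "multi", c("exposure_source", "pollutant", "mean_coef",
                             "se_w", "se_b", "bias_pct", "coverage_pct",
                             "power_pct")]
#>   exposure_source pollutant mean_coef se_w se_b bias_pct coverage_pct power_pct
#> 1     error_prone       no2      4.71 3.74 3.60  -21.458         93.0      22.5
#> 2     error_prone      pm25      5.02 2.83 2.78   -7.019         96.0      45.0
#> 3            true       no2      6.01 3.39 3.25    0.123         96.5      47.0
#> 4            true      pm25      5.34 2.76 2.94   -1.057         93.5      49.5
```

On the true exposures both coefficients are recovered (bias ≈ 0, ~95%
coverage). On the error-prone exposures the NO2 coefficient — the pollutant
with the lower true-variance/error-variance ratio — loses about a fifth of
its value, while PM2.5 is pulled down much less: the classical share of the
NO2 error has transferred part of the NO2 effect onto PM2.5. The analytic
oracle predicts the same fitted values from the scenario's covariance
components:

```r
sp <- as_scenario_spec(grid[1, ])
mc <- mixture_components(sp)
classical_attenuation(mc$Sigma_L, mc$Sigma_delta_c, c(6e-4, 5.4e-4))
#> lambda:
#>         no2    pm25
#> no2  0.7885 -0.0320
#> pm25 0.0293  0.9113
#> predicted multi-pollutant coefs: 0.0004558 0.0005097
#> predicted single-pollutant coefs: 0.0007996 0.0006865
```

(4.56 and 5.10 ×10⁻⁴, matching the simulated 4.71 and 5.02 within
Monte-Carlo noise.)

Scenario-level sensitivity branches (halved/doubled CRFs, single-pollutant
truth, larger classical shares, multiplicative error) are run with
`run_sensitivity()`; `table_by_area()`, `table_by_error_level()` and
`table_single_vs_multi()` pool a run into the standard reporting layouts,
and `effect_transfer_table()` emits the per-scenario scatter data with
quadrant classification.

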