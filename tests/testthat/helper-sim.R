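# Shared fixtures: everything is generated in code at test time.

# Europe scenario with configurable fields; short series by default for speed.
europe_spec <- function(..., rho_exposure = 0.5, err_level_pm = 1,
                        err_level_no2 = 1, error_type = "classical",
                        n_days = 1461) {
  scenario_spec("europe", rho_exposure = rho_exposure,
                err_level_pm = err_level_pm, err_level_no2 = err_level_no2,
                error_type = error_type, n_days = n_days, ...)
}

# Empirical standard error of a pooled mean coefficient (x 1e4 scale).
pooled_se <- function(pooled_row) {
  pooled_row$se_b / sqrt(pooled_row$n_reps_used)
}

# Pooled multi-pollutant coefficients (x 1e4) from a sim_run, by pollutant.
pooled_multi <- function(run, source = "error_prone") {
  s <- run$summaries
  p <- pool_summaries(s[s$model_kind == "multi" &
                          s$exposure_source == source, ],
                      group_by = "pollutant")
  rownames(p) <- p$pollutant
  p
}

# Fabricate a per-replicate fits frame with known values (metrics tests).
fake_fits <- function(coef, beta_true, se = 1e-4, scenario_id = "s1",
                      pollutant = "pm25", model_kind = "multi",
                      exposure_source = "error_prone", converged = TRUE) {
  n <- length(coef)
  data.frame(
    scenario_id = scenario_id, rep = seq_len(n),
    model_kind = model_kind, exposure_source = exposure_source,
    pollutant = pollutant, coef = coef, se = se,
    ci_lo = coef - 1.96 * se, ci_hi = coef + 1.96 * se,
    pvalue = 2 * stats::pnorm(-abs(coef / se)),
    dispersion = 1.3, converged = converged, beta_true = beta_true,
    stringsAsFactors = FALSE
  )
}
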