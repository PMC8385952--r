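## Metrics aggregation: Monte-Carlo summaries (mean coefficient, SE_W, SE_B,
## relative bias, coverage, power) and their pooling across scenarios.

#' Summarise per-replicate fits within scenarios
#'
#' Reduces the per-replicate fit rows to Monte-Carlo aggregates per
#' (scenario, model, exposure source, pollutant): number of converged
#' replicates, mean coefficient (x 1e4, the conventional reporting scale),
#' `se_w` (mean model-based SE x 1e4, the "within-simulation" SE), `se_b`
#' (SD of the estimates across replicates x 1e4, the "between-simulation"
#' SE), relative bias in percent, 95% CI coverage of the generating
#' coefficient, and power at the 5% level. Replicates whose fit did not
#' converge are excluded (their count is `n_reps` minus `n_reps_used`).
#'
#' For a pollutant whose generating coefficient is zero the relative bias is
#' undefined and reported as `NA`; the mean coefficient column still shows
#' the (transfer-induced) estimate.
#'
#' @param fits data frame of per-replicate fit rows as produced by
#'   [run_experiment()] (must contain `coef`, `se`, `ci_lo`, `ci_hi`,
#'   `pvalue`, `converged`, `beta_true` and the grouping columns).
#' @param by grouping columns; defaults to scenario id and factor columns
#'   present in `fits` plus (model_kind, exposure_source, pollutant).
#' @return Data frame of class `"scenario_summary"`.
#' @export
summarize_scenario <- function(fits, by = NULL) {
  if (is.null(by)) {
    by <- intersect(c("scenario_id", "area", "rho_exposure", "err_level_pm",
                      "err_level_no2", "error_type", "model_kind",
                      "exposure_source", "pollutant"), names(fits))
  }
  stopifnot(all(by %in% names(fits)), nrow(fits) > 0)
  keyed <- fits[, by, drop = FALSE]
  key <- do.call(paste, c(keyed, sep = "\r"))
  idx <- split(seq_len(nrow(fits)), key)
  rows <- lapply(idx, function(i) {
    g <- fits[i, ]
    ok <- g$converged & is.finite(g$coef)
    g <- g[ok, ]
    if (nrow(g) == 0) {
      out <- keyed[i[1], , drop = FALSE]
      out$n_reps_used <- 0L
      out[c("beta_true_e4", "mean_coef", "se_w", "se_b", "bias_pct",
            "coverage_pct", "power_pct")] <- NA_real_
      return(out)
    }
    bt <- g$beta_true[1]
    out <- keyed[i[1], , drop = FALSE]
    out$n_reps_used <- nrow(g)
    out$beta_true_e4 <- bt * 1e4
    out$mean_coef <- mean(g$coef) * 1e4
    out$se_w <- mean(g$se) * 1e4
    out$se_b <- stats::sd(g$coef) * 1e4
    out$bias_pct <- if (bt == 0) NA_real_ else
      100 * (mean(g$coef) - bt) / bt
    out$coverage_pct <- 100 * mean(g$ci_lo <= bt & bt <= g$ci_hi)
    out$power_pct <- 100 * mean(g$pvalue < 0.05)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[do.call(order, out[by]), ]
  rownames(out) <- NULL
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' Pool scenario summaries across grouping factors
#'
#' Replicate-weighted pooling: each summary contributes proportionally to
#' its converged replicate count, which is equivalent to recomputing the
#' Monte-Carlo aggregates over the union of all replicates in the group
#' (the study's table rows pool equally-replicated scenarios, where
#' replicate- and scenario-weighting coincide). `se_b` is pooled by exact
#' moment reconstruction (within- plus between-scenario variance of the
#' estimates); `bias_pct` is recomputed from the pooled mean coefficient.
#'
#' @param summaries a `scenario_summary` data frame.
#' @param group_by columns of `summaries` defining the pooled rows, e.g.
#'   `c("error_type", "model_kind", "exposure_source", "pollutant")`.
#' @return Data frame with one row per group and the same metric columns.
#' @export
pool_summaries <- function(summaries,
                           group_by = c("model_kind", "exposure_source",
                                        "pollutant")) {
  unknown <- setdiff(group_by, names(summaries))
  if (length(unknown)) {
    stop("unknown grouping factor(s): ", paste(unknown, collapse = ", "))
  }
  key <- do.call(paste, c(summaries[, group_by, drop = FALSE], sep = "\r"))
  idx <- split(seq_len(nrow(summaries)), key)
  rows <- lapply(idx, function(i) {
    g <- summaries[i, ]
    g <- g[g$n_reps_used > 0, ]
    if (nrow(g) == 0) return(NULL)
    n <- g$n_reps_used
    w <- n / sum(n)
    out <- summaries[i[1], group_by, drop = FALSE]
    out$n_scenarios <- nrow(g)
    out$n_reps_used <- sum(n)
    bt <- g$beta_true_e4[1]
    out$beta_true_e4 <- bt
    m <- sum(w * g$mean_coef)
    out$mean_coef <- m
    out$se_w <- sum(w * g$se_w)
    # pooled second moment of the estimates: sample variance uses (n-1)
    m2 <- sum(w * (g$se_b^2 * (n - 1) / n + g$mean_coef^2))
    nn <- sum(n)
    out$se_b <- sqrt(pmax(m2 - m^2, 0) * nn / max(nn - 1, 1))
    out$bias_pct <- if (is.na(bt) || bt == 0) NA_real_ else 100 * (m - bt) / bt
    out$coverage_pct <- sum(w * g$coverage_pct)
    out$power_pct <- sum(w * g$power_pct)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[group_by]), , drop = FALSE]
}

#' Effect-transfer scatter data
#'
#' Per-scenario mean two-pollutant coefficients on the error-prone
#' exposures, with Monte-Carlo confidence intervals, sorted by the NO2
#' effect size -- the data behind the effect-transfer scatter and ladder
#' plots. Each scenario is classified into a quadrant relative to the
#' generating coefficients: `both_attenuated`, `transfer_to_pm` (PM2.5 up,
#' NO2 down), `transfer_to_no2`, or `both_overestimated` (which should be
#' empty under mixture error).
#'
#' @param summaries a `scenario_summary` containing multi-pollutant,
#'   error-prone rows.
#' @return Data frame with one row per scenario: mean coefficients, CI
#'   half-widths of the scenario mean, biases and `quadrant`.
#' @export
effect_transfer_table <- function(summaries) {
  s <- summaries[summaries$model_kind == "multi" &
                   summaries$exposure_source == "error_prone", ]
  if (nrow(s) == 0) stop("no multi-pollutant error-prone summaries present")
  no2 <- s[s$pollutant == "no2", ]
  pm <- s[s$pollutant == "pm25", ]
  stopifnot(nrow(no2) == nrow(pm))
  pm <- pm[match(no2$scenario_id, pm$scenario_id), ]
  out <- data.frame(
    scenario_id = no2$scenario_id,
    mean_no2 = no2$mean_coef, mean_pm = pm$mean_coef,
    ci_no2 = 1.96 * no2$se_b / sqrt(no2$n_reps_used),
    ci_pm = 1.96 * pm$se_b / sqrt(pm$n_reps_used),
    bias_no2 = no2$bias_pct, bias_pm = pm$bias_pct,
    stringsAsFactors = FALSE
  )
  if ("area" %in% names(no2)) out$area <- no2$area
  up_no2 <- out$mean_no2 > no2$beta_true_e4
  up_pm <- out$mean_pm > pm$beta_true_e4
  out$quadrant <- ifelse(up_no2 & up_pm, "both_overestimated",
                    ifelse(up_pm, "transfer_to_pm",
                      ifelse(up_no2, "transfer_to_no2", "both_attenuated")))
  out <- out[order(out$mean_no2), ]
  rownames(out) <- NULL
  out
}

#' Percentage change from multi- to single-pollutant estimates
#'
#' `100 * (beta_single - beta_multi) / beta_multi` per pollutant, computed
#' from replicate-weighted pooled coefficients within each group. The
#' single-pollutant coefficient for PM2.5 comes from the `single_pm` model,
#' for NO2 from `single_no2`.
#'
#' @param summaries a `scenario_summary` containing both model kinds.
#' @param group_by extra grouping columns (e.g. `"error_type"`,
#'   `"exposure_source"`); pooling always separates pollutants.
#' @return Data frame with pooled multi and single coefficients (x 1e4) and
#'   `change_pct` per group x pollutant (`NA` when the multi-pollutant
#'   coefficient is zero).
#' @export
single_vs_multi_change <- function(summaries,
                                   group_by = c("error_type",
                                                "exposure_source")) {
  group_by <- intersect(group_by, names(summaries))
  pooled <- pool_summaries(summaries,
                           group_by = c(group_by, "model_kind", "pollutant"))
  single_kind <- c(no2 = "single_no2", pm25 = "single_pm")
  keep_multi <- pooled$model_kind == "multi"
  keep_single <- pooled$model_kind == single_kind[pooled$pollutant]
  m <- pooled[keep_multi, ]
  s <- pooled[keep_single, ]
  key <- function(d) do.call(paste, c(d[, c(group_by, "pollutant"),
                                        drop = FALSE], sep = "\r"))
  s <- s[match(key(m), key(s)), ]
  out <- m[, c(group_by, "pollutant"), drop = FALSE]
  out$coef_multi <- m$mean_coef
  out$coef_single <- s$mean_coef
  out$change_pct <- ifelse(m$mean_coef == 0, NA_real_,
                           100 * (s$mean_coef - m$mean_coef) / m$mean_coef)
  rownames(out) <- NULL
  out
}
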