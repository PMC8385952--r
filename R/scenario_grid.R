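## Scenario grid: factorial design of the simulation study and the
## natural-scale -> log-scale parameter bridge for the lognormal sampler.

.error_types <- c("none", "classical", "berkson", "mixture", "multiplicative")
.error_modes <- c("additive_natural", "additive_log")

#' Default scenario parameters
#'
#' Defaults shared by every scenario unless overridden: concentration-response
#' coefficients (log-rate per ppb NO2 and per ug/m3 PM2.5), overdispersion,
#' series length, replicate count, mixture shares, and the knobs the study
#' leaves open (cross-pollutant error correlation, Berkson variant,
#' multiplicative calibration).
#'
#' `beta0 = NA` means "derive so that the expected daily death count at mean
#' exposure equals `target_mean_deaths`". `rho_error = NA` means "equal to
#' `rho_exposure`".
#'
#' @return Named list of default scalar parameters.
#' @export
scenario_defaults <- function() {
  list(
    rho_error = NA_real_,          # NA -> follow rho_exposure
    mixture_frac_pm = 0.43,        # classical share of PM2.5 error variance
    mixture_frac_no2 = 0.33,       # classical share of NO2 error variance
    beta_no2 = 0.0006,             # log-rate per ppb
    beta_pm = 0.00054,             # log-rate per ug/m3
    beta0 = NA_real_,              # NA -> calibrated to target_mean_deaths
    target_mean_deaths = 130,      # expected daily deaths at mean exposure
    phi = 1.3,                     # quasi-Poisson overdispersion, Var = phi*mu
    n_days = 1461L,                # 4 years of daily data
    n_reps = 1000L,
    error_mode = "additive_natural",
    berkson_variant = "as_printed",   # or "strict"
    berkson_sigma_c = "classical_proxy",  # sigma_C^2 = sigma_A^2 + sigma_delta^2
    mult_calibration = "sd_at_mean",  # or "log_sd"
    nb_theta = "consistent"        # or "printed" (theta = phi/(mu-1))
  )
}

#' Construct a single simulation scenario
#'
#' A scenario is one cell of the factorial design: a study area, a correlation
#' between the two true exposures, one error-variability level per pollutant
#' (multiplier on the area's moderate error SD), an error type and mode, plus
#' the outcome-generation parameters.
#'
#' @param area area key, see [study_areas()].
#' @param rho_exposure natural-scale correlation between true NO2 and PM2.5
#'   (one of 0.25, 0.5, 0.75 in the default grid; any value in (-1, 1) is
#'   accepted).
#' @param err_level_pm,err_level_no2 multiplier on the moderate error SD
#'   (0.1 = very low, 0.5 = low, 1 = moderate, 1.3 = high).
#' @param error_type one of `"none"`, `"classical"`, `"berkson"`,
#'   `"mixture"`, `"multiplicative"`.
#' @param ... overrides of any field in [scenario_defaults()].
#' @return A list of class `"scenario_spec"`.
#' @export
#' @examples
#' sp <- scenario_spec("europe", 0.5, 1, 1, "mixture")
#' error_sds(sp)
scenario_spec <- function(area = "europe", rho_exposure = 0.5,
                          err_level_pm = 1, err_level_no2 = 1,
                          error_type = "mixture", ...) {
  ap <- area_params(area)
  spec <- c(
    list(area = area, rho_exposure = rho_exposure,
         err_level_pm = err_level_pm, err_level_no2 = err_level_no2,
         error_type = error_type),
    ap[c("mean_pm", "sd_pm", "mean_no2", "sd_no2",
         "mod_err_sd_pm", "mod_err_sd_no2")],
    scenario_defaults()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  }
  spec[names(dots)] <- dots
  spec$scenario_id <- scenario_id(spec)
  class(spec) <- "scenario_spec"
  validate_scenario(spec)
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$scenario_id, "\n")
  cat(sprintf("  area %s | rho_exposure %.2f | error levels PM %.1f / NO2 %.1f\n",
              x$area, x$rho_exposure, x$err_level_pm, x$err_level_no2))
  cat(sprintf("  error_type %s (%s) | beta_no2 %.2e, beta_pm %.2e | phi %.2f\n",
              x$error_type, x$error_mode, x$beta_no2, x$beta_pm, x$phi))
  invisible(x)
}

scenario_id <- function(spec) {
  sprintf("%s_%s_r%03d_pm%03d_no2%03d",
          spec$error_type, spec$area,
          as.integer(round(100 * spec$rho_exposure)),
          as.integer(round(100 * spec$err_level_pm)),
          as.integer(round(100 * spec$err_level_no2)))
}

validate_scenario <- function(spec) {
  stopifnot(
    spec$error_type %in% .error_types,
    spec$error_mode %in% .error_modes,
    spec$mean_pm > 0, spec$sd_pm > 0, spec$mean_no2 > 0, spec$sd_no2 > 0,
    spec$mod_err_sd_pm >= 0, spec$mod_err_sd_no2 >= 0,
    spec$err_level_pm >= 0, spec$err_level_no2 >= 0,
    spec$mixture_frac_pm >= 0, spec$mixture_frac_pm <= 1,
    spec$mixture_frac_no2 >= 0, spec$mixture_frac_no2 <= 1,
    abs(spec$rho_exposure) < 1,
    is.na(spec$rho_error) || abs(spec$rho_error) < 1,
    spec$phi >= 1,
    spec$n_days >= 3, spec$n_reps >= 1
  )
  invisible(spec)
}

#' Resolved cross-pollutant error correlation of a scenario
#'
#' @param spec a `scenario_spec`.
#' @return `rho_error` if set, otherwise `rho_exposure`.
#' @export
rho_error_of <- function(spec) {
  if (is.na(spec$rho_error)) spec$rho_exposure else spec$rho_error
}

#' Error standard deviations of a scenario (natural units)
#'
#' The per-pollutant error SD is the scenario's level multiplier applied to
#' the area's moderate error SD, so the very low / low / high levels are
#' exactly 0.1x / 0.5x / 1.3x the moderate value (the occasionally quoted
#' one-decimal figures, e.g. 0.5 ug/m3 for Europe PM2.5, are rounded).
#'
#' @param spec a `scenario_spec` (or a one-row grid slice).
#' @return Named numeric vector `c(no2 = , pm25 = )` in ppb and ug/m3.
#' @export
error_sds <- function(spec) {
  spec <- as_scenario_spec(spec)
  c(no2 = spec$err_level_no2 * spec$mod_err_sd_no2,
    pm25 = spec$err_level_pm * spec$mod_err_sd_pm)
}

#' Moment-matched log-scale parameters of a bivariate lognormal
#'
#' Translates natural-scale means, SDs and correlation into the mean vector
#' and covariance matrix of the underlying bivariate normal, using the exact
#' lognormal moment identities: `sigma_log^2 = log(1 + sd^2/mean^2)`,
#' `cov_log = log(1 + rho*sd1*sd2/(mean1*mean2))`,
#' `mu_log = log(mean) - sigma_log^2/2`. Sampling from the returned normal
#' and exponentiating reproduces the requested natural-scale moments.
#'
#' @param mean,sd length-2 positive numeric vectors (natural scale).
#' @param rho natural-scale correlation, `|rho| < 1`.
#' @return List with `mu_log` (length 2) and `sigma_log` (2x2 covariance),
#'   class `"lognormal_params"`.
#' @export
#' @examples
#' lp <- natural_to_log_params(c(21.6, 21.1), c(8.9, 10.9), 0.5)
#' exp(lp$mu_log + diag(lp$sigma_log) / 2)  # recovers the means
natural_to_log_params <- function(mean, sd, rho) {
  stopifnot(length(mean) == 2, length(sd) == 2, length(rho) == 1)
  if (any(mean <= 0) || any(sd <= 0)) {
    stop("natural-scale means and sds must be strictly positive")
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  s2 <- log1p((sd / mean)^2)
  arg <- rho * sd[1] * sd[2] / (mean[1] * mean[2])
  if (arg <= -1) {
    stop("rho implies a non-positive lognormal covariance argument")
  }
  cv <- log1p(arg)
  sigma_log <- matrix(c(s2[1], cv, cv, s2[2]), 2, 2)
  if (cv^2 >= s2[1] * s2[2]) {
    stop("implied log-scale covariance matrix is not positive-definite")
  }
  out <- list(mu_log = log(mean) - s2 / 2, sigma_log = sigma_log)
  class(out) <- "lognormal_params"
  out
}

#' Natural-scale covariance matrix of a scenario's true exposures
#'
#' @param spec a `scenario_spec`.
#' @return 2x2 covariance matrix, order (NO2, PM2.5).
#' @export
natural_covariance <- function(spec) {
  spec <- as_scenario_spec(spec)
  cv <- spec$rho_exposure * spec$sd_no2 * spec$sd_pm
  matrix(c(spec$sd_no2^2, cv, cv, spec$sd_pm^2), 2, 2,
         dimnames = list(c("no2", "pm25"), c("no2", "pm25")))
}

#' Build the factorial scenario grid
#'
#' The default design crosses 3 study areas x 3 exposure correlations
#' (0.25/0.5/0.75) x 4 PM2.5 error levels x 4 NO2 error levels
#' (0.1/0.5/1/1.3 x moderate) = 144 scenarios, for one error type and mode.
#' Rows are ordered by (area, correlation, PM level, NO2 level) and scenario
#' ids are a pure function of the factor levels, so the grid is reproducible.
#'
#' @param config named list of overrides. Factor-level keys `areas`,
#'   `rho_exposure`, `err_levels_pm`, `err_levels_no2` replace the default
#'   level sets; any field of [scenario_defaults()] plus `error_type` /
#'   `error_mode` is applied to every scenario.
#' @return Data frame of class `"scenario_grid"`, one row per scenario, with
#'   all scalar scenario fields as columns.
#' @export
#' @examples
#' nrow(build_grid())                                   # 144
#' nrow(build_grid(list(areas = "europe")))             # 48
#' nrow(build_grid(list(areas = "europe", rho_exposure = 0.5,
#'                      err_levels_pm = 1, err_levels_no2 = 1)))  # 1
build_grid <- function(config = list()) {
  stopifnot(is.list(config))
  level_keys <- c("areas", "rho_exposure", "err_levels_pm", "err_levels_no2")
  areas <- config$areas %||% study_areas()$area
  rhos <- config$rho_exposure %||% c(0.25, 0.5, 0.75)
  lv_pm <- config$err_levels_pm %||% c(0.1, 0.5, 1, 1.3)
  lv_no2 <- config$err_levels_no2 %||% c(0.1, 0.5, 1, 1.3)
  error_type <- config$error_type %||% "mixture"

  scalar <- config[setdiff(names(config), c(level_keys, "error_type"))]
  allowed <- names(scenario_defaults())
  unknown <- setdiff(names(scalar), allowed)
  if (length(unknown)) {
    stop("unknown grid override(s): ", paste(unknown, collapse = ", "))
  }

  cells <- expand.grid(err_level_no2 = lv_no2, err_level_pm = lv_pm,
                       rho_exposure = rhos, area = areas,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # reorder columns to the documented (area, rho, pm, no2) key order
  cells <- cells[, c("area", "rho_exposure", "err_level_pm", "err_level_no2")]
  specs <- lapply(seq_len(nrow(cells)), function(i) {
    do.call(scenario_spec, c(
      list(area = cells$area[i], rho_exposure = cells$rho_exposure[i],
           err_level_pm = cells$err_level_pm[i],
           err_level_no2 = cells$err_level_no2[i],
           error_type = error_type),
      scalar
    ))
  })
  grid <- do.call(rbind, lapply(specs, function(s) {
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  }))
  grid <- grid[, c("scenario_id", setdiff(names(grid), "scenario_id"))]
  if (anyDuplicated(grid$scenario_id)) {
    stop("duplicated scenario ids; factor levels must be distinct")
  }
  rownames(grid) <- NULL
  class(grid) <- c("scenario_grid", "data.frame")
  grid
}

#' Coerce a grid row (or list) to a scenario_spec
#'
#' @param x a `scenario_spec`, a one-row data frame from [build_grid()], or a
#'   named list with the scenario fields.
#' @return A `scenario_spec`.
#' @export
as_scenario_spec <- function(x) {
  if (inherits(x, "scenario_spec")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- as.list(x)
  }
  stopifnot(is.list(x))
  class(x) <- "scenario_spec"
  validate_scenario(x)
  x
}

#' Export a scenario grid to CSV
#'
#' One row per scenario, all scalar fields as columns.
#'
#' @param grid a `scenario_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
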