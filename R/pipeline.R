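## Pipeline: seed derivation, replicate loop, experiment orchestration,
## sensitivity branches and output persistence.

#' Derive a replicate seed from the master seed
#'
#' A pure integer hash of `(master_seed, scenario_id, rep)`, so every
#' scenario/replicate pair gets its own reproducible seed regardless of the
#' order in which scenarios are run.
#'
#' @param master_seed integer master seed.
#' @param scenario_id scenario identifier string.
#' @param rep replicate index.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, scenario_id, rep) {
  key <- paste(master_seed, scenario_id, rep, sep = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

#' Simulate and fit one replicate of one scenario
#'
#' Generates the true exposures, applies the scenario's error model,
#' simulates mortality from the (post-error-model) true series, and fits
#' the requested models. All randomness flows from `seed`.
#'
#' @param spec a `scenario_spec`.
#' @param seed integer seed for this replicate.
#' @inheritParams fit_all_models
#' @return The per-fit data frame from [fit_all_models()].
#' @export
simulate_rep <- function(spec, seed,
                         models = c("multi", "single_no2", "single_pm"),
                         sources = c("true", "error_prone")) {
  spec <- as_scenario_spec(spec)
  set.seed(seed)
  ex <- simulate_true_exposures(spec)
  ex <- apply_error(ex, spec)
  out <- simulate_outcomes(ex, spec)
  fit_all_models(ex, out, models = models, sources = sources)
}

#' Run the simulation experiment over a scenario grid
#'
#' For every scenario x replicate: simulate true exposures, apply the error
#' model, generate mortality, fit the requested battery of models. Returns
#' the per-replicate fit rows (annotated with the scenario's factor levels),
#' the per-scenario Monte-Carlo summaries, and a manifest sufficient to
#' reproduce the run bit-for-bit. Identical inputs give identical outputs;
#' scenarios may be run in any order or subset.
#'
#' @param grid a `scenario_grid` (default: the full 144-scenario mixture
#'   grid).
#' @param master_seed integer master seed.
#' @param reps replicates per scenario; `NULL` uses each scenario's
#'   `n_reps` (1000 by default -- scale down for exploratory runs).
#' @inheritParams fit_all_models
#' @param out_dir optional directory; when given, writes `fits.csv`,
#'   `summaries.csv`, `grid.csv` and `manifest.json`.
#' @param verbose print per-scenario progress lines.
#' @return List of class `"sim_run"`: `fits`, `summaries`, `grid`,
#'   `manifest`.
#' @export
run_experiment <- function(grid = build_grid(), master_seed = 1, reps = NULL,
                           models = c("multi", "single_no2", "single_pm"),
                           sources = c("true", "error_prone"),
                           out_dir = NULL, verbose = FALSE) {
  grid <- if (inherits(grid, "scenario_grid")) grid else
    build_grid(as.list(grid))
  factor_cols <- c("area", "rho_exposure", "err_level_pm", "err_level_no2",
                   "error_type")
  all_fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- as_scenario_spec(grid[i, ])
    nr <- if (is.null(reps)) spec$n_reps else reps
    rep_fits <- vector("list", nr)
    for (r in seq_len(nr)) {
      seed_r <- derive_seed(master_seed, spec$scenario_id, r)
      f <- simulate_rep(spec, seed_r, models = models, sources = sources)
      f$rep <- r
      rep_fits[[r]] <- f
    }
    sf <- do.call(rbind, rep_fits)
    sf$scenario_id <- spec$scenario_id
    for (cc in factor_cols) sf[[cc]] <- spec[[cc]]
    all_fits[[i]] <- sf
    if (verbose) {
      message(sprintf("[%3d/%d] %s: %d reps, %d non-converged rows",
                      i, nrow(grid), spec$scenario_id, nr,
                      sum(!sf$converged)))
    }
  }
  fits <- do.call(rbind, all_fits)
  front <- c("scenario_id", "rep", factor_cols)
  fits <- fits[, c(front, setdiff(names(fits), front))]
  summaries <- summarize_scenario(fits)
  manifest <- list(
    master_seed = master_seed,
    package_version = as.character(utils::packageVersion("pollerrsim")),
    n_scenarios = nrow(grid),
    scenario_ids = grid$scenario_id,
    reps = if (is.null(reps)) unique(grid$n_reps) else reps,
    models = models, sources = sources,
    error_types = unique(grid$error_type),
    error_modes = unique(grid$error_mode),
    n_fit_rows = nrow(fits),
    n_nonconverged_rows = sum(!fits$converged)
  )
  run <- structure(list(fits = fits, summaries = summaries, grid = grid,
                        manifest = manifest), class = "sim_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.sim_run <- function(x, ...) {
  cat("<sim_run>", x$manifest$n_scenarios, "scenarios x",
      paste(x$manifest$reps, collapse = "/"), "reps |",
      x$manifest$n_fit_rows, "fit rows |",
      x$manifest$n_nonconverged_rows, "non-converged\n")
  invisible(x)
}

#' Persist a simulation run
#'
#' Writes `fits.csv` (per-replicate fit rows), `summaries.csv`
#' (per-scenario Monte-Carlo summaries), `grid.csv` and `manifest.json`
#' into `out_dir`.
#'
#' @param run a `sim_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$summaries),
                   file.path(out_dir, "summaries.csv"), row.names = FALSE)
  write_grid(run$grid, file.path(out_dir, "grid.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Pooled table by study area and error type
#'
#' Replicate-weighted pooling of the two-pollutant fits by (area, error
#' type, exposure source, pollutant) -- the "regression estimates by area"
#' summary layout.
#'
#' @param fits per-replicate fit rows from [run_experiment()].
#' @return Pooled data frame.
#' @export
table_by_area <- function(fits) {
  s <- summarize_scenario(fits)
  pool_summaries(s[s$model_kind == "multi", ],
                 group_by = c("error_type", "exposure_source", "area",
                              "pollutant"))
}

#' Pooled table by correlation and error-variability levels
#'
#' Pools the three areas within each (exposure correlation, PM2.5 error
#' level, NO2 error level) cell for the multi-pollutant, error-prone fits --
#' the "bias by error variability" layout.
#'
#' @param fits per-replicate fit rows from [run_experiment()].
#' @return Pooled data frame.
#' @export
table_by_error_level <- function(fits) {
  s <- summarize_scenario(fits)
  pool_summaries(
    s[s$model_kind == "multi" & s$exposure_source == "error_prone", ],
    group_by = c("rho_exposure", "err_level_pm", "err_level_no2",
                 "pollutant"))
}

#' Pooled single- versus multi-pollutant comparison table
#'
#' Pools all scenarios per error type and exposure source and reports the
#' pooled coefficients of each model kind together with the percentage
#' change from multi- to single-pollutant estimates.
#'
#' @param fits per-replicate fit rows from [run_experiment()].
#' @return Pooled data frame (one row per error type x source x pollutant).
#' @export
table_single_vs_multi <- function(fits) {
  single_vs_multi_change(summarize_scenario(fits),
                         group_by = c("error_type", "exposure_source"))
}

#' Run the sensitivity branches around the core scenario
#'
#' The core branch is the Europe area with additive mixture error (48
#' scenarios: 3 correlations x 4 x 4 error levels). Sensitivity branches
#' re-run it with: the CRFs halved and doubled; a single true effect
#' (each pollutant's coefficient set to zero in turn); larger classical
#' shares in the mixture ((55,45)/(45,55) and (70,30)/(60,40)); and
#' multiplicative instead of additive error. Each branch is pooled over its
#' scenarios for the multi-pollutant, error-prone fits.
#'
#' @param master_seed integer master seed.
#' @param reps replicates per scenario.
#' @param area core area (default `"europe"`).
#' @param extra_config additional [build_grid()] config entries applied to
#'   every branch (e.g. a restricted level set for quick runs).
#' @param out_dir optional directory for `table5.csv`.
#' @param verbose print progress.
#' @return Data frame, one row per branch x pollutant, with pooled mean
#'   coefficient (x 1e4), `se_w`, `se_b`, `bias_pct`.
#' @export
run_sensitivity <- function(master_seed = 1, reps = 100, area = "europe",
                            extra_config = list(), out_dir = NULL,
                            verbose = FALSE) {
  branches <- list(
    main = list(),
    crf_half = list(beta_no2 = 0.0003, beta_pm = 0.00027),
    crf_double = list(beta_no2 = 0.0012, beta_pm = 0.00108),
    only_pm = list(beta_no2 = 0),
    only_no2 = list(beta_pm = 0),
    mix_55_45 = list(mixture_frac_pm = 0.55, mixture_frac_no2 = 0.45),
    mix_70_60 = list(mixture_frac_pm = 0.70, mixture_frac_no2 = 0.60),
    multiplicative = list(error_type = "multiplicative")
  )
  rows <- list()
  for (bn in names(branches)) {
    cfg <- c(list(areas = area, error_type = "mixture"), extra_config,
             branches[[bn]])
    cfg <- cfg[!duplicated(names(cfg), fromLast = TRUE)]
    run <- run_experiment(build_grid(cfg), master_seed = master_seed,
                          reps = reps, models = "multi",
                          sources = "error_prone", verbose = verbose)
    pooled <- pool_summaries(run$summaries,
                             group_by = c("exposure_source", "pollutant"))
    pooled$branch <- bn
    rows[[bn]] <- pooled[, c("branch", "pollutant", "n_reps_used",
                             "mean_coef", "se_w", "se_b", "bias_pct")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "table5.csv"),
                     row.names = FALSE)
  }
  out
}

#' Read a grid configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose keys mirror the
#' [build_grid()] config entries.
#'
#' @param path file path.
#' @return Named list suitable for `build_grid(config = ...)`.
#' @export
read_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  cfg <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext)
  )
  stopifnot(is.list(cfg))
  cfg
}
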