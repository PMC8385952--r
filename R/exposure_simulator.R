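## Exposure simulator: true bivariate lognormal series plus classical,
## Berkson, mixture and multiplicative measurement-error generators.
## Column order everywhere is (no2, pm25), matching the study's indexing.

.poll <- c("no2", "pm25")

new_exposure_set <- function(A, C, spec, seed = NULL, mixture = NULL) {
  delta <- C - A
  structure(list(days = seq_len(nrow(A)), A = A, C = C, delta = delta,
                 spec = spec, seed = seed, mixture = mixture),
            class = "exposure_set")
}

#' @export
print.exposure_set <- function(x, ...) {
  cat("<exposure_set>", nrow(x$A), "days,", x$spec$scenario_id, "\n")
  cat("  mean A:", round(colMeans(x$A), 2),
      "| sd A:", round(apply(x$A, 2, stats::sd), 2),
      "| sd(C-A):", round(apply(x$delta, 2, stats::sd), 3), "\n")
  invisible(x)
}

## Correlated bivariate normal draws with given SDs (either may be 0).
rbvnorm <- function(n, sd, rho) {
  stopifnot(length(sd) == 2, all(sd >= 0), abs(rho) <= 1)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  out <- cbind(no2 = sd[1] * z1, pm25 = sd[2] * z2)
  out
}

## Mean-one lognormal multiplicative noise with log-scale SDs s (length 2).
rmult_noise <- function(n, s, rho) {
  z <- rbvnorm(n, s, rho)
  exp(sweep(z, 2, s^2 / 2, "-"))
}

#' Simulate the true exposure series
#'
#' Draws `n_days` i.i.d. daily values of (NO2, PM2.5) from the bivariate
#' lognormal whose natural-scale means, SDs and correlation are given by the
#' scenario (moment-matched via [natural_to_log_params()]). The series has no
#' autocorrelation, trend or seasonality by design: the study isolates
#' measurement-error bias from the other biases of real time-series data.
#'
#' @param spec a `scenario_spec` (or grid row).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return An `exposure_set` with `C` identical to `A` and zero `delta`.
#' @export
simulate_true_exposures <- function(spec, seed = NULL) {
  spec <- as_scenario_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  lp <- natural_to_log_params(c(spec$mean_no2, spec$mean_pm),
                              c(spec$sd_no2, spec$sd_pm),
                              spec$rho_exposure)
  n <- spec$n_days
  Z <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(lp$sigma_log)
  A <- exp(sweep(Z, 2, lp$mu_log, "+"))
  colnames(A) <- .poll
  new_exposure_set(A, A, spec, seed)
}

#' Cross-pollutant error covariance matrix
#'
#' Diagonal entries are the squared error SDs; the off-diagonal is
#' `rho_error * sd1 * sd2`. This is the covariance of the bivariate error
#' draws shared by all additive error generators.
#'
#' @param sd_err length-2 nonnegative vector of error SDs (NO2, PM2.5).
#' @param rho_error correlation between the two pollutants' errors,
#'   `|rho_error| < 1`.
#' @return Symmetric positive semi-definite 2x2 matrix.
#' @export
error_covariance <- function(sd_err, rho_error) {
  stopifnot(length(sd_err) == 2, all(sd_err >= 0))
  if (abs(rho_error) >= 1) stop("|rho_error| must be < 1")
  cv <- rho_error * sd_err[1] * sd_err[2]
  matrix(c(sd_err[1]^2, cv, cv, sd_err[2]^2), 2, 2,
         dimnames = list(.poll, .poll))
}

## log-scale error SD such that the natural-scale SD of C - A equals sd_err
## at the exposure mean: sd(exp(d)) = sd_err/mean with E[exp(d)] = 1.
log_scale_err_sd <- function(sd_err, mean) {
  sqrt(log1p((sd_err / mean)^2))
}

## Covariance of the mixture's latent series: Sigma_0 - Sigma_b, with the
## off-diagonal capped at the positive-definiteness boundary. The cap binds
## only where a large independent Berkson component cannot coexist with the
## full nominal exposure covariance (2 of the 144 default cells); there the
## realized exposure correlation falls slightly below nominal.
latent_covariance <- function(Sigma_0, Sigma_b, rmax = 0.999) {
  Sigma_L <- Sigma_0 - Sigma_b
  if (any(diag(Sigma_L) <= 0)) {
    stop("Berkson error variance exceeds the true exposure variance; ",
         "the latent series would be degenerate")
  }
  bound <- rmax * sqrt(Sigma_L[1, 1] * Sigma_L[2, 2])
  if (abs(Sigma_L[1, 2]) > bound) {
    Sigma_L[1, 2] <- Sigma_L[2, 1] <- sign(Sigma_L[1, 2]) * bound
  }
  Sigma_L
}

#' Apply classical measurement error
#'
#' Classical error adds noise independent of the truth: `C = A + delta` with
#' `delta` drawn i.i.d. per day from a bivariate normal with covariance
#' [error_covariance()]. Under `error_mode = "additive_log"` the error is
#' added on the log scale (`C = A * exp(delta_log)`), with mean-one noise and
#' log-scale SDs calibrated so that the natural-scale SD of `C - A` matches
#' the scenario error SD at the exposure mean. Negative `C` values possible
#' under the natural-scale mode are retained: truncation would distort the
#' error moments and the downstream log-link regression admits them.
#'
#' @param exposures an `exposure_set` with `A` populated.
#' @param spec scenario; defaults to the one stored in `exposures`.
#' @param seed optional integer seed.
#' @return The `exposure_set` with `C` and `delta` filled in.
#' @export
apply_classical_error <- function(exposures, spec = exposures$spec,
                                  seed = NULL) {
  spec <- as_scenario_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  A <- exposures$A
  n <- nrow(A)
  sd_err <- error_sds(spec)
  rho <- rho_error_of(spec)
  if (spec$error_mode == "additive_log") {
    s <- log_scale_err_sd(sd_err, c(spec$mean_no2, spec$mean_pm))
    C <- A * rmult_noise(n, s, rho)
  } else {
    C <- A + rbvnorm(n, sd_err, rho)
  }
  new_exposure_set(A, C, spec, seed)
}

#' Apply Berkson measurement error
#'
#' Berkson error means the truth scatters around the observation
#' (`A = C + delta`, `delta` independent of `C`). The generator shrinks the
#' true series toward its mean by the best-linear-predictor factor
#' `lambda = sigma_C^2 / (sigma_C^2 + sigma_delta^2)` and adds independent
#' noise `delta*`:
#' `C = mu_A + lambda * (A - mu_A) + delta*`.
#'
#' Two variants are provided. `"as_printed"` uses
#' `Var(delta*) = sigma_C^2 sigma_delta^2 / (sigma_C^2 + sigma_delta^2)`,
#' with `sigma_C^2` interpreted as the variance of a classical proxy
#' (`sigma_A^2 + sigma_delta^2`; set `berkson_sigma_c = "true_variance"` for
#' the alternative reading `sigma_C^2 = sigma_A^2`). `"strict"` instead sets
#' `Var(delta*) = lambda * (1 - lambda) * sigma_A^2`, the unique choice for
#' which the Berkson orthogonality condition `Cov(C, A - C) = 0` holds in
#' expectation. Both shrink `Var(C)` below `Var(A)`.
#'
#' @inheritParams apply_classical_error
#' @param variant `"as_printed"` (default, literal formula) or `"strict"`
#'   (exact Berkson orthogonality).
#' @return The `exposure_set` with `C` and `delta` filled in.
#' @export
apply_berkson_error <- function(exposures, spec = exposures$spec, seed = NULL,
                                variant = spec$berkson_variant) {
  spec <- as_scenario_spec(spec)
  variant <- match.arg(variant, c("as_printed", "strict"))
  if (!is.null(seed)) set.seed(seed)
  A <- exposures$A
  n <- nrow(A)
  log_mode <- spec$error_mode == "additive_log"
  if (log_mode) {
    lp <- natural_to_log_params(c(spec$mean_no2, spec$mean_pm),
                                c(spec$sd_no2, spec$sd_pm),
                                spec$rho_exposure)
    mu_A <- lp$mu_log
    var_A <- diag(lp$sigma_log)
    var_d <- log_scale_err_sd(error_sds(spec),
                              c(spec$mean_no2, spec$mean_pm))^2
    X <- log(A)
  } else {
    mu_A <- c(spec$mean_no2, spec$mean_pm)
    var_A <- c(spec$sd_no2^2, spec$sd_pm^2)
    var_d <- error_sds(spec)^2
    X <- A
  }
  var_C <- if (spec$berkson_sigma_c == "true_variance") var_A else var_A + var_d
  tot <- var_C + var_d
  if (any(tot <= 0)) stop("zero total variance in Berkson construction")
  lambda <- var_C / tot
  var_star <- switch(variant,
    as_printed = var_C * var_d / tot,
    strict = lambda * (1 - lambda) * var_A
  )
  dstar <- rbvnorm(n, sqrt(var_star), rho_error_of(spec))
  C <- sweep(sweep(X, 2, mu_A, "-") %*% diag(lambda, 2), 2, mu_A, "+") + dstar
  if (log_mode) C <- exp(C)
  colnames(C) <- .poll
  new_exposure_set(A, C, spec, seed)
}

#' Apply mixture (classical + Berkson) measurement error
#'
#' The mixture routes both series through a latent intermediate `L`:
#' `A = L + delta_b` (Berkson component) and `C = L + delta_c` (classical
#' component), with `L`, `delta_b`, `delta_c` mutually independent. The total
#' error variance per pollutant equals the scenario error SD squared and is
#' partitioned by the classical shares `mixture_frac_pm` / `mixture_frac_no2`
#' (defaults 0.43 and 0.33): `Var(delta_c) = share x total`,
#' `Var(delta_b) = (1 - share) x total`. Both components are correlated
#' across pollutants with `rho_error`.
#'
#' The latent series is a linear transform of the simulated lognormal series
#' chosen so that `Cov(L) = Sigma_A - Sigma_delta_b` exactly; `A = L +
#' delta_b` then carries precisely the scenario's natural-scale means,
#' variances *and* cross-pollutant covariance. (In extreme cells where a
#' large Berkson component cannot coexist with the full nominal covariance,
#' the latent correlation is capped at the feasibility boundary and the
#' realized exposure correlation falls slightly below nominal.) The returned set therefore
#' *replaces* `A`, and downstream mortality must be generated from this
#' `A`. Shares of 1 reduce to pure classical error, shares of 0 to a pure
#' Berkson structure. Under `error_mode = "additive_log"` the identical
#' construction is applied to the log series with moment-calibrated
#' log-scale error variances (exact on the log scale, so the natural-scale
#' moments of `A` are preserved).
#'
#' @inheritParams apply_classical_error
#' @return The `exposure_set` with redefined `A`, new `C`, and a `mixture`
#'   element holding `L`, `delta_b`, `delta_c` (construction identities
#'   `A = L + delta_b`, `C = L + delta_c` hold exactly).
#' @export
apply_mixture_error <- function(exposures, spec = exposures$spec,
                                seed = NULL) {
  spec <- as_scenario_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  shares <- c(no2 = spec$mixture_frac_no2, pm25 = spec$mixture_frac_pm)
  if (any(shares < 0 | shares > 1)) stop("mixture shares must lie in [0, 1]")
  n <- nrow(exposures$A)
  log_mode <- spec$error_mode == "additive_log"
  lp <- natural_to_log_params(c(spec$mean_no2, spec$mean_pm),
                              c(spec$sd_no2, spec$sd_pm),
                              spec$rho_exposure)
  if (log_mode) {
    mu <- lp$mu_log
    Sigma_0 <- lp$sigma_log
    var_tot <- log_scale_err_sd(error_sds(spec),
                                c(spec$mean_no2, spec$mean_pm))^2
    X <- log(exposures$A)
  } else {
    mu <- c(spec$mean_no2, spec$mean_pm)
    Sigma_0 <- natural_covariance(spec)
    var_tot <- error_sds(spec)^2
    X <- exposures$A
  }
  var_b <- (1 - shares) * var_tot
  var_c <- shares * var_tot
  rho <- rho_error_of(spec)
  Sigma_b <- error_covariance(sqrt(var_b), rho)
  Sigma_L <- latent_covariance(Sigma_0, Sigma_b)
  # linear transform with T Sigma_0 T' = Sigma_L, so Cov(A) = Sigma_0 exactly
  Tm <- t(chol(Sigma_L)) %*% solve(t(chol(Sigma_0)))
  L <- sweep(sweep(X, 2, mu, "-") %*% t(Tm), 2, mu, "+")
  delta_b <- rbvnorm(n, sqrt(var_b), rho)
  delta_c <- rbvnorm(n, sqrt(var_c), rho)
  A <- L + delta_b
  C <- L + delta_c
  if (log_mode) {
    A <- exp(A); C <- exp(C); L <- exp(L)
  }
  colnames(A) <- colnames(C) <- .poll
  new_exposure_set(A, C, spec, seed,
                   mixture = list(L = L, delta_b = delta_b,
                                  delta_c = delta_c))
}

#' Apply multiplicative measurement error
#'
#' `C = A * eps` with `eps` mean-one lognormal noise, correlated across
#' pollutants with `rho_error`. The noise magnitude is configurable because
#' no canonical calibration exists for a constant-percent error:
#' `"sd_at_mean"` (default) chooses the log-scale SD so that the
#' natural-scale SD of `C - A` equals the scenario error SD at the exposure
#' mean; `"log_sd"` interprets the scenario's natural-unit error SD directly
#' as the log-scale SD of `eps`, a far harsher contamination that all but
#' destroys the exposure signal.
#'
#' @inheritParams apply_classical_error
#' @param calibration `"sd_at_mean"` or `"log_sd"`.
#' @return The `exposure_set` with `C = A * eps` (strictly positive).
#' @export
apply_multiplicative_error <- function(exposures, spec = exposures$spec,
                                       seed = NULL,
                                       calibration = spec$mult_calibration) {
  spec <- as_scenario_spec(spec)
  calibration <- match.arg(calibration, c("sd_at_mean", "log_sd"))
  if (!is.null(seed)) set.seed(seed)
  A <- exposures$A
  if (any(A <= 0)) stop("multiplicative error requires strictly positive A")
  sd_err <- error_sds(spec)
  s <- switch(calibration,
    sd_at_mean = log_scale_err_sd(sd_err, c(spec$mean_no2, spec$mean_pm)),
    log_sd = sd_err
  )
  C <- A * rmult_noise(nrow(A), s, rho_error_of(spec))
  new_exposure_set(A, C, spec, seed)
}

#' Apply the scenario's error model
#'
#' Dispatches on `spec$error_type`; `"none"` returns `C = A` unchanged.
#'
#' @inheritParams apply_classical_error
#' @return An `exposure_set` with error-prone `C`.
#' @export
apply_error <- function(exposures, spec = exposures$spec, seed = NULL) {
  spec <- as_scenario_spec(spec)
  switch(spec$error_type,
    none = {
      if (!is.null(seed)) set.seed(seed)
      new_exposure_set(exposures$A, exposures$A, spec, seed)
    },
    classical = apply_classical_error(exposures, spec, seed),
    berkson = apply_berkson_error(exposures, spec, seed),
    mixture = apply_mixture_error(exposures, spec, seed),
    multiplicative = apply_multiplicative_error(exposures, spec, seed),
    stop("unknown error_type: ", spec$error_type)
  )
}

#' Dump an exposure set to CSV
#'
#' Columns: day, A_no2 (ppb), A_pm25 (ug/m3), C_no2, C_pm25.
#'
#' @param exposures an `exposure_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path) {
  df <- data.frame(day = exposures$days,
                   A_no2 = exposures$A[, "no2"],
                   A_pm25 = exposures$A[, "pm25"],
                   C_no2 = exposures$C[, "no2"],
                   C_pm25 = exposures$C[, "pm25"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
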