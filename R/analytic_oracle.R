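## Closed-form oracles: errors-in-variables attenuation and omitted-variable
## bias. These are probability limits for *linear* models on the
## natural-scale exposure covariances; with the study's small log-linear
## coefficients they predict the Monte-Carlo pipeline to within its noise
## and serve as its independent cross-check.

#' Classical-error attenuation prediction for the two-pollutant model
#'
#' Under classical error the two-pollutant regression estimates converge to
#' `lambda %*% beta` with reliability (attenuation) matrix
#' `lambda = solve(Sigma_A + Sigma_delta) %*% Sigma_A`. Off-diagonal
#' elements of `lambda` carry the effect transfer: with positively
#' correlated exposures, inflating one pollutant's error moves part of its
#' effect onto the better-measured co-pollutant. The single-pollutant
#' (omitted co-pollutant) limits under the same error are
#' `(Sigma_A %*% beta)[i] / (Sigma_A[i,i] + Sigma_delta[i,i])`.
#'
#' @param Sigma_A 2x2 positive-definite covariance of the true exposures
#'   (order NO2, PM2.5; see [natural_covariance()]).
#' @param Sigma_delta 2x2 positive semi-definite error covariance
#'   (see [error_covariance()]).
#' @param beta length-2 generating coefficients (NO2, PM2.5).
#' @return List of class `"bias_prediction"`: `lambda_matrix`,
#'   `predicted_coefs`, `predicted_single` (all named by pollutant).
#' @export
#' @examples
#' Sg <- natural_covariance(scenario_spec("europe", 0.5))
#' classical_attenuation(Sg, error_covariance(c(6.2, 5.2), 0.5),
#'                       c(no2 = 6e-4, pm25 = 5.4e-4))
classical_attenuation <- function(Sigma_A, Sigma_delta, beta) {
  check_cov2 <- function(S, name, strict) {
    stopifnot(is.matrix(S), all(dim(S) == 2))
    if (abs(S[1, 2] - S[2, 1]) > 1e-8 * (1 + max(abs(S)))) {
      stop(name, " must be symmetric")
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if ((strict && any(ev <= 0)) || (!strict && any(ev < -1e-10))) {
      stop(name, " must be positive ", if (strict) "definite" else
        "semi-definite")
    }
  }
  check_cov2(Sigma_A, "Sigma_A", strict = TRUE)
  check_cov2(Sigma_delta, "Sigma_delta", strict = FALSE)
  stopifnot(length(beta) == 2)
  tot <- Sigma_A + Sigma_delta
  if (abs(det(tot)) < 1e-12) stop("singular total covariance matrix")
  lambda <- solve(tot, Sigma_A)
  beta <- as.numeric(beta)
  predicted <- as.numeric(lambda %*% beta)
  single <- as.numeric(Sigma_A %*% beta) / (diag(Sigma_A) + diag(Sigma_delta))
  nm <- c("no2", "pm25")
  dimnames(lambda) <- list(nm, nm)
  structure(list(lambda_matrix = lambda,
                 predicted_coefs = stats::setNames(predicted, nm),
                 predicted_single = stats::setNames(single, nm)),
            class = "bias_prediction")
}

#' @export
print.bias_prediction <- function(x, ...) {
  cat("<bias_prediction>\nlambda:\n")
  print(round(x$lambda_matrix, 4))
  cat("predicted multi-pollutant coefs:",
      format(x$predicted_coefs, digits = 4), "\n")
  cat("predicted single-pollutant coefs:",
      format(x$predicted_single, digits = 4), "\n")
  invisible(x)
}

#' Omitted-variable bias of error-free single-pollutant models
#'
#' With no measurement error, dropping the co-pollutant inflates each
#' single-pollutant estimate to
#' `beta_i + beta_j * Cov(A_j, A_i) / Var(A_i)`.
#'
#' @param Sigma_A 2x2 positive-definite true-exposure covariance
#'   (NO2, PM2.5).
#' @param beta length-2 generating coefficients (NO2, PM2.5).
#' @return Named length-2 vector of predicted single-pollutant estimates.
#' @export
omitted_variable_bias <- function(Sigma_A, beta) {
  stopifnot(is.matrix(Sigma_A), all(dim(Sigma_A) == 2), length(beta) == 2)
  if (any(diag(Sigma_A) <= 0)) stop("zero exposure variance")
  beta <- as.numeric(beta)
  stats::setNames(c(
    beta[1] + beta[2] * Sigma_A[1, 2] / Sigma_A[1, 1],
    beta[2] + beta[1] * Sigma_A[1, 2] / Sigma_A[2, 2]
  ), c("no2", "pm25"))
}

#' Mixture-scenario covariance components
#'
#' Helper assembling, for one scenario, the covariance matrices implied by
#' the mixture generator (natural-scale mode): the latent series `L` (with
#' `Cov(L) = Sigma_A - Sigma_delta_b`), the Berkson component `delta_b` and
#' the classical component `delta_c`; the realized true-exposure covariance
#' is `Sigma_A = Sigma_L + Sigma_delta_b`, the scenario covariance exactly.
#' [classical_attenuation()] applied to `(Sigma_L, Sigma_delta_c)` predicts
#' the mixture-error multi-pollutant limits: the Berkson component drops
#' out of the probability limit because it is independent of `C`.
#'
#' @param spec a `scenario_spec` with `error_type = "mixture"`.
#' @return List with `Sigma_L`, `Sigma_delta_b`, `Sigma_delta_c` and
#'   `Sigma_A`.
#' @export
mixture_components <- function(spec) {
  spec <- as_scenario_spec(spec)
  Sigma_0 <- natural_covariance(spec)
  sd_err <- error_sds(spec)
  shares <- c(no2 = spec$mixture_frac_no2, pm25 = spec$mixture_frac_pm)
  rho <- rho_error_of(spec)
  Sigma_b <- error_covariance(sqrt(1 - shares) * sd_err, rho)
  Sigma_c <- error_covariance(sqrt(shares) * sd_err, rho)
  Sigma_L <- latent_covariance(Sigma_0, Sigma_b)
  dimnames(Sigma_L) <- dimnames(Sigma_0)
  list(Sigma_L = Sigma_L, Sigma_delta_b = Sigma_b, Sigma_delta_c = Sigma_c,
       Sigma_A = Sigma_L + Sigma_b)
}
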