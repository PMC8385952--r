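test_that("attenuation matrix has the right limits and guards", {
  Sg <- natural_covariance(europe_spec())
  beta <- c(6e-4, 5.4e-4)
  # no error: identity reliability, no bias
  bp0 <- classical_attenuation(Sg, matrix(0, 2, 2), beta)
  expect_equal(unname(bp0$lambda_matrix), diag(2), tolerance = 1e-12)
  expect_equal(unname(bp0$predicted_coefs), beta)
  expect_equal(unname(bp0$predicted_single),
               unname(omitted_variable_bias(Sg, beta)))
  # scalar reliability in the uncorrelated diagonal case
  Sd <- diag(c(0, 5.2^2))
  bp <- classical_attenuation(diag(c(8.9^2, 10.9^2)), Sd, beta)
  expect_equal(bp$lambda_matrix["pm25", "pm25"],
               10.9^2 / (10.9^2 + 5.2^2), tolerance = 1e-12)
  expect_equal(unname(bp$predicted_coefs[1]), beta[1])
  # guards
  expect_error(classical_attenuation(matrix(c(1, 2, 2, 1), 2), Sd, beta),
               "definite")
  expect_error(classical_attenuation(Sg, matrix(c(1, 2, 3, 4), 2), beta),
               "symmetric")
})

test_that("omitted-variable bias formula behaves at its boundaries", {
  beta <- c(6e-4, 5.4e-4)
  S0 <- diag(c(8.9^2, 10.9^2))
  expect_equal(unname(omitted_variable_bias(S0, beta)), beta)
  Sg <- natural_covariance(europe_spec())
  expect_equal(unname(omitted_variable_bias(Sg, c(6e-4, 0))[1]), 6e-4)
  ovb <- omitted_variable_bias(Sg, beta)
  expect_equal(unname(ovb["pm25"]),
               5.4e-4 + 6e-4 * 0.5 * 8.9 / 10.9)
  expect_error(omitted_variable_bias(diag(c(0, 1)), beta))
})

test_that("oracle agrees with a linear errors-in-variables simulation", {
  set.seed(77)
  sp <- europe_spec(rho_exposure = 0.25, rho_error = 0.25)
  Sg <- natural_covariance(sp)
  Sd <- error_covariance(error_sds(sp), 0.25)
  beta <- c(6e-4, 5.4e-4)
  n <- 5e4
  A <- matrix(rnorm(2 * n), n, 2) %*% chol(Sg)
  y <- as.vector(A %*% beta) + rnorm(n, sd = 0.05)
  C <- A + matrix(rnorm(2 * n), n, 2) %*% chol(Sd)
  bp <- classical_attenuation(Sg, Sd, beta)
  fit <- lm(y ~ C)
  expect_lt(max(abs(coef(fit)[2:3] - bp$predicted_coefs) /
                  sqrt(diag(vcov(fit))[2:3])), 3)
  # single-covariate limits, including the transfer orientation
  f1 <- lm(y ~ C[, 1])
  f2 <- lm(y ~ C[, 2])
  expect_lt(abs(coef(f1)[2] - bp$predicted_single[1]) /
              sqrt(diag(vcov(f1))[2]), 3)
  expect_lt(abs(coef(f2)[2] - bp$predicted_single[2]) /
              sqrt(diag(vcov(f2))[2]), 3)
})

test_that("oracle predicts the quasi-Poisson pipeline under classical error", {
  g <- build_grid(list(areas = "europe", rho_exposure = 0.5,
                       err_levels_pm = 1, err_levels_no2 = 1,
                       error_type = "classical"))
  run <- run_experiment(g, master_seed = 4, reps = 100, models = "multi",
                        sources = "error_prone")
  sp <- as_scenario_spec(g[1, ])
  bp <- classical_attenuation(natural_covariance(sp),
                              error_covariance(error_sds(sp),
                                               rho_error_of(sp)),
                              c(sp$beta_no2, sp$beta_pm))
  p <- pooled_multi(run)
  for (poll in c("no2", "pm25")) {
    expect_lt(abs(p[poll, "mean_coef"] - bp$predicted_coefs[poll] * 1e4),
              3 * pooled_se(p[poll, ]))
  }
})

test_that("mixture components predict the mixture-error pipeline", {
  sp <- europe_spec(error_type = "mixture")
  mc <- mixture_components(sp)
  # the components re-assemble the scenario covariance
  expect_equal(mc$Sigma_L + mc$Sigma_delta_b, natural_covariance(sp))
  expect_equal(unname(diag(mc$Sigma_delta_c + mc$Sigma_delta_b)),
               unname(error_sds(sp)^2))
  # infeasible cells are capped at the positive-definiteness boundary
  spx <- scenario_spec("europe", 0.75, err_level_pm = 0.1,
                       err_level_no2 = 1.3, error_type = "mixture")
  mcx <- mixture_components(spx)
  rl <- mcx$Sigma_L[1, 2] / sqrt(prod(diag(mcx$Sigma_L)))
  expect_lte(rl, 0.999)
  expect_true(all(eigen(mcx$Sigma_L, TRUE, TRUE)$values > 0))
  # Monte-Carlo agreement
  g <- build_grid(list(areas = "europe", rho_exposure = 0.5,
                       err_levels_pm = 1, err_levels_no2 = 1))
  run <- run_experiment(g, master_seed = 5, reps = 100, models = "multi",
                        sources = "error_prone")
  bp <- classical_attenuation(mc$Sigma_L, mc$Sigma_delta_c,
                              c(sp$beta_no2, sp$beta_pm))
  p <- pooled_multi(run)
  for (poll in c("no2", "pm25")) {
    expect_lt(abs(p[poll, "mean_coef"] - bp$predicted_coefs[poll] * 1e4),
              3 * pooled_se(p[poll, ]))
  }
})
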