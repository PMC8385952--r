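test_that("true exposure series matches the scenario moments", {
  sp <- europe_spec()
  ex <- simulate_true_exposures(sp, seed = 21)
  expect_equal(nrow(ex$A), 1461)
  expect_true(all(ex$A > 0))
  expect_identical(ex$A, ex$C)
  expect_true(all(ex$delta == 0))
  # sample means within 3 * sd/sqrt(T) of the area values
  expect_lt(abs(mean(ex$A[, "pm25"]) - 21.1), 3 * 10.9 / sqrt(1461))
  expect_lt(abs(mean(ex$A[, "no2"]) - 21.6), 3 * 8.9 / sqrt(1461))
  # long series nails the correlation
  exl <- simulate_true_exposures(europe_spec(n_days = 1e5), seed = 22)
  expect_equal(cor(exl$A[, 1], exl$A[, 2]), 0.5, tolerance = 0.02)
  expect_equal(apply(exl$A, 2, sd), c(no2 = 8.9, pm25 = 10.9),
               tolerance = 0.02)
  # bit-reproducible
  expect_identical(simulate_true_exposures(sp, seed = 21)$A, ex$A)
  # near-degenerate spread collapses to the means
  spd <- as_scenario_spec(modifyList(unclass(sp),
                                     list(sd_pm = 1e-6, sd_no2 = 1e-6)))
  exd <- simulate_true_exposures(spd, seed = 1)
  expect_lt(max(abs(exd$A[, "pm25"] - 21.1)), 1e-4)
})

test_that("classical error adds variance orthogonally to the truth", {
  sp <- europe_spec(n_days = 1e5)
  ex <- apply_classical_error(simulate_true_exposures(sp, seed = 31))
  # Var(C) = Var(A) + Var(delta), errors uncorrelated with truth
  expect_equal(var(ex$C[, "no2"]), 8.9^2 + 6.2^2, tolerance = 0.03)
  expect_equal(var(ex$C[, "pm25"]), 10.9^2 + 5.2^2, tolerance = 0.03)
  expect_lt(abs(cor(ex$delta[, "no2"], ex$A[, "no2"])), 3 / sqrt(1e5) * 1.5)
  # cross-pollutant error correlation follows rho_error (= rho_exposure here)
  expect_equal(cor(ex$delta[, 1], ex$delta[, 2]), 0.5, tolerance = 0.03)
  # explicit rho_error overrides
  sp0 <- europe_spec(n_days = 1e5, rho_error = 0)
  ex0 <- apply_classical_error(simulate_true_exposures(sp0, seed = 32))
  expect_lt(abs(cor(ex0$delta[, 1], ex0$delta[, 2])), 0.02)
  # zero error level leaves the series untouched
  spz <- europe_spec(err_level_pm = 0, err_level_no2 = 0)
  exz <- apply_classical_error(simulate_true_exposures(spz, seed = 33))
  expect_equal(exz$C, exz$A)
  # log-scale mode: multiplicative with SD calibrated at the exposure mean
  spl <- europe_spec(n_days = 1e5, error_mode = "additive_log")
  exl <- apply_classical_error(simulate_true_exposures(spl, seed = 34))
  expect_true(all(exl$C > 0))
  expect_equal(sd(exl$C[, "no2"] / exl$A[, "no2"]), 6.2 / 21.6,
               tolerance = 0.02)
  expect_lt(abs(cor(log(exl$C[, 1] / exl$A[, 1]), log(exl$A[, 1]))), 0.02)
})

test_that("Berkson error shrinks toward the mean; strict variant orthogonal", {
  sp <- europe_spec(n_days = 1e5, error_type = "berkson")
  exs <- apply_berkson_error(simulate_true_exposures(sp, seed = 41),
                             variant = "strict")
  for (p in c("no2", "pm25")) {
    # Cov(C, A - C) = 0 is the defining Berkson property
    r <- cor(exs$C[, p], exs$A[, p] - exs$C[, p])
    expect_lt(abs(r), 3 / sqrt(1e5) * 1.5)
    expect_lt(var(exs$C[, p]), var(exs$A[, p]))
  }
  exp_ <- apply_berkson_error(simulate_true_exposures(sp, seed = 42),
                              variant = "as_printed")
  # printed variant: Var(C) = lambda^2 sigma_A^2 + lambda sigma_d^2
  v_a <- 8.9^2; v_d <- 6.2^2; v_c <- v_a + v_d
  lam <- v_c / (v_c + v_d)
  expect_equal(var(exp_$C[, "no2"]), lam^2 * v_a + lam * v_d,
               tolerance = 0.03)
  expect_lt(var(exp_$C[, "no2"]), var(exp_$A[, "no2"]))
  # vanishing error returns the truth
  spt <- europe_spec(err_level_pm = 1e-6, err_level_no2 = 1e-6,
                     error_type = "berkson")
  ext <- apply_berkson_error(simulate_true_exposures(spt, seed = 43))
  expect_equal(ext$C, ext$A, tolerance = 1e-4)
})

test_that("mixture construction partitions the error variance", {
  sp <- europe_spec(n_days = 1e5, error_type = "mixture")
  ex <- apply_mixture_error(simulate_true_exposures(sp, seed = 51))
  mx <- ex$mixture
  # construction identities hold exactly
  expect_equal(ex$A, mx$L + mx$delta_b)
  expect_equal(ex$C, mx$L + mx$delta_c)
  expect_equal(ex$delta, ex$C - ex$A)
  # variance partition: classical share of total error variance
  share <- c(no2 = 0.33, pm25 = 0.43)
  tot <- error_sds(sp)^2
  for (p in c("no2", "pm25")) {
    expect_equal(var(mx$delta_c[, p]) /
                   (var(mx$delta_b[, p]) + var(mx$delta_c[, p])),
                 unname(share[p]), tolerance = 0.03)
    expect_equal(var(ex$delta[, p]), unname(tot[p]), tolerance = 0.03)
  }
  # the redefined A keeps the scenario moments, including the covariance
  expect_equal(colMeans(ex$A), c(no2 = 21.6, pm25 = 21.1), tolerance = 0.01)
  expect_equal(cov(ex$A)[1, 2], 0.5 * 8.9 * 10.9, tolerance = 0.05)
  expect_equal(apply(ex$A, 2, sd), c(no2 = 8.9, pm25 = 10.9),
               tolerance = 0.02)
  # boundary shares: all classical leaves A untouched ...
  sp1 <- europe_spec(error_type = "mixture", mixture_frac_pm = 1,
                     mixture_frac_no2 = 1)
  base <- simulate_true_exposures(sp1, seed = 52)
  ex1 <- apply_mixture_error(base)
  expect_equal(ex1$A, base$A, tolerance = 1e-8)
  expect_equal(max(abs(ex1$mixture$delta_b)), 0)
  # ... all Berkson makes C the noise-free latent
  sp0 <- europe_spec(error_type = "mixture", mixture_frac_pm = 0,
                     mixture_frac_no2 = 0)
  ex0 <- apply_mixture_error(simulate_true_exposures(sp0, seed = 53))
  expect_equal(max(abs(ex0$mixture$delta_c)), 0)
  expect_equal(ex0$C, ex0$mixture$L)
  # shares outside [0, 1] rejected
  expect_error(scenario_spec("europe", mixture_frac_no2 = -0.1))
})

test_that("multiplicative noise is mean-one and erodes the log correlation", {
  sp <- europe_spec(n_days = 1e5, error_type = "multiplicative")
  ex <- apply_multiplicative_error(simulate_true_exposures(sp, seed = 61))
  eps <- ex$C / ex$A
  expect_true(all(ex$C > 0))
  expect_lt(abs(mean(eps[, "no2"]) - 1), 3 * sd(eps[, "no2"]) / sqrt(1e5))
  # log-correlation with the truth decreases as the error SD grows
  cors <- sapply(c(0.5, 1, 1.3), function(lv) {
    spi <- europe_spec(n_days = 2e4, error_type = "multiplicative",
                       err_level_pm = lv, err_level_no2 = lv)
    exi <- apply_multiplicative_error(simulate_true_exposures(spi, seed = 62))
    cor(log(exi$C[, "no2"]), log(exi$A[, "no2"]))
  })
  expect_true(all(diff(cors) < 0))
  expect_true(all(cors < 1))
  # interpreting the natural-unit SD on the log scale all but destroys it
  sph <- europe_spec(n_days = 2e4, error_type = "multiplicative",
                     mult_calibration = "log_sd")
  exh <- apply_multiplicative_error(simulate_true_exposures(sph, seed = 63))
  expect_lt(cor(log(exh$C[, "no2"]), log(exh$A[, "no2"])), 0.2)
})

test_that("error covariance matrix is assembled correctly", {
  expect_equal(unname(error_covariance(c(6.2, 5.2), 0)),
               diag(c(38.44, 27.04)))
  expect_equal(error_covariance(c(6.2, 5.2), 0.5)[1, 2], 16.12)
  expect_equal(error_covariance(c(0, 5.2), 0.7)[1, 2], 0)
  expect_error(error_covariance(c(1, 1), 1))
  expect_error(error_covariance(c(-1, 1), 0))
})

test_that("the error dispatcher honors the scenario error type", {
  sp <- europe_spec(error_type = "none")
  ex <- apply_error(simulate_true_exposures(sp, seed = 71))
  expect_identical(ex$A, ex$C)
  for (et in c("classical", "berkson", "mixture", "multiplicative")) {
    spi <- europe_spec(error_type = et)
    exi <- apply_error(simulate_true_exposures(spi, seed = 72), seed = 73)
    expect_false(identical(exi$A, exi$C))
    exj <- apply_error(simulate_true_exposures(spi, seed = 72), seed = 73)
    expect_identical(exi$C, exj$C)  # reproducible given the seed
  }
})
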