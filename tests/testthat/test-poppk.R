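test_that("macro-model predictions match structural limits and a quadrature oracle", {
  pars <- list(A = 140, B = 1.4, alpha = 1.2, beta = 0.103, ka = 12,
               dose_ref = 145803)
  # C(0) = 0 by construction
  expect_equal(predict_macro_model(pars, 145803, 0), 0)
  # decays to zero
  expect_lt(predict_macro_model(pars, 145803, 500), 1e-10)
  # Ka -> infinity limit: pure biexponential disposition
  pars_inst <- modifyList(pars, list(ka = 1e9))
  tt <- c(0.5, 2, 8, 24)
  expect_equal(predict_macro_model(pars_inst, 145803, tt),
               140 * exp(-1.2 * tt) + 1.4 * exp(-0.103 * tt),
               tolerance = 1e-9)

  # quadrature oracle: first-order absorption input convolved with the
  # disposition kernel implied by the macro constants
  G <- c(pars$A, pars$B) * (pars$ka - c(pars$alpha, pars$beta)) /
    (pars$ka * pars$dose_ref)
  tt20 <- seq(0.1, 30, length.out = 20)
  num <- sapply(tt20, function(t) {
    stats::integrate(function(tau) {
      pars$dose_ref * pars$ka * exp(-pars$ka * tau) *
        (G[1] * exp(-pars$alpha * (t - tau)) + G[2] * exp(-pars$beta * (t - tau)))
    }, 0, t, rel.tol = 1e-12)$value
  })
  expect_equal(predict_macro_model(pars, pars$dose_ref, tt20), num,
               tolerance = 1e-9)
})

test_that("noise-free synthetic data recover the generating parameters", {
  cfg <- bolus_sim_config(sigma = 0, seed = 5)
  s <- generate_bolus_study(cfg)
  f <- fit_macro_model(s, macro_model_spec(2, "multiplicative"))
  expect_true(f$converged)
  expect_equal(f$alpha, 1.2, tolerance = 1e-3)
  expect_equal(f$beta, 0.103, tolerance = 1e-3)
  expect_equal(f$ka, 12, tolerance = 1e-3)
  u <- derive_uir(f)
  expect_equal(u$coefficients, c(9.8e-4, 9.6e-6), tolerance = 1e-3)
  # diagnostics: raw residuals vanish, one row per quantifiable observation
  # (weighted residuals are scaled by the profiled sigma, so they stay O(1))
  d <- model_diagnostics(f, s)
  expect_equal(nrow(d$residuals), sum(!s$observations$blq))
  expect_lt(max(abs(d$residuals$residual / d$residuals$observed)), 1e-6)
})

test_that("1-compartment fit of monoexponential data matches the log-linear oracle", {
  # instantaneous-absorption-like data: very fast ka truth
  u1 <- uir(5e-4, 0.2)
  cfg <- bolus_sim_config(true_uir = u1, ka = 50, sigma = 0, seed = 6,
                          timepoints = c(0.5, 1, 2, 4, 8, 24))
  s <- generate_bolus_study(cfg)
  f <- fit_macro_model(s, macro_model_spec(1, "multiplicative"))
  # oracle: log-linear regression on late dose-normalised values
  obs <- s$observations[!s$observations$blq & s$observations$time >= 1, ]
  dose <- s$doses$absolute_dose_ng[match(obs$animal_id, s$doses$animal_id)]
  sl <- -coef(lm(log(obs$value / dose) ~ obs$time))[[2]]
  expect_equal(f$alpha, sl, tolerance = 1e-3)
})

test_that("error-model likelihoods are exact for hand-computed residuals", {
  s <- tiny_bolus_study()
  obs <- s$observations
  dose <- s$doses$absolute_dose_ng[match(obs$animal_id, s$doses$animal_id)]
  nll <- implantpk:::.make_nll(obs$time, obs$value, dose, mean(dose), 2,
                               "additive")
  theta <- log(c(2e-4, 1e-5, 1.0, 0.1, 10) * c(mean(dose), mean(dose), 1, 1, 1) /
                 c(1, 1, 1, 1, 1))
  # oracle: direct normal log-likelihood with profiled sigma
  p <- exp(theta)
  pars <- list(A = p[1], B = p[2], alpha = p[3], beta = p[4], ka = p[5],
               dose_ref = mean(dose))
  f <- predict_macro_model(pars, dose, obs$time)
  s2 <- mean((obs$value - f)^2)
  expect_equal(nll(theta),
               -sum(dnorm(obs$value, f, sqrt(s2), log = TRUE)),
               tolerance = 1e-10)
  # log-additive likelihood includes the Jacobian of the log transform
  nll_log <- implantpk:::.make_nll(obs$time, obs$value, dose, mean(dose), 2,
                                   "log_additive")
  s2l <- mean((log(obs$value) - log(f))^2)
  expect_equal(nll_log(theta),
               -sum(dnorm(log(obs$value), log(f), sqrt(s2l), log = TRUE)) +
                 sum(log(obs$value)),
               tolerance = 1e-10)
})

test_that("model selection ranks by AIC and demotes failed candidates", {
  s <- generate_bolus_study(bolus_sim_config(sigma = 0.1, seed = 9))
  f2 <- fit_macro_model(s, macro_model_spec(2, "multiplicative"))
  f1 <- fit_macro_model(s, macro_model_spec(1, "multiplicative"))
  sel <- select_model(list(f1, f2))
  # 2-compartment truth: richer model wins on AIC and log-likelihood
  expect_equal(sel$selected$n_compartments, 2)
  expect_lt(f2$aic, f1$aic)
  expect_gt(f2$loglik, f1$loglik)  # nested models: fuller fit dominates

  # a non-converged candidate ranks last regardless of AIC
  f_bad <- f2
  f_bad$converged <- FALSE
  f_bad$aic <- -1e6
  sel2 <- select_model(list(f_bad, f1, f2))
  expect_equal(utils::tail(sel2$table$converged, 1), FALSE)
  # all failed: informative error
  f1_bad <- f1; f1_bad$converged <- FALSE
  expect_error(select_model(list(f_bad, f1_bad)), "no candidate")
})

test_that("weighted residuals are correctly scaled under multiplicative noise", {
  cfg <- bolus_sim_config(sigma = 0.2, animals_per_timepoint = 24, seed = 13)
  s <- generate_bolus_study(cfg)
  f <- fit_macro_model(s, macro_model_spec(2, "multiplicative"))
  d <- model_diagnostics(f, s)
  # scale-free spread check: IQR within [0.8, 1.8] x the standard normal IQR
  iqr <- diff(quantile(d$residuals$weighted_residual, c(0.25, 0.75)))
  expect_gt(iqr, 0.8 * 1.349)
  expect_lt(iqr, 1.8 * 1.349)
})

test_that("UIR derivation is macro constants over average dose", {
  f <- structure(list(n_compartments = 2, A = 142.89, B = 1.4,
                      alpha = 1.2, beta = 0.103, ka = 12, dose_ref = 145803),
                 class = "macro_model_fit")
  u <- derive_uir(f, 145803)
  expect_equal(u$coefficients[1], 9.8e-4, tolerance = 1e-3)
  expect_equal(u$rates, c(1.2, 0.103))
  # average_dose = 1: UIR equals the macro constants
  u1 <- derive_uir(f, 1)
  expect_equal(u1$coefficients, c(142.89, 1.4))
  # doubling the dose halves the coefficients, leaves rates unchanged
  u2 <- derive_uir(f, 2 * 145803)
  expect_equal(u2$coefficients, u$coefficients / 2)
  expect_equal(u2$rates, u$rates)
  # 1-compartment fit: single-exponential UIR with a warning
  f1 <- structure(list(n_compartments = 1, A = 100, B = NA_real_, alpha = 0.2,
                       beta = NA_real_, ka = 12, dose_ref = 1e5),
                  class = "macro_model_fit")
  expect_warning(u3 <- derive_uir(f1), "single exponential")
  expect_length(u3$rates, 1)
})

test_that("the UIR integral and the absorption-drop approximation hold", {
  u <- default_uir()
  # analytic integral equals numeric quadrature of the kernel
  num <- stats::integrate(function(t) eval_uir(u, t), 0, Inf,
                          rel.tol = 1e-12)$value
  expect_equal(uir_auc(u), num, tolerance = 1e-9)
  # dropping the absorption exponential changes predictions < 1% once the
  # absorption phase has decayed (within ~half an hour at Ka = 12 1/h)
  ka <- 12
  tt <- seq(6 / ka, 24, length.out = 50)
  with_abs <- eval_uir(u, tt) - sum(u$coefficients) * exp(-ka * tt)
  without <- eval_uir(u, tt)
  expect_lt(max(abs(with_abs - without) / without), 0.01)
})

test_that("rate constants are recovered across replicate sparse studies", {
  # 50 simulated studies at the fitting module's simulation condition
  # (multiplicative CV 20%): median relative error of alpha and beta < 15%
  errs <- sapply(1:50, function(i) {
    s <- generate_bolus_study(bolus_sim_config(sigma = 0.2, seed = 7000 + i))
    f <- fit_macro_model(s, macro_model_spec(2, "multiplicative"), n_starts = 3)
    c(abs(f$alpha - 1.2) / 1.2, abs(f$beta - 0.103) / 0.103)
  })
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.15)
})

test_that("BLQ likelihood-censoring option runs and keeps estimates close", {
  s <- generate_bolus_study(bolus_sim_config(sigma = 0.3, seed = 31))
  f_ex <- fit_macro_model(s, macro_model_spec(2, "multiplicative"),
                          blq = "exclude")
  f_ce <- fit_macro_model(s, macro_model_spec(2, "multiplicative"),
                          blq = "censor")
  expect_true(f_ce$converged)
  expect_equal(f_ce$alpha, f_ex$alpha, tolerance = 0.2)
})
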