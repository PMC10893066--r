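test_that("bolus design arithmetic and seed determinism hold", {
  s <- generate_bolus_study(bolus_sim_config(seed = 11))
  expect_equal(nrow(s$observations), 3 * 7 * 3)  # doses x timepoints x animals
  expect_equal(nrow(s$doses), 63)
  # destructive sampling: one observation per animal
  expect_equal(anyDuplicated(s$observations$animal_id), 0)

  s2 <- generate_bolus_study(bolus_sim_config(seed = 11))
  expect_identical(s$observations, s2$observations)
  expect_identical(s$doses, s2$doses)
  s3 <- generate_bolus_study(bolus_sim_config(seed = 12))
  expect_false(identical(s$observations$value, s3$observations$value))
})

test_that("noise-free bolus observations equal the deterministic model", {
  cfg <- bolus_sim_config(sigma = 0, seed = 2)
  s <- generate_bolus_study(cfg)
  u <- cfg$true_uir
  dose <- s$doses$absolute_dose_ng[match(s$observations$animal_id,
                                         s$doses$animal_id)]
  pred <- dose * (eval_uir(u, s$observations$time) -
                    sum(u$coefficients) * exp(-cfg$ka * s$observations$time))
  expect_equal(s$observations$value, pred, tolerance = 1e-12)
})

test_that("multiplicative noise realizes the nominal CV", {
  set.seed(99)
  x <- multiplicative_noise(10000, 0.76)
  cv <- sd(x) / mean(x)
  expect_lt(abs(cv - 0.76), 0.03)
  expect_true(all(x > 0))
  # the truncated proportional variant stays positive too
  set.seed(99)
  y <- multiplicative_noise(10000, 0.76, "proportional_truncated")
  expect_true(all(y > 0))
})

test_that("BLQ fraction is non-decreasing in the LLOQ", {
  fr <- sapply(c(0.05, 0.5, 2, 10), function(l) {
    s <- generate_bolus_study(bolus_sim_config(lloq = l, seed = 21))
    mean(s$observations$blq)
  })
  expect_true(all(diff(fr) >= 0))
})

test_that("implant design arithmetic: 10 animals x 11 post-dose samples", {
  s <- generate_implant_study(implant_sim_config(seed = 5))
  post <- s$observations[s$observations$time > 0, ]
  expect_equal(nrow(post), 110)
  expect_equal(sort(unique(post$time)), seq(14, 154, by = 14))
  # day-0 predose anchors are BLQ
  d0 <- s$observations[s$observations$time == 0, ]
  expect_equal(nrow(d0), 10)
  expect_true(all(d0$blq))
  expect_setequal(unique(post$group), c("isl_only", "isl_plus"))
})

test_that("noise-free implant concentrations match the convolution oracle", {
  cfg <- implant_sim_config(sigma = 0, seed = 8)
  s <- generate_implant_study(cfg)
  days <- seq(14, 154, by = 14)
  # oracle: staircase convolution with a single constant-rate interval
  rate_ngh <- cfg$true_release$rate * 1e6 / 24
  oracle <- convolve_input(cfg$true_uir, c(0, 154 * 24), rate_ngh, days * 24)
  for (id in unique(s$observations$animal_id)) {
    v <- s$observations$value[s$observations$animal_id == id &
                                s$observations$time > 0]
    expect_equal(v, oracle, tolerance = 1e-10)
  }
})

test_that("late constant-rate concentrations approach the steady state", {
  u <- default_uir()
  cfg <- implant_sim_config(sigma = 0, duration = 300, sampling_interval = 30,
                            true_release = list(model = "zero", rate = 0.072),
                            seed = 3)
  s <- generate_implant_study(cfg)
  css <- (0.072 * 1e6 / 24) * uir_auc(u)  # R * sum(Ai/alpha_i)
  late <- s$observations$value[s$observations$time == 300]
  expect_equal(unique(round(late, 10)), round(css, 10), tolerance = 1e-6)
})

test_that("exact closed forms hold for first-order, Higuchi and power release", {
  u <- default_uir()
  days <- c(10, 50, 154)
  # oracle by adaptive quadrature on the convolution integral (hours)
  quad_oracle <- function(rate_ngh_fun, t_h) {
    sapply(t_h, function(t) {
      stats::integrate(function(s) rate_ngh_fun(t - s) *
                         drop(exp(-outer(s, u$rates)) %*% u$coefficients),
                       0, t, rel.tol = 1e-11)$value
    })
  }
  # first-order, K = 0.01 1/day, load 98.6 mg
  relF <- list(model = "first", K = 0.01)
  cF <- implantpk:::.conc_from_release(u, relF, days * 24, 98.6)
  oF <- quad_oracle(function(tau) 98.6e6 * (0.01 / 24) * exp(-(0.01 / 24) * tau),
                    days * 24)
  expect_equal(cF, oF, tolerance = 1e-8)
  # Higuchi, K = 0.6 mg/day^0.5
  relH <- list(model = "higuchi", K = 0.6)
  cH <- implantpk:::.conc_from_release(u, relH, days * 24, 98.6)
  oH <- quad_oracle(function(tau) 0.5 * 0.6e6 / sqrt(24) / sqrt(pmax(tau, 1e-12)),
                    days * 24)
  expect_equal(cH, oH, tolerance = 1e-7)
  # power law, n = 1.3
  relP <- list(model = "power", K = 5e-4, n = 1.3)
  cP <- implantpk:::.conc_from_release(u, relP, days * 24, 98.6)
  cmass <- 98.6e6 * 5e-4 / 24^1.3
  oP <- quad_oracle(function(tau) cmass * 1.3 * pmax(tau, 0)^0.3, days * 24)
  expect_equal(cP, oP, tolerance = 1e-8)
})

test_that("release laws exceeding the loaded dose are rejected", {
  expect_error(implant_sim_config(true_release = list(model = "zero", rate = 1)),
               "exceeding")
  expect_error(implant_sim_config(true_release = list(model = "power",
                                                      K = 0.1, n = 1)),
               "exceeding")
  # saturating first-order can never exceed the load
  expect_s3_class(implant_sim_config(true_release = list(model = "first", K = 0.5)),
                  "implant_sim_config")
})

test_that("metabolite simulator follows the indirect-response closed forms", {
  # parent impulse e^(-ka t): Bateman curve with analytic Tmax
  ka <- 2; k <- 0.5
  tt <- seq(0.01, 10, by = 0.001)
  m <- simulate_metabolite_profile(data.frame(coef = 1, rate = ka), tt,
                                   k_in = k, k_out = k, scale = 1)
  tmax_analytic <- log(ka / k) / (ka - k)
  expect_equal(tt[which.max(m)], tmax_analytic, tolerance = 1e-3)

  # k_out -> infinity: metabolite proportional to the parent curve
  parent <- data.frame(coef = c(5, 1), rate = c(1.2, 0.1))
  tt2 <- c(1, 2, 5, 10)
  cp <- drop(exp(-outer(tt2, parent$rate)) %*% parent$coef)
  m2 <- simulate_metabolite_profile(parent, tt2, k_in = 1, k_out = 1e6, scale = 1)
  expect_equal(m2 * 1e6, cp, tolerance = 1e-4)

  # zero gain: all-zero metabolite, flagged BLQ by the study wrapper
  s <- generate_bolus_study(bolus_sim_config(sigma = 0, seed = 1))
  s <- add_metabolite_observations(s, scale = 0, sigma = 0)
  met <- s$observations[s$observations$analyte == "pbmc_triphosphate", ]
  expect_true(all(met$value == 0))
  expect_true(all(met$blq))
})

test_that("metabolite Tmax in the study wrapper is later than parent Tmax", {
  s <- add_metabolite_observations(
    generate_bolus_study(bolus_sim_config(sigma = 0, seed = 1)), sigma = 0)
  obs <- beal_m2_censor(s$observations)
  parent <- pool_sparse_profile(obs, group = "bolus_high", analyte = "plasma_parent")
  met <- pool_sparse_profile(obs, group = "bolus_high",
                             analyte = "pbmc_triphosphate")
  tmax_parent <- parent$time[which.max(parent$mean_conc)]
  tmax_met <- met$time[which.max(met$mean_conc)]
  expect_gt(tmax_met, tmax_parent)
  expect_true(tmax_met >= 2 && tmax_met <= 4)
})
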