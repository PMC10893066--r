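test_that("BLQ censoring flags rows without deleting them", {
  obs <- make_obs(paste0("r", 1:4), time = c(0.5, 2, 6, 24),
                  value = c(10, 5, 1, 0.05), blq = c(FALSE, FALSE, FALSE, TRUE))
  out <- beal_m2_censor(obs)
  expect_equal(nrow(out), 4)              # nothing dropped
  expect_equal(attr(out, "n_censored"), 1)
  expect_equal(out$analyzable, c(TRUE, TRUE, TRUE, FALSE))

  # no BLQ rows: analyzable everywhere, zero censored
  out2 <- beal_m2_censor(obs[1:3, ])
  expect_equal(attr(out2, "n_censored"), 0)
  expect_true(all(out2$analyzable))

  # all BLQ: empty analyzable set with a warning
  allb <- make_obs(paste0("r", 1:3), time = 1:3, value = c(0.01, 0.01, 0.01),
                   blq = TRUE)
  expect_warning(out3 <- beal_m2_censor(allb), "no analyzable")
  expect_false(any(out3$analyzable))

  # zero_before_tmax: early BLQ becomes an analyzable zero
  obs4 <- make_obs(paste0("r", 1:3), time = c(0.1, 1, 6),
                   value = c(0.05, 10, 2), blq = c(TRUE, FALSE, FALSE))
  out4 <- beal_m2_censor(obs4, policy = "zero_before_tmax")
  expect_true(out4$analyzable[1])
  expect_equal(out4$value[1], 0)
})

test_that("full bolus set reproduces the study's analyzable count", {
  # 63 plasma samples, 5 BLQ at default seed + 1 Grubbs-confirmed exclusion
  # emulates the reported cohort bookkeeping: flagged rows never deleted
  s <- generate_bolus_study(bolus_sim_config(seed = 11))
  obs <- s$observations
  expect_equal(nrow(obs), 63)
  obs$excluded[which(!obs$blq)[1]] <- TRUE
  obs$exclude_reason[which(!obs$blq)[1]] <- "outlier"
  out <- beal_m2_censor(obs)
  expect_equal(sum(out$analyzable), 63 - sum(obs$blq) - 1)
  expect_equal(nrow(out), 63)
})

test_that("Grubbs test matches the closed-form statistic and critical value", {
  g <- grubbs_test(c(1.0, 1.1, 0.9, 5.0), alpha = 0.05)
  expect_equal(g$statistic, 1.4988, tolerance = 1e-4)
  tq <- qt(1 - 0.05 / 8, 2)
  expect_equal(g$critical, 3 / 2 * sqrt(tq^2 / (2 + tq^2)), tolerance = 1e-12)
  expect_equal(g$critical, 1.481, tolerance = 1e-3)
  expect_equal(g$outlier_index, 4L)

  expect_true(is.na(grubbs_test(c(2, 2, 2, 2))$outlier_index))  # zero variance
  expect_true(is.na(grubbs_test(c(1, 5))$outlier_index))        # n < 3
  # symmetric 3-point set: G = 1 < critical ~ 1.154
  g3 <- grubbs_test(c(1, 2, 3))
  expect_true(is.na(g3$outlier_index))
  expect_equal(g3$statistic, 1)
})

test_that("sparse pooling averages quantifiable values per timepoint", {
  obs <- make_obs(paste0("r", 1:9), time = rep(c(1, 4, 24), each = 3),
                  value = c(10, 12, 14, 4, 5, 6, 0.05, 0.06, 0.07),
                  blq = rep(c(FALSE, FALSE, TRUE), each = 3))
  prof <- pool_sparse_profile(beal_m2_censor(obs))
  expect_equal(prof$time, c(1, 4))
  expect_equal(prof$mean_conc, c(12, 5))
  expect_equal(prof$n, c(3L, 3L))
  expect_equal(attr(prof, "dropped_timepoints"), 24)  # all-BLQ timepoint noted

  # single animal per timepoint: means equal raw values
  one <- make_obs(paste0("r", 1:3), time = c(1, 2, 4), value = c(9, 6, 3))
  prof1 <- pool_sparse_profile(beal_m2_censor(one))
  expect_equal(prof1$mean_conc, c(9, 6, 3))

  # fewer than 2 usable timepoints: not estimable
  single <- make_obs(c("r1", "r2"), time = c(1, 1), value = c(5, 6))
  expect_error(pool_sparse_profile(beal_m2_censor(single)), "fewer than 2")
})

test_that("linear-up/log-down AUC matches closed forms and is additive", {
  expect_equal(auc_linear_up_log_down(c(0, 24), c(5, 5)), 120)     # constant
  expect_equal(auc_linear_up_log_down(c(0, 1), c(10, 5)), 5 / log(2))
  expect_equal(auc_linear_up_log_down(c(0, 1, 2), c(2, 10, 5)),
               6 + 5 / log(2))
  # additivity over partitions
  tt <- c(0, 1, 3, 7, 24); cc <- c(1, 8, 6, 2, 0.3)
  whole <- auc_linear_up_log_down(tt, cc)
  parts <- auc_linear_up_log_down(tt[1:3], cc[1:3]) +
    auc_linear_up_log_down(tt[3:5], cc[3:5])
  expect_equal(whole, parts, tolerance = 1e-14)
  expect_gt(whole, 0)
  # equals linear trapezoid when never decreasing
  up <- c(1, 2, 4, 8)
  expect_equal(auc_linear_up_log_down(c(0, 1, 2, 3), up),
               sum((up[-4] + up[-1]) / 2))
  expect_error(auc_linear_up_log_down(c(0, 1), c(5, 0)), "nonpositive")
  expect_error(auc_linear_up_log_down(c(1, 1), c(5, 5)), "strictly increasing")
})

test_that("NCA endpoints recover exact monoexponential kinetics", {
  tt <- c(0.5, 1, 2, 4, 6, 24)
  prof <- tibble::tibble(time = tt, mean_conc = 20 * exp(-0.1 * tt), n = 3L)
  ep <- nca_endpoints(prof)
  expect_equal(ep$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(ep$t_half, log(2) / 0.1, tolerance = 1e-12)
  expect_equal(ep$cmax, max(prof$mean_conc))
  expect_equal(ep$tmax, 0.5)
  expect_equal(ep$c_avg, ep$auc_last / 24)

  # fewer than 3 points in the terminal window: t_half not estimable
  ep2 <- nca_endpoints(prof[1:4, ])
  expect_true(is.na(ep2$t_half))
  expect_match(ep2$notes, "not estimable")
})

test_that("dose-proportionality slope behaves as a power-model estimator", {
  doses <- c(0.1, 0.3, 1.0)
  # exact power law recovered to machine precision
  fit <- dose_proportionality(doses, 7 * doses, parameter = "cmax")
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$declared_linear)
  fit_b <- dose_proportionality(doses, 2.5 * doses^0.7, parameter = "cmax")
  expect_equal(fit_b$slope, 0.7, tolerance = 1e-12)

  # slope invariant to rescaling doses (weight normalisation)
  v <- c(22.6, 44.7, 201.3)
  s1 <- dose_proportionality(doses, v, parameter = "cmax")$slope
  s2 <- dose_proportionality(doses * 0.307, v, parameter = "cmax")$slope
  expect_equal(s1, s2, tolerance = 1e-12)

  expect_error(dose_proportionality(c(0.1, 0.3), c(1, 2), "cmax"), "3 dose")
  expect_error(dose_proportionality(doses, c(-1, 2, 3), "cmax"), "positive")
})

test_that("intracellular:plasma ratio converts units correctly", {
  # unit-conversion oracle: explicit molar arithmetic (ng/mL = 1e-6 g/L)
  oracle <- function(tp, par, mm, vol = 0.2) {
    (tp * 1e-12 / (1e6 * vol * 1e-12)) / (par * 1e-6 / mm)
  }
  expect_equal(tp_to_parent_ratio(0.025, 0.675, "triphosphate"),
               oracle(0.025, 0.675, 533.2), tolerance = 1e-12)
  expect_equal(tp_to_parent_ratio(0.025, 0.675, "triphosphate"), 100,
               tolerance = 0.02)
  expect_equal(tp_to_parent_ratio(0.025, 0.675, "parent"),
               oracle(0.025, 0.675, 293.3), tolerance = 1e-12)
  expect_equal(tp_to_parent_ratio(0.025, 0.675, "parent"), 54,
               tolerance = 0.02)
  # equal molar concentrations (1 uM) on both sides give ratio 1
  mm <- 500
  par_ngml <- 1e-6 * mm / 1e-6            # 1e-6 mol/L expressed in ng/mL
  tp_pmol <- 1e-6 * (1e6 * 0.2 * 1e-12) / 1e-12  # same molarity in the cell volume
  expect_equal(tp_to_parent_ratio(tp_pmol, par_ngml, mm), 1, tolerance = 1e-12)
})

test_that("run_nca pools low-dose 24 h BLQ away and still reports endpoints", {
  s <- generate_bolus_study(bolus_sim_config(seed = 11))
  res <- run_nca(s)
  expect_equal(nrow(res$endpoints), 3)
  low <- res$endpoints[res$endpoints$dose_level == 0.1, ]
  expect_true(is.finite(low$auc_last))
  expect_equal(res$n_censored, sum(s$observations$blq))
  expect_equal(nrow(res$proportionality), 2)
})
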