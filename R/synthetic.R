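# Synthetic study generator: emulates the two preclinical designs the
# pipeline analyses (sparse SC bolus dose-ranging; serial implant sampling)
# so every downstream stage is testable without animal data.

#' Configuration for the synthetic SC bolus dose-ranging study
#'
#' Defaults reproduce the rat study design the analysis assumes: three dose
#' levels (0.1/0.3/1 mg/kg), destructive sparse sampling at 0.17, 0.5, 1, 2,
#' 4, 6 and 24 h with 3 animals per timepoint per dose (one sample per
#' animal), body weight 0.307 +/- 0.02 kg, biexponential disposition with
#' fast first-order absorption (Ka = 12 1/h), ~76% multiplicative residual
#' error, and an assay LLOQ of 0.1 ng/mL.
#'
#' @param dose_levels mg/kg dose levels.
#' @param mean_weight,sd_weight Body weight distribution, kg. Draws are
#'   clipped at +/- 3 SD.
#' @param timepoints Sampling times, hours, strictly increasing.
#' @param animals_per_timepoint Animals sampled (destructively) per
#'   timepoint per dose level.
#' @param true_uir Disposition kernel used as simulation truth, a [uir()].
#' @param ka First-order absorption rate, 1/h.
#' @param error_model `"lognormal"` (default: multiplicative noise with
#'   exact coefficient of variation `sigma`, mean-unbiased) or
#'   `"proportional_truncated"` (`C*(1+eps)`, `eps ~ N(0, sigma^2)`
#'   truncated to keep concentrations positive).
#' @param sigma Residual error magnitude as a CV fraction (0.76 = 76%).
#' @param lloq Lower limit of quantification, ng/mL; draws below it are
#'   flagged BLQ (retained, not dropped).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A list of class `bolus_sim_config`.
#' @export
bolus_sim_config <- function(dose_levels = c(0.1, 0.3, 1.0),
                             mean_weight = 0.307, sd_weight = 0.02,
                             timepoints = c(0.17, 0.5, 1, 2, 4, 6, 24),
                             animals_per_timepoint = 3,
                             true_uir = default_uir(),
                             ka = 12,
                             error_model = c("lognormal", "proportional_truncated"),
                             sigma = 0.76,
                             lloq = 0.1,
                             seed = 20240201L) {
  error_model <- match.arg(error_model)
  stopifnot(all(dose_levels > 0), mean_weight > 0, sd_weight >= 0,
            all(diff(timepoints) > 0), all(timepoints >= 0),
            animals_per_timepoint >= 1, inherits(true_uir, "uir"),
            ka > 0, sigma >= 0, lloq > 0)
  structure(as.list(environment()), class = "bolus_sim_config")
}

#' Configuration for the synthetic implant study
#'
#' Defaults emulate the published implant cohort the deconvolution targets:
#' 10 rats, serial plasma sampling in 14-day increments to day 154 (11
#' scheduled post-dose samples), loaded dose 98.6 +/- 3.31 mg, and
#' near-constant (zero-order) release of 0.072 mg/day. Day-0 records are
#' generated as predose BLQ rows so deconvolution has a defined zero anchor.
#'
#' @param n_animals Number of animals; the first half are labelled
#'   `isl_only`, the rest `isl_plus` (drug + hormone co-implant arm).
#' @param duration Last sampling day.
#' @param sampling_interval Days between serial samples.
#' @param loaded_dose,sd_loaded_dose Implant payload distribution, mg.
#' @param true_release Release-law truth: a list with `model` one of
#'   `"zero"` (`rate` mg/day), `"first"` (`K` 1/day), `"higuchi"`
#'   (`K` mg/day^0.5), `"power"` (`K` 1/day^n and exponent `n`; fraction of
#'   loaded dose scale).
#' @inheritParams bolus_sim_config
#' @param mean_weight,sd_weight Body weight distribution, kg.
#' @return A list of class `implant_sim_config`.
#' @export
implant_sim_config <- function(n_animals = 10,
                               duration = 154,
                               sampling_interval = 14,
                               loaded_dose = 98.6, sd_loaded_dose = 3.31,
                               true_release = list(model = "zero", rate = 0.072),
                               true_uir = default_uir(),
                               error_model = c("lognormal", "proportional_truncated"),
                               sigma = 0.76,
                               lloq = 0.1,
                               mean_weight = 0.307, sd_weight = 0.02,
                               seed = 20240202L) {
  error_model <- match.arg(error_model)
  stopifnot(n_animals >= 1, duration > 0, sampling_interval > 0,
            loaded_dose > 0, sd_loaded_dose >= 0,
            inherits(true_uir, "uir"), sigma >= 0, lloq > 0)
  .check_release_spec(true_release, loaded_dose, duration)
  structure(as.list(environment()), class = "implant_sim_config")
}

.check_release_spec <- function(rel, loaded_dose, duration) {
  if (is.null(rel$model) ||
      !rel$model %in% c("zero", "first", "higuchi", "power")) {
    stop("true_release$model must be one of zero/first/higuchi/power",
         call. = FALSE)
  }
  released <- .cumulative_release_mg(rel, duration, loaded_dose)
  if (released > loaded_dose) {
    stop(sprintf(paste0("release law implies %.3g mg released by day %g, ",
                        "exceeding the %.3g mg loaded dose"),
                 released, duration, loaded_dose), call. = FALSE)
  }
  invisible(TRUE)
}

# Cumulative mass released (mg) at `day` under a release-law truth.
.cumulative_release_mg <- function(rel, day, loaded_mg) {
  switch(rel$model,
         zero    = rel$rate * day,
         first   = loaded_mg * (1 - exp(-rel$K * day)),
         higuchi = rel$K * sqrt(day),
         power   = loaded_mg * rel$K * day^rel$n)
}

#' Draw multiplicative residual noise factors
#'
#' The default `"lognormal"` model draws factors
#' `exp(eps - s^2/2)`, `eps ~ N(0, s^2)` with `s^2 = log(1 + sigma^2)`, so
#' the factors have mean exactly 1 and coefficient of variation exactly
#' `sigma`, and concentrations stay positive at any error magnitude.
#' `"proportional_truncated"` draws `1 + eps`, `eps ~ N(0, sigma^2)`
#' truncated to `eps > -1` (inverse-CDF sampling); at large `sigma` the
#' truncation inflates the mean and shrinks the realized CV.
#'
#' @param n Number of draws.
#' @param sigma Nominal CV fraction.
#' @param error_model See [bolus_sim_config()].
#' @return Numeric vector of positive multiplicative factors.
#' @export
multiplicative_noise <- function(n, sigma,
                                 error_model = c("lognormal", "proportional_truncated")) {
  error_model <- match.arg(error_model)
  if (sigma == 0) return(rep(1, n))
  if (error_model == "lognormal") {
    s2 <- log1p(sigma^2)
    exp(stats::rnorm(n, 0, sqrt(s2)) - s2 / 2)
  } else {
    p_floor <- stats::pnorm(-1, sd = sigma)
    u <- stats::runif(n, p_floor, 1)
    1 + stats::qnorm(u, sd = sigma)
  }
}

.draw_clipped_normal <- function(n, mean, sd, clip_sd = 3) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, mean - clip_sd * sd), mean + clip_sd * sd)
}

# Predicted plasma concentration (ng/mL) after an SC bolus, macro form:
# C(t) = D * [sum_i Ai e^(-alpha_i t) - (sum_i Ai) e^(-ka t)], D in ng.
.bolus_conc <- function(dose_ng, u, ka, t) {
  dose_ng * (eval_uir(u, t) - sum(u$coefficients) * exp(-ka * t))
}

#' Generate a synthetic sparse SC bolus study
#'
#' One plasma observation per animal (destructive sampling). True
#' concentrations follow the macro-constant first-order-absorption model
#' `C(t) = D [A1 e^(-a1 t) + A2 e^(-a2 t) - (A1+A2) e^(-Ka t)]` with the
#' configured truth; multiplicative noise and BLQ flagging are then applied.
#'
#' @param config A [bolus_sim_config()].
#' @return A [pk_study()] with design `"sparse_bolus"`; simulation truth is
#'   kept in `metadata` (`true_uir`, `ka`, `sigma`).
#' @export
generate_bolus_study <- function(config = bolus_sim_config()) {
  stopifnot(inherits(config, "bolus_sim_config"))
  set.seed(config$seed)
  group_labels <- c("bolus_low", "bolus_mid", "bolus_high")
  if (length(config$dose_levels) > 3) {
    group_labels <- paste0("bolus_", seq_along(config$dose_levels))
  }
  ord <- order(config$dose_levels)
  doses_sorted <- config$dose_levels[ord]

  rows <- list()
  dose_rows <- list()
  idx <- 0L
  for (d in seq_along(doses_sorted)) {
    grp <- group_labels[d]
    for (tp in config$timepoints) {
      for (a in seq_len(config$animals_per_timepoint)) {
        idx <- idx + 1L
        id <- sprintf("%s_%03d", grp, idx)
        w <- .draw_clipped_normal(1, config$mean_weight, config$sd_weight)
        dose_ng <- doses_sorted[d] * w * NG_PER_MG
        ctrue <- .bolus_conc(dose_ng, config$true_uir, config$ka, tp)
        cobs <- ctrue * multiplicative_noise(1, config$sigma, config$error_model)
        rows[[idx]] <- tibble::tibble(
          animal_id = id, group = grp, analyte = "plasma_parent",
          time = tp, time_unit = "hours",
          value = cobs, blq = cobs < config$lloq, lloq = config$lloq)
        dose_rows[[idx]] <- tibble::tibble(
          animal_id = id, dose_level_mg_per_kg = doses_sorted[d], weight_kg = w)
      }
    }
  }
  pk_study(dplyr::bind_rows(rows), dplyr::bind_rows(dose_rows),
           design = "sparse_bolus",
           metadata = list(true_uir = config$true_uir, ka = config$ka,
                           sigma = config$sigma, error_model = config$error_model,
                           seed = config$seed))
}

# J(n, x) = e^(-x) * integral_0^x u^(n-1) e^u du, the exponentially scaled
# kernel needed for exact convolution of power-law inputs. Positive-term
# power series for x < 30; asymptotic expansion (in 1/x) beyond, where the
# series terms would overflow/cancel.
.power_conv_J <- function(n, x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    if (xi < 30) {
      k <- 0
      term <- xi^n / n
      total <- term
      while (k < 500) {
        k <- k + 1
        term <- term * xi / k * (n + k - 1) / (n + k)
        total <- total + term
        if (term < total * 1e-16) break
      }
      exp(-xi) * total
    } else {
      # J ~ x^(n-1) * sum_k (1-n)(2-n)...(k-n) / x^k (asymptotic in 1/x)
      total <- 1
      term <- 1
      prev <- Inf
      for (k in 1:60) {
        term <- term * (k - n) / xi
        if (abs(term) > prev) break  # stop at the smallest term
        total <- total + term
        prev <- abs(term)
      }
      xi^(n - 1) * total
    }
  }, numeric(1))
}

# Exact plasma concentration (ng/mL) at hours `t_h` from convolving a
# release law (mg/day parameterisation) with the UIR. Closed forms per law;
# no numerical quadrature.
.conc_from_release <- function(u, rel, t_h, loaded_mg) {
  A <- u$coefficients; al <- u$rates
  out <- numeric(length(t_h))
  for (i in seq_along(A)) {
    out <- out + switch(rel$model,
      zero = {
        r_ngh <- rel$rate * NG_PER_MG / HOURS_PER_DAY
        r_ngh * A[i] / al[i] * (1 - exp(-al[i] * t_h))
      },
      first = {
        k_h <- rel$K / HOURS_PER_DAY
        m_ng <- loaded_mg * NG_PER_MG
        if (abs(al[i] - k_h) < 1e-12 * al[i]) {
          A[i] * m_ng * k_h * t_h * exp(-k_h * t_h)
        } else {
          A[i] * m_ng * k_h * (exp(-k_h * t_h) - exp(-al[i] * t_h)) / (al[i] - k_h)
        }
      },
      higuchi = ,
      power = {
        if (rel$model == "higuchi") {
          n_exp <- 0.5
          cmass_ng <- rel$K * NG_PER_MG / sqrt(HOURS_PER_DAY)  # M = cmass * t_h^0.5
        } else {
          n_exp <- rel$n
          cmass_ng <- loaded_mg * NG_PER_MG * rel$K / HOURS_PER_DAY^rel$n
        }
        A[i] * cmass_ng * n_exp * al[i]^(-n_exp) * .power_conv_J(n_exp, al[i] * t_h)
      })
  }
  out
}

#' Generate a synthetic serial-sampling implant study
#'
#' Per-animal serial plasma profiles whose true concentrations are the exact
#' closed-form convolution of the configured release law with the true UIR
#' (no numerical quadrature), with multiplicative noise and BLQ flagging as
#' in the bolus generator. Day-0 predose records are emitted as BLQ rows.
#'
#' @param config An [implant_sim_config()].
#' @return A [pk_study()] with design `"serial_implant"`; `metadata$truth`
#'   holds the release-law parameters for recovery tests.
#' @export
generate_implant_study <- function(config = implant_sim_config()) {
  stopifnot(inherits(config, "implant_sim_config"))
  set.seed(config$seed)
  days <- seq(config$sampling_interval, config$duration,
              by = config$sampling_interval)
  n_only <- ceiling(config$n_animals / 2)
  groups <- rep(c("isl_only", "isl_plus"),
                c(n_only, config$n_animals - n_only))

  rows <- list(); dose_rows <- list()
  for (a in seq_len(config$n_animals)) {
    id <- sprintf("imp_%02d", a)
    w <- .draw_clipped_normal(1, config$mean_weight, config$sd_weight)
    loaded <- .draw_clipped_normal(1, config$loaded_dose, config$sd_loaded_dose)
    ctrue <- .conc_from_release(config$true_uir, config$true_release,
                                days * HOURS_PER_DAY, loaded)
    cobs <- ctrue * multiplicative_noise(length(days), config$sigma,
                                         config$error_model)
    rows[[a]] <- dplyr::bind_rows(
      tibble::tibble(animal_id = id, group = groups[a],
                     analyte = "plasma_parent", time = 0, time_unit = "days",
                     value = NA_real_, blq = TRUE, lloq = config$lloq),
      tibble::tibble(animal_id = id, group = groups[a],
                     analyte = "plasma_parent", time = days, time_unit = "days",
                     value = cobs, blq = cobs < config$lloq, lloq = config$lloq))
    dose_rows[[a]] <- tibble::tibble(
      animal_id = id, dose_level_mg_per_kg = loaded / w, weight_kg = w,
      loaded_dose_mg = loaded)
  }
  pk_study(dplyr::bind_rows(rows), dplyr::bind_rows(dose_rows),
           design = "serial_implant",
           metadata = list(true_uir = config$true_uir,
                           truth = config$true_release,
                           sigma = config$sigma,
                           error_model = config$error_model,
                           seed = config$seed))
}

#' Simulate an intracellular metabolite profile from a parent curve
#'
#' One-compartment indirect (formation-limited) response: the metabolite
#' pool M satisfies `dM/dt = k_in * scale * Cp(t) - k_out * M`, driven by a
#' parent plasma curve expressed as a sum of exponentials. The closed-form
#' solution is again polyexponential; metabolite Tmax is strictly later than
#' parent Tmax. This generator is a stand-in for intracellular triphosphate
#' kinetics (not calibrated to any reported cellular data) so that the PBMC
#' arm of the NCA is testable.
#'
#' @param parent_terms Data frame with columns `coef` (ng/mL) and `rate`
#'   (1/h) defining `Cp(t) = sum coef_j exp(-rate_j t)`.
#' @param times Hours at which to evaluate the metabolite.
#' @param k_in Formation rate constant, 1/h.
#' @param k_out Loss rate constant, 1/h.
#' @param scale Conversion gain, (pmol/million cells) per (ng/mL) at
#'   equilibrium formation.
#' @return Numeric metabolite concentrations, pmol/million cells.
#' @export
simulate_metabolite_profile <- function(parent_terms, times, k_in, k_out, scale) {
  stopifnot(k_in > 0, k_out > 0, scale >= 0,
            all(c("coef", "rate") %in% names(parent_terms)))
  vals <- numeric(length(times))
  for (j in seq_len(nrow(parent_terms))) {
    cj <- parent_terms$coef[j]; lj <- parent_terms$rate[j]
    if (abs(k_out - lj) < 1e-12 * max(k_out, lj)) {
      vals <- vals + cj * times * exp(-k_out * times)
    } else {
      vals <- vals + cj * (exp(-lj * times) - exp(-k_out * times)) / (k_out - lj)
    }
  }
  scale * k_in * vals
}

#' Add synthetic PBMC metabolite observations to a bolus study
#'
#' Mirrors the destructive design: each plasma sample also yields one
#' metabolite measurement from the same animal and timepoint, computed from
#' that animal's true parent curve via [simulate_metabolite_profile()] with
#' multiplicative noise and its own LLOQ. Defaults place metabolite Tmax at
#' 2-4 h and peak values of order 0.05-0.6 pmol/million cells across the
#' default dose range.
#'
#' @param study A bolus [pk_study()] produced by [generate_bolus_study()]
#'   (its metadata must carry the simulation truth).
#' @param k_in,k_out Formation/loss rate constants, 1/h.
#' @param scale Gain, (pmol/million cells)/(ng/mL).
#' @param lloq Metabolite LLOQ, pmol/million cells.
#' @param sigma CV fraction for metabolite noise (defaults to the study's).
#' @param seed Seed for the metabolite noise draws.
#' @return The study with `pbmc_triphosphate` rows appended.
#' @export
add_metabolite_observations <- function(study, k_in = 0.2, k_out = 0.2,
                                        scale = 0.018, lloq = 0.005,
                                        sigma = NULL, seed = 1L) {
  stopifnot(inherits(study, "pk_study"), study$design == "sparse_bolus")
  md <- study$metadata
  if (is.null(md$true_uir)) {
    stop("study metadata lacks simulation truth (true_uir); ",
         "metabolite simulation needs the parent model", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- md$sigma
  set.seed(seed)
  obs <- study$observations
  parent <- obs[obs$analyte == "plasma_parent", ]
  dose_ng <- study$doses$absolute_dose_ng[match(parent$animal_id,
                                                study$doses$animal_id)]
  u <- md$true_uir
  met_rows <- parent
  vals <- numeric(nrow(parent))
  for (i in seq_len(nrow(parent))) {
    terms <- data.frame(
      coef = dose_ng[i] * c(u$coefficients, -sum(u$coefficients)),
      rate = c(u$rates, md$ka))
    vals[i] <- simulate_metabolite_profile(terms, parent$time[i],
                                           k_in, k_out, scale)
  }
  vals <- vals * multiplicative_noise(length(vals), sigma, md$error_model)
  met_rows$analyte <- "pbmc_triphosphate"
  met_rows$value <- vals
  met_rows$lloq <- lloq
  met_rows$blq <- vals < lloq
  study$observations <- dplyr::bind_rows(obs, met_rows)
  study$metadata$metabolite <- list(k_in = k_in, k_out = k_out,
                                    scale = scale, lloq = lloq)
  study
}
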