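# Numerical deconvolution of implant plasma profiles against the UIR:
# piecewise-constant input rates solved by (non-negative) linear least
# squares with an exact exponential convolution matrix.

# Exact convolution matrix: entry [k, j] is the concentration at times[k]
# produced by a unit input rate (1 ng/h) on (breaks[j], breaks[j+1]], all in
# hours: sum_i (Ai/ai) * (exp(-ai*(t - min(b,t))) - exp(-ai*(t - a))) for t >= a.
.conv_matrix <- function(u, breaks_h, times_h) {
  K <- length(breaks_h) - 1
  X <- matrix(0, nrow = length(times_h), ncol = K)
  for (j in seq_len(K)) {
    a <- breaks_h[j]; b <- breaks_h[j + 1]
    for (k in seq_along(times_h)) {
      t <- times_h[k]
      if (t <= a) next
      hi <- min(b, t)
      X[k, j] <- sum(u$coefficients / u$rates *
                       (exp(-u$rates * (t - hi)) - exp(-u$rates * (t - a))))
    }
  }
  X
}

#' Convolve a piecewise-constant input rate with a UIR
#'
#' Evaluates `C(t) = integral r(tau) u(t - tau) dtau` exactly for a
#' staircase input, using the closed-form integral of each exponential over
#' each interval -- no numerical quadrature.
#'
#' @param u A [uir()].
#' @param breakpoints Interval edges in hours, starting at 0, strictly
#'   increasing, length `K + 1`.
#' @param rates Non-negative input rates in ng/h, length `K` (zero after the
#'   last breakpoint).
#' @param times Evaluation times in hours.
#' @return Concentrations, ng/mL.
#' @export
convolve_input <- function(u, breakpoints, rates, times) {
  stopifnot(inherits(u, "uir"),
            length(rates) == length(breakpoints) - 1,
            breakpoints[1] == 0, all(diff(breakpoints) > 0),
            all(times >= 0))
  if (any(rates < 0)) stop("input rates must be non-negative", call. = FALSE)
  drop(.conv_matrix(u, breakpoints, times) %*% rates)
}

#' Deconvolve one animal's implant profile
#'
#' Represents the in vivo absorption (input) rate as piecewise-constant on a
#' day grid, builds the exact exponential convolution matrix against the
#' UIR, and solves linear least squares on the concentration scale --
#' non-negative least squares by default, so cumulative mass is
#' monotonically non-decreasing. Units are handled internally (grid days to
#' hours; solved ng/h rates reported as mg/day). `M(0)` is assumed
#' negligible (no burst term): cumulative mass starts at 0.
#'
#' @param observations One animal's observation tibble (design
#'   `serial_implant`, times in days). BLQ and excluded rows are dropped.
#' @param u A [uir()].
#' @param grid Day grid for the input intervals; default: 0 plus the
#'   quantifiable observation days within the horizon (one interval per
#'   inter-sample gap, a square system).
#' @param nonneg Enforce non-negative rates (default `TRUE`).
#' @param horizon Analysis horizon in days; observations beyond it are
#'   dropped (default 154).
#' @param loaded_dose Implant payload in mg (`M_inf`), used for the
#'   fraction-of-load scale.
#' @param ridge Optional ridge penalty (default 0) for grids finer than the
#'   sampling density.
#' @return An object of class `input_rate_profile`: `breakpoints` (days),
#'   `rates` (mg/day per interval), `cumulative_mass` (mg at each
#'   breakpoint), `fraction_absorbed`, `loaded_dose`, `fit_rss`, and the
#'   fitted concentrations.
#' @export
deconvolve_profile <- function(observations, u, grid = NULL, nonneg = TRUE,
                               horizon = 154, loaded_dose = NA_real_,
                               ridge = 0) {
  obs <- .ensure_flags(observations)
  if (!"analyzable" %in% names(obs)) obs$analyzable <- !obs$blq & !obs$excluded
  obs <- obs[obs$analyzable & obs$time > 0 & obs$time <= horizon, ]
  if (nrow(obs) < 2) {
    stop("deconvolution needs at least 2 quantifiable post-dose observations",
         call. = FALSE)
  }
  obs <- obs[order(obs$time), ]
  if (is.null(grid)) grid <- c(0, obs$time)
  grid <- sort(unique(grid))
  if (grid[1] != 0) grid <- c(0, grid)
  K <- length(grid) - 1
  if (K > nrow(obs) && ridge == 0) {
    stop(sprintf(paste0("underdetermined system: %d rate intervals but only ",
                        "%d observations; coarsen the grid or set ridge > 0"),
                 K, nrow(obs)), call. = FALSE)
  }
  times_h <- obs$time * HOURS_PER_DAY
  breaks_h <- grid * HOURS_PER_DAY
  X <- .conv_matrix(u, breaks_h, times_h)
  y <- obs$value
  if (ridge > 0) {
    X_aug <- rbind(X, sqrt(ridge) * diag(K))
    y_aug <- c(y, rep(0, K))
  } else {
    X_aug <- X; y_aug <- y
  }
  rates_ngh <- if (nonneg) {
    pracma::lsqnonneg(X_aug, y_aug)$x
  } else {
    stats::lsfit(X_aug, y_aug, intercept = FALSE)$coefficients
  }
  fitted <- drop(X %*% rates_ngh)
  rates_mgday <- rates_ngh * HOURS_PER_DAY / NG_PER_MG
  dt_days <- diff(grid)
  cum_mass <- c(0, cumsum(rates_mgday * dt_days))
  structure(list(
    animal_id = if (nrow(obs)) obs$animal_id[1] else NA_character_,
    breakpoints = grid,
    rates = unname(rates_mgday),
    cumulative_mass = unname(cum_mass),
    fraction_absorbed = if (is.na(loaded_dose)) rep(NA_real_, length(cum_mass))
                        else unname(cum_mass) / loaded_dose,
    loaded_dose = loaded_dose,
    fit_rss = sum((y - fitted)^2),
    observed = y, fitted = fitted, obs_days = obs$time,
    nonneg = nonneg), class = "input_rate_profile")
}

#' @export
print.input_rate_profile <- function(x, ...) {
  cat(sprintf("<input_rate_profile> %s: %d intervals to day %g\n",
              x$animal_id, length(x$rates), max(x$breakpoints)))
  cat(sprintf("  mean rate %.4g mg/day; cumulative %.4g mg (%.3g%% of load); RSS %.4g\n",
              utils::tail(x$cumulative_mass, 1) / max(x$breakpoints),
              utils::tail(x$cumulative_mass, 1),
              100 * utils::tail(x$fraction_absorbed, 1),
              x$fit_rss))
  invisible(x)
}

#' Cumulative mass absorbed at an arbitrary day
#'
#' Piecewise-constant rates integrate to a piecewise-linear cumulative
#' mass; this interpolates it exactly at `day`.
#'
#' @param profile An [deconvolve_profile()] result.
#' @param day Day within the profile's span.
#' @return Cumulative mass, mg.
#' @export
cumulative_mass_at <- function(profile, day) {
  stopifnot(inherits(profile, "input_rate_profile"),
            day >= 0, day <= max(profile$breakpoints))
  stats::approx(profile$breakpoints, profile$cumulative_mass, xout = day)$y
}

#' Deconvolve every animal in an implant study
#'
#' @param study A serial-implant [pk_study()].
#' @param u A [uir()].
#' @param exclude Character vector of animal IDs to exclude (explicit
#'   cohort definition; exclusion is never automatic).
#' @inheritParams deconvolve_profile
#' @return Named list of `input_rate_profile` objects.
#' @export
deconvolve_study <- function(study, u, grid = NULL, nonneg = TRUE,
                             horizon = 154, exclude = character()) {
  stopifnot(inherits(study, "pk_study"), study$design == "serial_implant")
  ids <- setdiff(unique(study$observations$animal_id), exclude)
  profiles <- list()
  for (id in ids) {
    obs <- study$observations[study$observations$animal_id == id, ]
    loaded <- study$doses$loaded_dose_mg[study$doses$animal_id == id][1]
    profiles[[id]] <- deconvolve_profile(obs, u, grid = grid, nonneg = nonneg,
                                         horizon = horizon,
                                         loaded_dose = loaded)
  }
  profiles
}

#' Summarise absorption across deconvolved profiles
#'
#' Per-group and overall mean and SD of the per-animal mean absorption rate
#' (cumulative mass at the horizon divided by the horizon) and of the
#' cumulative mass at the horizon, the percent of loaded dose absorbed, and
#' drug recovery (mean loaded dose minus mean mass absorbed).
#'
#' @param profiles List of `input_rate_profile` objects (all extending to
#'   `horizon`).
#' @param groups Optional named character vector mapping animal ID to group
#'   label; unmapped animals fall in group `"all"`.
#' @param horizon Summary horizon, days.
#' @return List with `by_animal` (tibble) and `summary` (tibble with one
#'   row per group plus `"overall"`).
#' @export
summarize_absorption <- function(profiles, groups = NULL, horizon = 154) {
  by_animal <- dplyr::bind_rows(lapply(profiles, function(p) {
    m <- cumulative_mass_at(p, horizon)
    tibble::tibble(animal_id = p$animal_id,
                   mean_rate = m / horizon,
                   cumulative_mass = m,
                   loaded_dose = p$loaded_dose,
                   fraction_absorbed = m / p$loaded_dose,
                   max_interval_rate = max(p$rates))
  }))
  by_animal$group <- if (is.null(groups)) "all" else
    unname(groups[by_animal$animal_id])
  by_animal$group[is.na(by_animal$group)] <- "all"

  summ_one <- function(d, label) {
    tibble::tibble(
      group = label, n = nrow(d),
      mean_rate = mean(d$mean_rate), sd_rate = stats::sd(d$mean_rate),
      mean_cumulative_mass = mean(d$cumulative_mass),
      sd_cumulative_mass = stats::sd(d$cumulative_mass),
      mean_loaded_dose = mean(d$loaded_dose),
      percent_of_load = 100 * mean(d$cumulative_mass) / mean(d$loaded_dose),
      drug_recovery = mean(d$loaded_dose) - mean(d$cumulative_mass))
  }
  groups_present <- unique(by_animal$group)
  summary <- dplyr::bind_rows(
    lapply(groups_present, function(g) summ_one(by_animal[by_animal$group == g, ], g)),
    summ_one(by_animal, "overall"))
  list(by_animal = by_animal, summary = summary)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance comparison of two groups (e.g. mean absorption rates of
#' the drug-only and co-implant arms at a given day), with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param group_a,group_b Numeric vectors, each `n >= 2`.
#' @return List with `t`, `df`, `p_value`, group means.
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    stop("degenerate (zero) variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b))
}
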