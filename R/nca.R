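# Sparse noncompartmental analysis: BLQ censoring, outlier screening,
# naive-pooled mean profiles, linear-up/log-down AUC, endpoint estimation
# and dose-proportionality assessment.

#' Censor below-quantification-limit observations for NCA
#'
#' Applies the discard-with-count reading of the Beal "M2" policy to
#' trapezoidal NCA: BLQ rows are flagged as excluded from NCA computations
#' but never deleted, and the exclusion count is reported as an attribute.
#' With `policy = "zero_before_tmax"`, BLQ rows earlier than the first
#' quantifiable maximum are instead treated as zero concentrations (kept
#' analyzable with value 0).
#'
#' @param observations An observation tibble (see [pk_study()]).
#' @param policy `"discard"` (default) or `"zero_before_tmax"`.
#' @return The observations with a logical `analyzable` column; attribute
#'   `n_censored` holds the number of BLQ exclusions. Warns if nothing is
#'   analyzable.
#' @export
beal_m2_censor <- function(observations, policy = c("discard", "zero_before_tmax")) {
  policy <- match.arg(policy)
  obs <- .ensure_flags(observations)
  obs$analyzable <- !obs$blq & !obs$excluded
  if (policy == "zero_before_tmax" && any(obs$analyzable)) {
    for (an in unique(obs$analyte)) {
      sel <- obs$analyte == an
      quant <- sel & obs$analyzable
      if (!any(quant)) next
      tmax <- obs$time[quant][which.max(obs$value[quant])]
      early_blq <- sel & obs$blq & !obs$excluded & obs$time < tmax
      obs$value[early_blq] <- 0
      obs$analyzable[early_blq] <- TRUE
    }
  }
  n_censored <- sum(obs$blq & !obs$analyzable)
  if (!any(obs$analyzable)) {
    warning("no analyzable observations remain after BLQ censoring")
  }
  attr(obs, "n_censored") <- n_censored
  obs
}

#' Grubbs test for a single outlier
#'
#' Two-sided test on the most extreme value:
#' `G = max|x - mean(x)| / sd(x)`, compared against the critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)`. At most one outlier is flagged per call.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return A list with `outlier_index` (integer or `NA` if none),
#'   `statistic` (G), `critical`, `n`. With `n < 3` or zero variance, no
#'   outlier is reported (`statistic` is `NA` for degenerate input).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) {
    return(list(outlier_index = NA_integer_, statistic = NA_real_,
                critical = NA_real_, n = n,
                note = "not applicable: fewer than 3 values"))
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(outlier_index = NA_integer_, statistic = NA_real_,
                critical = NA_real_, n = n, note = "zero variance"))
  }
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  g <- dev[idx] / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(outlier_index = if (g > crit) idx else NA_integer_,
       statistic = g, critical = crit, n = n)
}

#' Pool a sparse destructive-sampling profile
#'
#' With one observation per animal, individual NCA is impossible; the
#' sparse-NCA convention pools animals and takes the per-timepoint
#' arithmetic mean of quantifiable values. Timepoints with no quantifiable
#' value are omitted with a note.
#'
#' @param observations Observation tibble, already passed through
#'   [beal_m2_censor()] (rows with `analyzable = FALSE` are ignored; if the
#'   column is absent, BLQ/excluded rows are ignored).
#' @param group,analyte Optional filters applied before pooling.
#' @return A tibble `time`, `mean_conc`, `n`, `sd_conc`; attribute
#'   `dropped_timepoints` lists all-BLQ times. Errors if fewer than two
#'   usable timepoints remain (NCA not estimable).
#' @export
pool_sparse_profile <- function(observations, group = NULL, analyte = NULL) {
  obs <- .ensure_flags(observations)
  if (!is.null(group)) obs <- obs[obs$group %in% group, ]
  if (!is.null(analyte)) obs <- obs[obs$analyte == analyte, ]
  if (!"analyzable" %in% names(obs)) obs$analyzable <- !obs$blq & !obs$excluded

  all_times <- sort(unique(obs$time))
  usable <- obs[obs$analyzable, ]
  prof <- usable |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean_conc = mean(.data$value),
                     n = dplyr::n(),
                     sd_conc = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$time)
  dropped <- setdiff(all_times, prof$time)
  if (nrow(prof) < 2) {
    stop("NCA not estimable: fewer than 2 timepoints with quantifiable values",
         call. = FALSE)
  }
  attr(prof, "dropped_timepoints") <- dropped
  prof
}

#' Area under the curve by the linear-up / log-down trapezoidal rule
#'
#' Rising (or flat) segments use the linear trapezoid
#' `(C1 + C2)/2 * dt`; falling segments use the logarithmic trapezoid
#' `(C1 - C2) / ln(C1/C2) * dt`. The total runs from the first to the last
#' quantifiable point (no back-extrapolation to t = 0 and no extrapolation
#' to infinity).
#'
#' @param times Strictly increasing times (h).
#' @param conc Positive concentrations (post-censoring), same length.
#' @return Scalar AUC in h times the concentration unit.
#' @export
auc_linear_up_log_down <- function(times, conc) {
  stopifnot(length(times) == length(conc), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc <= 0)) {
    stop("nonpositive concentration: log trapezoid undefined (censor first)",
         call. = FALSE)
  }
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- ifelse(c2 >= c1,
                (c1 + c2) / 2 * dt,
                (c1 - c2) / log(c1 / c2) * dt)
  sum(seg)
}

#' NCA endpoints from a pooled sparse profile
#'
#' Cmax/Tmax are read from the pooled means; AUC_last uses
#' [auc_linear_up_log_down()]; the terminal slope `lambda_z` comes from an
#' unweighted log-linear regression of the pooled means on time within
#' `t_half_window`, requiring at least 3 quantifiable points
#' (`t_half = ln 2 / lambda_z`); and `c_avg = auc_last / cavg_duration`
#' (the nominal 24 h profile duration by default, matching the convention
#' the dose levels are compared under).
#'
#' @param profile Tibble from [pool_sparse_profile()].
#' @param t_half_window Two-element window (h) for the terminal fit.
#' @param cavg_duration Denominator for `c_avg`, hours.
#' @return A one-row tibble: `cmax`, `tmax`, `auc_last`, `lambda_z`,
#'   `t_half`, `c_avg`, `n_obs`, `notes`. `lambda_z`/`t_half` are `NA` with
#'   a note when not estimable (fewer than 3 window points or a
#'   non-decreasing terminal phase).
#' @export
nca_endpoints <- function(profile, t_half_window = c(4, 24), cavg_duration = 24) {
  stopifnot(all(c("time", "mean_conc") %in% names(profile)))
  prof <- profile[order(profile$time), ]
  cmax <- max(prof$mean_conc)
  tmax <- prof$time[which.max(prof$mean_conc)]
  auc <- auc_linear_up_log_down(prof$time, prof$mean_conc)

  notes <- character()
  lambda_z <- NA_real_; t_half <- NA_real_
  inwin <- prof$time >= t_half_window[1] & prof$time <= t_half_window[2]
  if (sum(inwin) >= 3) {
    fit <- stats::lm(log(mean_conc) ~ time, data = prof[inwin, ])
    slope <- unname(stats::coef(fit)[2])
    if (is.finite(slope) && slope < 0) {
      lambda_z <- -slope
      t_half <- log(2) / lambda_z
    } else {
      notes <- c(notes, "t_half not estimable: non-negative terminal slope")
    }
  } else {
    notes <- c(notes, "t_half not estimable: fewer than 3 points in window")
  }
  tibble::tibble(
    cmax = cmax, tmax = tmax, auc_last = auc,
    lambda_z = lambda_z, t_half = t_half,
    c_avg = auc / cavg_duration,
    n_obs = sum(prof$n %||% rep(1, nrow(prof))),
    notes = paste(notes, collapse = "; "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dose-proportionality assessment by the power model
#'
#' Unweighted ordinary least squares of `ln(parameter)` on `ln(dose)`
#' across dose levels. Linearity is declared when the slope lies in
#' `slope_band` and r-squared exceeds `r2_min`. The slope is invariant to
#' rescaling all doses by a constant, so mg vs ng and weight-normalised vs
#' absolute dose give identical slopes.
#'
#' @param doses Positive doses (any consistent unit).
#' @param param_values Positive endpoint values (Cmax or AUC_last), one per
#'   dose.
#' @param parameter Label, `"cmax"` or `"auc_last"`.
#' @param slope_band Two-element interval around 1 within which the slope
#'   supports proportionality.
#' @param r2_min Minimum r-squared.
#' @return One-row tibble: `parameter`, `slope`, `intercept`, `r_squared`,
#'   `declared_linear`.
#' @export
dose_proportionality <- function(doses, param_values,
                                 parameter = c("cmax", "auc_last"),
                                 slope_band = c(0.8, 1.25), r2_min = 0.8) {
  parameter <- match.arg(parameter)
  if (length(doses) < 3) stop("need at least 3 dose levels", call. = FALSE)
  if (any(doses <= 0) || any(param_values <= 0)) {
    stop("doses and parameter values must be positive (log transform)",
         call. = FALSE)
  }
  fit <- stats::lm(log(param_values) ~ log(doses))
  slope <- unname(stats::coef(fit)[2])
  # r^2 computed directly (summary.lm warns on numerically perfect fits)
  sstot <- sum((log(param_values) - mean(log(param_values)))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sstot
  tibble::tibble(
    parameter = parameter,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    declared_linear = slope >= slope_band[1] & slope <= slope_band[2] & r2 > r2_min)
}

#' Intracellular-to-plasma molar exposure ratio
#'
#' Converts the intracellular metabolite average concentration
#' (pmol/million cells, assuming `cell_volume` pL per cell) and the plasma
#' parent average concentration (ng/mL, divided by `molar_mass`) to molar
#' units and returns their ratio. Presets for the molar mass of islatravir
#' (`"parent"`, 293.3 g/mol) and its triphosphate (`"triphosphate"`,
#' 533.2 g/mol) are provided; which mass is used changes the ratio by
#' ~1.8x, so the choice is an explicit argument.
#'
#' @param c_avg_tp Metabolite average concentration, pmol/million cells.
#' @param c_avg_parent Parent plasma average concentration, ng/mL.
#' @param molar_mass `"triphosphate"` (default), `"parent"`, or a numeric
#'   g/mol value for the plasma conversion.
#' @param cell_volume PBMC volume, pL per cell (default 0.2).
#' @return Dimensionless molar ratio (intracellular / plasma).
#' @export
tp_to_parent_ratio <- function(c_avg_tp, c_avg_parent,
                               molar_mass = "triphosphate",
                               cell_volume = 0.2) {
  mm <- if (is.character(molar_mass)) {
    switch(match.arg(molar_mass, c("triphosphate", "parent")),
           triphosphate = 533.2, parent = 293.3)
  } else as.numeric(molar_mass)
  stopifnot(c_avg_tp > 0, c_avg_parent > 0, mm > 0, cell_volume > 0)
  # intracellular: c_avg_tp pmol in (1e6 cells * cell_volume pL) of cytosol
  intracellular_nM <- c_avg_tp * 1e-12 / (1e6 * cell_volume * 1e-12) / 1e-9
  # plasma: 1 ng/mL = 1e-6 g/L, so molarity = c * 1e-6 / mm mol/L
  plasma_nM <- c_avg_parent * 1e-6 / mm / 1e-9
  intracellular_nM / plasma_nM
}

#' Run the full sparse NCA for one study
#'
#' Censors BLQ rows, pools each dose level and analyte, computes endpoints,
#' and assesses dose proportionality of Cmax and AUC_last against the mean
#' absolute dose of each level.
#'
#' @param study A bolus [pk_study()].
#' @param t_half_window,cavg_duration Passed to [nca_endpoints()].
#' @param blq_policy Passed to [beal_m2_censor()].
#' @param slope_band,r2_min Passed to [dose_proportionality()].
#' @return List with `endpoints` (tibble: one row per dose level x analyte)
#'   and `proportionality` (tibble: one row per analyte x parameter),
#'   plus `n_censored`.
#' @export
run_nca <- function(study, t_half_window = c(4, 24), cavg_duration = 24,
                    blq_policy = "discard",
                    slope_band = c(0.8, 1.25), r2_min = 0.8) {
  stopifnot(inherits(study, "pk_study"), study$design == "sparse_bolus")
  obs <- beal_m2_censor(study$observations, policy = blq_policy)
  n_censored <- attr(obs, "n_censored")

  dose_by_animal <- study$doses
  obs$dose_level <- dose_by_animal$dose_level_mg_per_kg[
    match(obs$animal_id, dose_by_animal$animal_id)]
  obs$absolute_dose_mg <- dose_by_animal$absolute_dose_ng[
    match(obs$animal_id, dose_by_animal$animal_id)] / NG_PER_MG

  endpoints <- list(); k <- 0
  for (an in unique(obs$analyte)) {
    for (dl in sort(unique(obs$dose_level))) {
      sub <- obs[obs$analyte == an & obs$dose_level == dl, ]
      res <- tryCatch({
        prof <- pool_sparse_profile(sub)
        ep <- nca_endpoints(prof, t_half_window, cavg_duration)
        ep$dropped_timepoints <- length(attr(prof, "dropped_timepoints"))
        ep
      }, error = function(e) {
        tibble::tibble(cmax = NA_real_, tmax = NA_real_, auc_last = NA_real_,
                       lambda_z = NA_real_, t_half = NA_real_, c_avg = NA_real_,
                       n_obs = 0L, notes = conditionMessage(e),
                       dropped_timepoints = NA_integer_)
      })
      k <- k + 1
      endpoints[[k]] <- dplyr::bind_cols(
        tibble::tibble(analyte = an, dose_level = dl,
                       mean_absolute_dose_mg = mean(sub$absolute_dose_mg)),
        res)
    }
  }
  endpoints <- dplyr::bind_rows(endpoints)

  prop <- list(); k <- 0
  for (an in unique(endpoints$analyte)) {
    sub <- endpoints[endpoints$analyte == an & !is.na(endpoints$auc_last), ]
    if (nrow(sub) < 3) next
    for (par in c("cmax", "auc_last")) {
      k <- k + 1
      prop[[k]] <- dplyr::bind_cols(
        tibble::tibble(analyte = an),
        dose_proportionality(sub$mean_absolute_dose_mg, sub[[par]],
                             parameter = par, slope_band = slope_band,
                             r2_min = r2_min))
    }
  }
  list(endpoints = endpoints,
       proportionality = if (length(prop)) dplyr::bind_rows(prop) else NULL,
       n_censored = n_censored)
}
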