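# Naive-pooled compartmental fitting in the macro-constant parameterisation,
# error-model selection, diagnostics, and unit-impulse-response derivation.

#' Specify a macro-constant compartmental model
#'
#' @param n_compartments 1 or 2.
#' @param error_model Residual model for the pooled likelihood:
#'   `"multiplicative"` (residual SD proportional to the prediction),
#'   `"additive"` (constant SD), or `"log_additive"` (normal on the log
#'   scale).
#' @return A list of class `macro_model_spec`.
#' @export
macro_model_spec <- function(n_compartments = 2,
                             error_model = c("multiplicative", "additive",
                                             "log_additive")) {
  error_model <- match.arg(error_model)
  stopifnot(n_compartments %in% c(1, 2))
  structure(list(n_compartments = n_compartments, error_model = error_model),
            class = "macro_model_spec")
}

#' Predict concentrations from a macro-constant model
#'
#' First-order absorption polyexponential in the macro parameterisation
#' `C(t) = (dose/dose_ref) [A e^(-alpha t) + B e^(-beta t) -
#' (A+B) e^(-Ka t)]`, which satisfies `C(0) = 0` by construction and decays
#' to 0. `A`, `B` are expressed at the reference dose `dose_ref`. For a
#' 1-compartment model set `B = 0` (or omit it). The parameterisation is
#' continuous in `Ka`; when `Ka` approaches a disposition rate the two
#' exponential terms merge smoothly (no singular factor is involved).
#'
#' @param params List/`macro_model_fit` with `A`, `alpha`, `ka`, `dose_ref`
#'   and optionally `B`, `beta`.
#' @param dose Dose(s) in ng (scalar or one per time).
#' @param times Times in hours, `>= 0`.
#' @return Concentrations, ng/mL.
#' @export
predict_macro_model <- function(params, dose, times) {
  stopifnot(all(times >= 0))
  A <- params$A
  B <- if (is.null(params$B) || is.na(params$B)) 0 else params$B
  beta <- if (is.null(params$beta) || is.na(params$beta)) 1 else params$beta
  dose_ref <- params$dose_ref %||% 1
  base <- A * exp(-params$alpha * times) + B * exp(-beta * times) -
    (A + B) * exp(-params$ka * times)
  (dose / dose_ref) * base
}

# Concentrated negative log-likelihood for a parameter vector on log scale.
# theta: log(A[, B], alpha[, beta], ka). Sigma is profiled out analytically.
.make_nll <- function(times, conc, dose, dose_ref, n_comp, error_model) {
  n <- length(conc)
  log_y_sum <- sum(log(conc))
  function(theta) {
    p <- exp(theta)
    if (any(!is.finite(p))) return(1e10)
    if (n_comp == 2) {
      pars <- list(A = p[1], B = p[2], alpha = p[3], beta = p[4], ka = p[5],
                   dose_ref = dose_ref)
    } else {
      pars <- list(A = p[1], B = 0, alpha = p[2], beta = 1, ka = p[3],
                   dose_ref = dose_ref)
    }
    f <- predict_macro_model(pars, dose, times)
    if (any(!is.finite(f)) || any(f <= 0)) return(1e10)
    nll <- switch(error_model,
      additive = {
        s2 <- max(mean((conc - f)^2), 1e-300)
        n / 2 * (log(2 * pi * s2) + 1)
      },
      multiplicative = {
        s2 <- max(mean(((conc - f) / f)^2), 1e-300)
        n / 2 * (log(2 * pi * s2) + 1) + sum(log(f))
      },
      log_additive = {
        s2 <- max(mean((log(conc) - log(f))^2), 1e-300)
        n / 2 * (log(2 * pi * s2) + 1) + log_y_sum
      })
    if (!is.finite(nll)) 1e10 else nll
  }
}

# Method-of-residuals (curve stripping) initial estimates on dose-normalised
# pooled data. Returns log-scale theta for the requested model.
.strip_initials <- function(times, conc, dose, dose_ref, n_comp, ka0 = 10) {
  yn <- conc * dose_ref / dose
  ts <- sort(unique(times))
  late <- times >= ts[max(1, length(ts) - 2)]
  beta0 <- 0.1; B0 <- max(yn) * 0.01
  fit_late <- tryCatch(stats::lm(log(yn[late]) ~ times[late]), error = function(e) NULL)
  if (!is.null(fit_late) && is.finite(stats::coef(fit_late)[2]) &&
      stats::coef(fit_late)[2] < 0) {
    beta0 <- -unname(stats::coef(fit_late)[2])
    B0 <- exp(unname(stats::coef(fit_late)[1]))
  }
  if (n_comp == 1) {
    return(log(c(A = B0, alpha = beta0, ka = ka0)))
  }
  early <- times <= stats::median(times) & times > 0
  resid <- yn[early] - B0 * exp(-beta0 * times[early])
  alpha0 <- beta0 * 8; A0 <- B0 * 10
  pos <- resid > 0
  if (sum(pos) >= 2) {
    fit_early <- tryCatch(stats::lm(log(resid[pos]) ~ times[early][pos]),
                          error = function(e) NULL)
    if (!is.null(fit_early) && is.finite(stats::coef(fit_early)[2]) &&
        stats::coef(fit_early)[2] < 0) {
      alpha0 <- -unname(stats::coef(fit_early)[2])
      A0 <- exp(unname(stats::coef(fit_early)[1]))
    }
  }
  if (alpha0 <= beta0) alpha0 <- beta0 * 8
  log(c(A = A0, B = B0, alpha = alpha0, beta = beta0, ka = ka0))
}

#' Fit a macro-constant model by the naive pooled method
#'
#' Concatenates all animals' quantifiable observations as if from a single
#' subject (no random effects; appropriate for destructive sparse sampling)
#' and maximises the exact pooled likelihood under the spec's error model,
#' with the residual scale profiled out analytically. Optimisation is
#' multi-start Nelder-Mead followed by BFGS refinement, starting from
#' method-of-residuals (curve-stripping) initials plus jittered replicates.
#' Percent CVs come from the inverse observed information (Hessian of the
#' negative log-likelihood on the log-parameter scale, i.e. a delta-method
#' CV for each parameter).
#'
#' @param study A bolus [pk_study()] (plasma observations are used).
#' @param spec A [macro_model_spec()].
#' @param blq `"exclude"` (default; mirrors the NCA censoring policy) or
#'   `"censor"`, which keeps BLQ rows in the likelihood as
#'   `P(observation < LLOQ)` under the error model.
#' @param n_starts Number of optimisation starts (>= 1).
#' @param seed Seed for the start jitter.
#' @return An object of class `macro_model_fit`: macro constants (`A`, `B`
#'   ng/mL at `dose_ref`), rates (`alpha > beta`, `ka`, 1/h), `sigma`,
#'   `loglik`, `aic`, `bic`, `cv_percent`, `residual_error_percent`,
#'   `converged`, `n_obs`.
#' @export
fit_macro_model <- function(study, spec = macro_model_spec(),
                            blq = c("exclude", "censor"),
                            n_starts = 5, seed = 1L) {
  stopifnot(inherits(study, "pk_study"), inherits(spec, "macro_model_spec"))
  blq <- match.arg(blq)
  obs <- study$observations
  obs <- obs[obs$analyte == "plasma_parent" & !obs$excluded, ]
  dose_all <- study$doses$absolute_dose_ng[match(obs$animal_id,
                                                 study$doses$animal_id)]
  quant <- !obs$blq
  times <- obs$time[quant]; conc <- obs$value[quant]; dose <- dose_all[quant]
  n_comp <- spec$n_compartments
  n_par <- if (n_comp == 2) 5L else 3L
  if (length(conc) < 2 * n_par) {
    stop("too few quantifiable observations to fit ", n_par,
         " structural parameters", call. = FALSE)
  }
  dose_ref <- mean(dose)
  nll <- .make_nll(times, conc, dose, dose_ref, n_comp, spec$error_model)
  if (blq == "censor" && any(!quant)) {
    cens_t <- obs$time[!quant]; cens_lloq <- obs$lloq[!quant]
    cens_dose <- dose_all[!quant]
    base_nll <- nll
    nll <- function(theta) {
      val <- base_nll(theta)
      if (val >= 1e10) return(val)
      p <- exp(theta)
      pars <- if (n_comp == 2) {
        list(A = p[1], B = p[2], alpha = p[3], beta = p[4], ka = p[5],
             dose_ref = dose_ref)
      } else {
        list(A = p[1], B = 0, alpha = p[2], beta = 1, ka = p[3],
             dose_ref = dose_ref)
      }
      f <- predict_macro_model(pars, cens_dose, cens_t)
      fq <- predict_macro_model(pars, dose, times)
      s <- switch(spec$error_model,
                  additive = sqrt(max(mean((conc - fq)^2), 1e-300)),
                  multiplicative = sqrt(max(mean(((conc - fq) / fq)^2), 1e-300)),
                  log_additive = sqrt(max(mean((log(conc) - log(fq))^2), 1e-300)))
      pr <- switch(spec$error_model,
                   additive = stats::pnorm(cens_lloq, f, s),
                   multiplicative = stats::pnorm(cens_lloq, f, s * f),
                   log_additive = stats::pnorm(log(cens_lloq), log(f), s))
      val - sum(log(pmax(pr, 1e-300)))
    }
  }

  theta0 <- .strip_initials(times, conc, dose, dose_ref, n_comp)
  set.seed(seed)
  starts <- c(list(theta0),
              lapply(seq_len(max(0, n_starts - 1)), function(i) {
                theta0 + stats::rnorm(length(theta0), 0, 0.5)
              }))
  best <- NULL
  for (th in starts) {
    o1 <- tryCatch(stats::optim(th, nll, method = "Nelder-Mead",
                                control = list(maxit = 4000, reltol = 1e-12)),
                   error = function(e) NULL)
    if (is.null(o1)) next
    o2 <- tryCatch(stats::optim(o1$par, nll, method = "BFGS",
                                control = list(maxit = 1000, reltol = 1e-14)),
                   error = function(e) o1)
    cand <- if (!is.null(o2) && o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  converged <- best$value < 1e9 && (best$convergence %in% c(0, 1))

  p <- unname(exp(best$par))
  if (n_comp == 2) {
    # enforce alpha > beta by sorting the exponential pairs
    if (p[3] < p[4]) p <- p[c(2, 1, 4, 3, 5)]
    A <- p[1]; B <- p[2]; alpha <- p[3]; beta <- p[4]; ka <- p[5]
  } else {
    A <- p[1]; B <- NA_real_; alpha <- p[2]; beta <- NA_real_; ka <- p[3]
  }
  pars_hat <- list(A = A, B = if (is.na(B)) 0 else B, alpha = alpha,
                   beta = if (is.na(beta)) 1 else beta, ka = ka,
                   dose_ref = dose_ref)
  f <- predict_macro_model(pars_hat, dose, times)
  sigma <- switch(spec$error_model,
                  additive = sqrt(mean((conc - f)^2)),
                  multiplicative = sqrt(mean(((conc - f) / f)^2)),
                  log_additive = sqrt(mean((log(conc) - log(f))^2)))
  loglik <- -best$value
  k <- n_par + 1  # + residual scale
  n <- length(conc)
  cv <- tryCatch({
    H <- pracma::hessian(nll, best$par)
    v <- diag(solve(H))
    se <- ifelse(v > 0, sqrt(v), NA_real_)  # non-PD information: CV unreliable
    stats::setNames(100 * se, names(theta0))
  }, error = function(e) stats::setNames(rep(NA_real_, n_par), names(theta0)))

  structure(list(
    n_compartments = n_comp, error_model = spec$error_model,
    A = A, B = B, alpha = alpha, beta = beta, ka = ka,
    sigma = sigma, dose_ref = dose_ref,
    loglik = loglik, aic = 2 * k - 2 * loglik,
    bic = k * log(n) - 2 * loglik,
    cv_percent = cv,
    residual_error_percent = if (spec$error_model == "additive") NA_real_
                             else 100 * sigma,
    converged = converged, n_obs = n, n_params = k,
    objective = best$value), class = "macro_model_fit")
}

#' @export
print.macro_model_fit <- function(x, ...) {
  cat(sprintf("<macro_model_fit> %d-compartment, %s error%s\n",
              x$n_compartments, x$error_model,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  A = %.5g ng/mL  alpha = %.5g 1/h\n", x$A, x$alpha))
  if (x$n_compartments == 2) {
    cat(sprintf("  B = %.5g ng/mL  beta  = %.5g 1/h\n", x$B, x$beta))
  }
  cat(sprintf("  Ka = %.5g 1/h  sigma = %.4g  (dose_ref = %.6g ng)\n",
              x$ka, x$sigma, x$dose_ref))
  cat(sprintf("  logLik = %.4f  AIC = %.4f  BIC = %.4f  (n = %d)\n",
              x$loglik, x$aic, x$bic, x$n_obs))
  invisible(x)
}

#' Rank candidate fits and select a final model
#'
#' Candidates are ranked by AIC with BIC as tie-break; candidates that did
#' not converge or whose worst parameter %CV is 30% or more are demoted
#' below all passing candidates (non-converged last). Errors if every
#' candidate failed to converge.
#'
#' @param fits List of [fit_macro_model()] results on identical data.
#' @param cv_limit %CV threshold (default 30).
#' @return List with `table` (ranked tibble) and `selected` (the winning
#'   fit object).
#' @export
select_model <- function(fits, cv_limit = 30) {
  stopifnot(length(fits) >= 1)
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      model = sprintf("%dcomp_%s", f$n_compartments, f$error_model),
      n_compartments = f$n_compartments, error_model = f$error_model,
      loglik = f$loglik, aic = f$aic, bic = f$bic,
      max_cv_percent = if (all(is.na(f$cv_percent))) NA_real_
                       else max(f$cv_percent, na.rm = TRUE),
      converged = f$converged)
  }))
  if (!any(tab$converged)) {
    stop("no candidate model converged; review data and initial estimates",
         call. = FALSE)
  }
  tab$cv_ok <- !is.na(tab$max_cv_percent) & tab$max_cv_percent < cv_limit
  tab$demoted <- !tab$converged | !tab$cv_ok
  ord <- order(!tab$converged, tab$demoted, tab$aic, tab$bic)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  list(table = tab, selected = fits[[ord[1]]])
}

#' Residual diagnostics for a fitted macro model
#'
#' Per-observation predictions, residuals and weighted residuals under the
#' fit's error model (additive: `(y-f)/sigma`; multiplicative:
#' `(y-f)/(sigma f)`; log-additive: `(log y - log f)/sigma`), plus the
#' weighted-residual quantiles against the standard normal for a
#' quantile-quantile check.
#'
#' @param fit A converged [fit_macro_model()] result.
#' @param study The study it was fitted to.
#' @return List with `residuals` (tibble, one row per quantifiable
#'   observation) and `qq` (tibble of observed vs theoretical quantiles).
#' @export
model_diagnostics <- function(fit, study) {
  stopifnot(inherits(fit, "macro_model_fit"), inherits(study, "pk_study"))
  obs <- study$observations
  obs <- obs[obs$analyte == "plasma_parent" & !obs$excluded & !obs$blq, ]
  dose <- study$doses$absolute_dose_ng[match(obs$animal_id,
                                             study$doses$animal_id)]
  pars <- list(A = fit$A, B = if (is.na(fit$B)) 0 else fit$B,
               alpha = fit$alpha, beta = if (is.na(fit$beta)) 1 else fit$beta,
               ka = fit$ka, dose_ref = fit$dose_ref)
  pred <- predict_macro_model(pars, dose, obs$time)
  resid <- obs$value - pred
  wres <- switch(fit$error_model,
                 additive = resid / fit$sigma,
                 multiplicative = resid / (fit$sigma * pred),
                 log_additive = (log(obs$value) - log(pred)) / fit$sigma)
  tab <- tibble::tibble(animal_id = obs$animal_id, time = obs$time,
                        observed = obs$value, predicted = pred,
                        residual = resid, weighted_residual = wres)
  probs <- stats::ppoints(length(wres))
  qq <- tibble::tibble(theoretical = stats::qnorm(probs),
                       observed = sort(wres))
  list(residuals = tab, qq = qq)
}

#' Derive the unit impulse response from a fitted macro model
#'
#' Divides the macro constants by the average dose to obtain the
#' dose-normalised disposition kernel, dropping the absorption exponential
#' (instantaneous-absorption assumption; at Ka around 12 1/h the absorption
#' term changes predictions by under 1% beyond ~0.4 h). A 1-compartment fit
#' yields a single-exponential UIR with a warning.
#'
#' @param fit A [fit_macro_model()] result.
#' @param average_dose Dose in ng at which the macro constants are
#'   expressed; defaults to the fit's reference (mean) dose.
#' @return A [uir()].
#' @export
derive_uir <- function(fit, average_dose = fit$dose_ref) {
  stopifnot(inherits(fit, "macro_model_fit"), average_dose > 0)
  if (fit$n_compartments == 1) {
    warning("1-compartment fit: UIR is a single exponential")
    return(uir(fit$A / average_dose, fit$alpha))
  }
  uir(c(fit$A, fit$B) / average_dose, c(fit$alpha, fit$beta))
}
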