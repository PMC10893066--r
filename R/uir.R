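# Unit impulse response: dose-normalised polyexponential disposition kernel.

#' Construct a unit impulse response (UIR)
#'
#' The UIR is the plasma concentration-time curve per unit of instantaneously
#' absorbed dose, represented as a sum of exponentials
#' \eqn{u(t) = \sum_i A_i e^{-\alpha_i t}} with coefficients in (ng/mL)/ng and
#' rates in 1/h. It is the kernel used for convolution and deconvolution of
#' implant absorption. Terms are sorted so that `alpha[1] > alpha[2] > ...`.
#'
#' The package default (`default_uir()`) is the disposition estimated for
#' islatravir in rats after subcutaneous bolus dosing: A1 = 9.8e-4,
#' A2 = 9.6e-6 (ng/mL)/ng, alpha1 = 1.2, alpha2 = 0.103 1/h.
#'
#' @param coefficients Positive coefficients, (ng/mL)/ng.
#' @param rates Positive first-order rates, 1/h, same length.
#' @return An object of class `uir` with elements `coefficients`, `rates`.
#' @export
uir <- function(coefficients, rates) {
  stopifnot(length(coefficients) == length(rates), length(rates) >= 1)
  if (any(!is.finite(coefficients)) || any(coefficients <= 0)) {
    stop("UIR coefficients must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("UIR rates must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(rates)) stop("UIR rates must be distinct", call. = FALSE)
  ord <- order(rates, decreasing = TRUE)
  structure(list(coefficients = as.numeric(coefficients[ord]),
                 rates = as.numeric(rates[ord])),
            class = "uir")
}

#' @rdname uir
#' @export
default_uir <- function() {
  uir(coefficients = c(9.8e-4, 9.6e-6), rates = c(1.2, 0.103))
}

#' Evaluate a UIR at given times
#'
#' @param u A [uir()].
#' @param times Times in hours, `>= 0`.
#' @return Concentrations per unit dose, (ng/mL)/ng.
#' @export
eval_uir <- function(u, times) {
  stopifnot(inherits(u, "uir"), all(times >= 0))
  drop(exp(-outer(times, u$rates)) %*% u$coefficients)
}

#' Area under the UIR from zero to infinity
#'
#' Analytic integral \eqn{\sum_i A_i/\alpha_i}, in h·(ng/mL)/ng. Multiplied
#' by a constant infusion rate in ng/h this gives the steady-state plasma
#' concentration in ng/mL.
#'
#' @param u A [uir()].
#' @return Scalar integral value.
#' @export
uir_auc <- function(u) {
  stopifnot(inherits(u, "uir"))
  sum(u$coefficients / u$rates)
}

#' @export
print.uir <- function(x, ...) {
  cat("<unit impulse response>\n")
  for (i in seq_along(x$rates)) {
    cat(sprintf("  A%d = %.6g (ng/mL)/ng   alpha%d = %.6g 1/h\n",
                i, x$coefficients[i], i, x$rates[i]))
  }
  cat(sprintf("  integral = %.6g h*(ng/mL)/ng\n", uir_auc(x)))
  invisible(x)
}
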