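#' Double-logistic calcium-flux activation model
#'
#' The population-level Fluo-4 kinetic after B-cell receptor crosslinking is
#' modelled as the sum of a rising and a falling logistic,
#' \deqn{f(t) = S + \frac{A_1}{1+e^{-r_1 (t-\tau_1)}} -
#'              \frac{A_2}{1+e^{-r_2 (t-\tau_2)}},}
#' the simplest smooth family whose limit at \eqn{-\infty} is the resting
#' level \eqn{S}, whose limit at \eqn{+\infty} is the plateau
#' \eqn{S + A_1 - A_2}, and which rises to a single maximum in between.
#'
#' @param t time in seconds (vectorised).
#' @param S pre-stimulus fluorescence level (intensity, > 0).
#' @param A1,A2 rise and decay amplitudes (intensity, >= 0).
#' @param r1,r2 rise and decay rates (1/s, > 0).
#' @param tau1,tau2 rise and decay midpoint times (s).
#' @return numeric vector of model values, same length as `t`.
#' @seealso [double_logistic_deriv()], [double_logistic_auc()],
#'   [kinetic_ground_truth()]
#' @export
#' @examples
#' double_logistic(210, S = 100, A1 = 120, r1 = 0.05, tau1 = 210,
#'                 A2 = 0, r2 = 0.015, tau2 = 420)  # S + A1/2
double_logistic <- function(t, S, A1, r1, tau1, A2, r2, tau2) {
  S + A1 * stats::plogis(r1 * (t - tau1)) - A2 * stats::plogis(r2 * (t - tau2))
}

#' First derivative of the double-logistic model
#'
#' Analytic derivative used for the slope parameters at the 50% crossing
#' times (units: intensity per second).
#'
#' @inheritParams double_logistic
#' @return numeric vector of derivative values.
#' @export
double_logistic_deriv <- function(t, S, A1, r1, tau1, A2, r2, tau2) {
  p1 <- stats::plogis(r1 * (t - tau1))
  p2 <- stats::plogis(r2 * (t - tau2))
  A1 * r1 * p1 * (1 - p1) - A2 * r2 * p2 * (1 - p2)
}

# log(1 + exp(x)) without overflow; primitive of the logistic cdf
log1pexp <- function(x) {
  out <- x
  small <- x <= 35
  out[small] <- log1p(exp(x[small]))
  # for x > 35, log(1+e^x) == x to double precision
  out
}

#' Closed-form definite integral of the double-logistic model
#'
#' Each logistic term integrates to a softplus primitive,
#' \eqn{\int \mathrm{plogis}(r(t-\tau))\,dt = \log(1+e^{r(t-\tau)})/r},
#' so the area under the fitted curve needs no quadrature.
#'
#' @inheritParams double_logistic
#' @param t0,t1 integration limits in seconds, `t0 <= t1`.
#' @return the integral of the (unstandardised) model over `[t0, t1]`.
#' @export
double_logistic_auc <- function(t0, t1, S, A1, r1, tau1, A2, r2, tau2) {
  if (any(t1 < t0)) stop("t1 must be >= t0")
  term <- function(A, r, tau) {
    if (A == 0) return(0)
    (A / r) * (log1pexp(r * (t1 - tau)) - log1pexp(r * (t0 - tau)))
  }
  S * (t1 - t0) + term(A1, r1, tau1) - term(A2, r2, tau2)
}

#' Ground-truth kinetic parameters for the synthetic generator
#'
#' Validates and stores one set of double-logistic coefficients describing
#' the true (noiseless) Fluo-4 kinetic of a cell subset. The constraints
#' encode the shape of a BCR activation curve: the rise precedes the decay
#' and the ending plateau never falls below the resting level.
#'
#' @inheritParams double_logistic
#' @return an object of class `kinetic_ground_truth` (named list of the
#'   seven coefficients).
#' @export
#' @examples
#' g <- kinetic_ground_truth(S = 100, A1 = 120, r1 = 0.05, tau1 = 210,
#'                           A2 = 66, r2 = 0.015, tau2 = 420)
#' true_curve(g, c(0, 300, 1020))
kinetic_ground_truth <- function(S, A1, r1, tau1, A2, r2, tau2) {
  stopifnot(is.numeric(S), is.numeric(A1), is.numeric(A2))
  if (S <= 0) stop("S must be > 0")
  if (A1 < 0 || A2 < 0) stop("amplitudes A1, A2 must be >= 0")
  if (r1 <= 0 || r2 <= 0) stop("rates r1, r2 must be > 0")
  if (A2 > A1) stop("A2 must not exceed A1 (plateau >= resting level)")
  if (A2 > 0 && tau1 >= tau2) stop("tau1 must precede tau2 when A2 > 0")
  structure(list(S = S, A1 = A1, r1 = r1, tau1 = tau1,
                 A2 = A2, r2 = r2, tau2 = tau2),
            class = "kinetic_ground_truth")
}

#' @export
print.kinetic_ground_truth <- function(x, ...) {
  cat("kinetic ground truth: S =", format(x$S),
      " A1 =", format(x$A1), " r1 =", format(x$r1), " tau1 =", format(x$tau1),
      "\n                      A2 =", format(x$A2), " r2 =", format(x$r2),
      " tau2 =", format(x$tau2), "\n")
  invisible(x)
}

#' Evaluate the noiseless ground-truth curve
#'
#' @param g a [kinetic_ground_truth()] object.
#' @param t time(s) in seconds.
#' @return expected fluorescence at `t` (total function, no error cases).
#' @export
true_curve <- function(g, t) {
  stopifnot(inherits(g, "kinetic_ground_truth"))
  double_logistic(t, g$S, g$A1, g$r1, g$tau1, g$A2, g$r2, g$tau2)
}
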