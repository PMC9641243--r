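#' Time-binned median-fluorescence series
#'
#' Partitions the acquisition into fixed-width bins `[k w, (k+1) w)` and
#' takes the per-bin median Fluo-4 intensity — the statistic the kinetic
#' model is fitted to, robust to the heavy right tail of cytometry
#' intensities. Bins with fewer events than `min_per_bin` are dropped;
#' when nothing survives the sample x subset is excluded (too few events
#' for a trustworthy curve).
#'
#' @param events event table for one gated subset (columns `time`,
#'   `Fluo4`).
#' @param bin_width bin width in seconds (> 0), default 5.
#' @param min_per_bin minimum events per retained bin, default 5.
#' @param stim_time stimulation time (s), carried on the result for the
#'   fitter.
#' @return object of class `kinetic_series`: a `data.table` with columns
#'   `time` (bin centre), `median`, `n`, plus attributes `stim_time`,
#'   `bin_width`.
#' @export
bin_median_series <- function(events, bin_width = 5, min_per_bin = 5,
                              stim_time = 120) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (nrow(events) == 0)
    stop("too few events: no bin reaches ", min_per_bin, " events")
  k <- floor(events$time / bin_width)
  dt <- data.table::data.table(k = k, y = events$Fluo4)
  agg <- dt[, list(median = stats::median(y), n = .N), by = "k"]
  agg <- agg[agg$n >= min_per_bin, ]
  if (nrow(agg) == 0)
    stop("too few events: no bin reaches ", min_per_bin, " events")
  data.table::setorderv(agg, "k")
  out <- data.table::data.table(time = (agg$k + 0.5) * bin_width,
                                median = agg$median, n = agg$n)
  data.table::setattr(out, "stim_time", stim_time)
  data.table::setattr(out, "bin_width", bin_width)
  data.table::setattr(out, "class",
                      c("kinetic_series", class(out)))
  out
}

#' Raw baseline median fluorescence
#'
#' Median Fluo-4 intensity over the pre-stimulation events (raw intensity
#' units, not standardised) — the basal cytoplasmic calcium readout.
#'
#' @param events event table for one gated subset.
#' @param stim_time stimulation time in seconds (default 120).
#' @return the baseline MFI.
#' @export
baseline_mfi <- function(events, stim_time = 120) {
  pre <- events$Fluo4[events$time < stim_time]
  if (length(pre) == 0) stop("no pre-stimulation events before t = ", stim_time)
  stats::median(pre)
}

# residual sum of squares of the double-logistic model on a series
.dl_rss <- function(par, t, y) {
  r <- y - double_logistic(t, par[1], par[2], par[3], par[4],
                           par[5], par[6], par[7])
  sum(r * r)
}

#' Fit the double-logistic model to a kinetic series
#'
#' Bounded nonlinear least squares (L-BFGS-B) of the seven-coefficient
#' double-logistic model to the (bin centre, median) pairs. Initialisation
#' is deterministic and data-driven: S from the pre-stimulation bins, the
#' ending level from the last 60 s, amplitudes from the observed maximum,
#' midpoints from the first crossings of the half levels, both rates at
#' 0.05/s. Up to five fixed perturbed restarts guard against local minima;
#' the best converged solution wins. No randomness: identical input gives
#' an identical fit.
#'
#' @param series a [bin_median_series()] result (or any data.frame with
#'   `time` and `median`; supply `stim_time` via attribute or argument).
#' @param stim_time override for the series' stimulation time.
#' @return object of class `double_logistic_fit`: list with the seven
#'   coefficients (`S`, `A1`, `r1`, `tau1`, `A2`, `r2`, `tau2`), `rss`,
#'   `converged`, `n_bins`.
#' @export
fit_double_logistic <- function(series, stim_time = NULL) {
  stim_time <- stim_time %||% attr(series, "stim_time") %||% 120
  t <- series$time; y <- series$median
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 8)
    stop("unusable fit: need >= 8 retained bins, got ", length(t))
  if (!any(t < stim_time) || !any(t >= stim_time))
    stop("unusable fit: series must span pre- and post-stimulation time")

  S0 <- stats::median(y[t < stim_time])
  E0 <- stats::median(y[t >= max(t) - 60])
  M <- max(y); tmax_obs <- t[which.max(y)]
  A1_0 <- max(M - S0, 1e-3 * S0)
  A2_0 <- min(max(S0 + A1_0 - E0, 1e-3 * S0), A1_0)
  half_up <- (S0 + M) / 2
  i1 <- which(y > half_up & t >= stim_time)
  tau1_0 <- if (length(i1)) t[min(i1)] else stim_time + 60
  post <- which(t > tmax_obs & y < (M + E0) / 2)
  tau2_0 <- if (length(post)) t[min(post)] else tmax_obs + 60
  if (tau2_0 <= tau1_0) tau2_0 <- tau1_0 + 30

  span <- max(t) - min(t)
  lower <- c(S = 1e-6, A1 = 0, r1 = 1e-4, tau1 = min(t) - span,
             A2 = 0, r2 = 1e-4, tau2 = min(t) - span)
  upper <- c(S = 10 * max(M, 1), A1 = 20 * max(M, 1), r1 = 2,
             tau1 = max(t) + span, A2 = 20 * max(M, 1), r2 = 2,
             tau2 = 2 * (max(t) + span))
  starts <- list(
    c(S0, A1_0, 0.05, tau1_0, A2_0, 0.05, tau2_0),
    c(S0, A1_0, 0.02, tau1_0, A2_0, 0.01, tau2_0),
    c(S0, A1_0, 0.15, tau1_0, A2_0, 0.03, tau2_0 + 60),
    c(S0, A1_0 * 1.5, 0.05, tau1_0 - 30, A2_0 * 1.5, 0.02, tau2_0 + 120),
    c(S0, A1_0, 0.01, tau1_0 + 30, A2_0 * 0.5, 0.005, tau2_0 + 240))
  parscale <- c(max(S0, 1), max(A1_0, 1), 0.05, max(span / 4, 1),
                max(A2_0, 1), 0.02, max(span / 4, 1))
  run1 <- function(p0) tryCatch(
    stats::optim(p0, .dl_rss, t = t, y = y, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 1000, factr = 1e2,
                                parscale = parscale)),
    error = function(e) NULL)
  best <- NULL
  for (p0 in starts) {
    res <- run1(pmin(pmax(p0, lower), upper))
    if (is.null(res)) next
    # L-BFGS-B sometimes ends a line search abnormally (code 52) at an
    # excellent solution; a restart from that point settles the verdict
    if (res$convergence != 0) {
      res2 <- run1(res$par)
      if (!is.null(res2) && res2$value <= res$value + 1e-12) res <- res2
    }
    res$ok <- res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
    if (best$ok && best$value < 1e-10 * max(1, sum(y * y))) break
  }
  if (is.null(best))
    stop("unusable fit: optimizer failed from every start")
  # a code-52 endpoint counts as converged only if a fresh restart from it
  # reproduces the same rss (stationary point, step size at noise floor)
  if (!best$ok) {
    res3 <- run1(best$par)
    best$ok <- !is.null(res3) &&
      (res3$convergence == 0 || abs(res3$value - best$value) <=
         1e-8 * max(best$value, 1e-12))
    if (!is.null(res3) && res3$value <= best$value) {
      best$par <- res3$par; best$value <- res3$value
    }
  }
  par <- best$par
  fit <- structure(list(S = par[[1]], A1 = par[[2]], r1 = par[[3]],
                        tau1 = par[[4]], A2 = par[[5]], r2 = par[[6]],
                        tau2 = par[[7]], rss = best$value,
                        converged = isTRUE(best$ok),
                        n_bins = length(t)),
                   class = "double_logistic_fit")
  if (!fit$converged)
    stop("unusable fit: optimizer did not converge")
  fit
}

#' @export
print.double_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "double-logistic fit (%d bins, rss %.4g)\n  S=%.4g A1=%.4g r1=%.4g tau1=%.4g A2=%.4g r2=%.4g tau2=%.4g\n",
    x$n_bins, x$rss, x$S, x$A1, x$r1, x$tau1, x$A2, x$r2, x$tau2))
  invisible(x)
}

# standardised curve and derivative: fitted model divided by its limit at
# minus infinity, so every curve starts at 1
.std_curve <- function(fit) {
  function(t) double_logistic(t, fit$S, fit$A1, fit$r1, fit$tau1,
                              fit$A2, fit$r2, fit$tau2) / fit$S
}
.std_deriv <- function(fit) {
  function(t) double_logistic_deriv(t, fit$S, fit$A1, fit$r1, fit$tau1,
                                    fit$A2, fit$r2, fit$tau2) / fit$S
}

#' Area under the standardised fitted curve
#'
#' Definite integral of the fitted curve divided by its starting limit,
#' computed in closed form (each logistic term has a softplus primitive).
#'
#' @param fit a [fit_double_logistic()] result.
#' @param t0,t1 integration limits in seconds (`t0 <= t1`).
#' @return the integral, in relative units times seconds.
#' @export
area_under_curve <- function(fit, t0 = 0, t1 = 1020) {
  if (t0 > t1) stop("t0 must be <= t1")
  double_logistic_auc(t0, t1, fit$S, fit$A1, fit$r1, fit$tau1,
                      fit$A2, fit$r2, fit$tau2) / fit$S
}

#' Derive the ten kinetic parameters from a fitted curve
#'
#' Standardises the fitted curve to start at 1 (division by its limit at
#' minus infinity) and extracts, on `[0, t_end]`: the maximum and its
#' time (1-s grid plus local refinement), the first-50% crossing — the
#' midpoint level between start and maximum, located by root-finding on
#' the ascending branch — with its analytic slope, the second-50% crossing
#' (midpoint between maximum and ending value, descending branch) with its
#' slope, the ending value (limit at plus infinity), and the closed-form
#' AUC over `[0, t_end]`. If the maximum sits at the domain boundary with
#' no descending branch, the descending-phase parameters are `NA` and
#' `descending` is flagged `FALSE`.
#'
#' @param fit a converged [fit_double_logistic()] result.
#' @param t_end end of the measurement window in seconds (default 1020).
#' @param baseline raw baseline MFI to carry along (see [baseline_mfi()]);
#'   optional.
#' @return object of class `kinetic_parameter_set`: one-row `data.frame`
#'   with columns `starting_value`, `time_to_first_50`, `slope_first_50`,
#'   `time_first50_to_max`, `time_to_max`, `max_value`,
#'   `time_max_to_second_50`, `slope_second_50`, `ending_value`, `auc`,
#'   `baseline_mfi`, and logical flags `ascending`, `descending`.
#' @export
derive_parameters <- function(fit, t_end = 1020, baseline = NA_real_) {
  stopifnot(inherits(fit, "double_logistic_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; parameters unusable")
  g <- .std_curve(fit); dg <- .std_deriv(fit)
  ending <- (fit$S + fit$A1 - fit$A2) / fit$S

  grid <- seq(0, t_end, by = 1)
  vals <- g(grid)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(g, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  t_max <- opt$maximum
  max_val <- opt$objective
  # boundary maximum with the curve still rising: no descending branch
  # (the refinement cannot leave the last 1-s grid cell, hence the window)
  descending <- !(t_max >= t_end - 1 && dg(t_end) > -1e-12) &&
    max_val > ending + 1e-9
  if (t_max >= t_end - 1 && dg(t_end) >= -1e-12 && !descending) {
    t_max <- t_end       # non-decreasing into the boundary: max is at t_end
    max_val <- g(t_end)
  }

  tol <- 1e-9
  ascending <- max_val > 1 + tol && g(0) < (1 + max_val) / 2
  t50_1 <- slope1 <- NA_real_
  if (ascending) {
    L1 <- (1 + max_val) / 2
    t50_1 <- stats::uniroot(function(t) g(t) - L1, c(0, t_max),
                            tol = 1e-8)$root
    slope1 <- dg(t50_1)
  }
  t50_2 <- slope2 <- NA_real_
  if (descending) {
    L2 <- (max_val + ending) / 2
    upper <- t_end
    k <- 0
    while (g(upper) > L2 && k < 60) { upper <- upper + (t_end - t_max + 60); k <- k + 1 }
    if (g(upper) <= L2) {
      t50_2 <- stats::uniroot(function(t) g(t) - L2, c(t_max, upper),
                              tol = 1e-8)$root
      slope2 <- dg(t50_2)
    } else {
      descending <- FALSE
    }
  }
  out <- data.frame(
    starting_value = 1,
    time_to_first_50 = t50_1,
    slope_first_50 = slope1,
    time_first50_to_max = if (ascending) t_max - t50_1 else NA_real_,
    time_to_max = t_max,
    max_value = max_val,
    time_max_to_second_50 = if (descending) t50_2 - t_max else NA_real_,
    slope_second_50 = slope2,
    ending_value = ending,
    auc = area_under_curve(fit, 0, t_end),
    baseline_mfi = baseline,
    ascending = ascending,
    descending = descending)
  class(out) <- c("kinetic_parameter_set", class(out))
  out
}

#' Names of the derived kinetic parameters
#'
#' @return character vector of the ten standardised curve parameters plus
#'   the raw baseline MFI, in reporting order.
#' @export
kinetic_parameter_names <- function() {
  c("starting_value", "time_to_first_50", "slope_first_50",
    "time_first50_to_max", "time_to_max", "max_value",
    "time_max_to_second_50", "slope_second_50", "ending_value", "auc",
    "baseline_mfi")
}
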