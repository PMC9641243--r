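#' FMO-derived positivity threshold
#'
#' The positivity cut for a channel is a high quantile of the matching
#' Fluorescence-Minus-One control: cells carrying every stain except this
#' one define the distribution of "negative" signal, and the threshold
#' leaves a fixed small fraction of that control above the gate.
#'
#' @param fmo_values intensities measured in the FMO control (nonempty).
#' @param q quantile in `(0, 1]`; default 0.995 (0.5% of the control
#'   counted positive).
#' @return the threshold intensity.
#' @export
fmo_threshold <- function(fmo_values, q = 0.995) {
  if (length(fmo_values) == 0) stop("empty FMO control")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  unname(stats::quantile(fmo_values, q, type = 7, names = FALSE))
}

#' Gating scheme: thresholds and the subset sign patterns
#'
#' Thresholds for the four gating channels plus the Fluo-4 loading gate.
#' Events strictly above a threshold are positive; events exactly at it
#' count negative (deterministic tie-break). The four IgD/CD27 patterns
#' over CD19-positive events are naive (+,-), non-switched memory (+,+),
#' switched memory (-,+) and double-negative memory (-,-) — mutually
#' exclusive and exhaustive.
#'
#' @param CD19,IgD,CD27,CD25 per-channel thresholds (finite).
#' @param loading Fluo-4 threshold for the indicator-loading (viability)
#'   gate: only live cells with intact membranes retain the dye.
#' @return an object of class `gating_scheme`.
#' @export
gating_scheme <- function(CD19, IgD, CD27, CD25, loading = 10) {
  th <- c(CD19 = CD19, IgD = IgD, CD27 = CD27, CD25 = CD25,
          loading = loading)
  if (any(!is.finite(th))) stop("all thresholds must be finite")
  structure(as.list(th), class = "gating_scheme")
}

#' Gating scheme from FMO controls
#'
#' @param fmo named list of FMO intensity vectors for `CD19`, `IgD`,
#'   `CD27`, `CD25`.
#' @param q FMO quantile, see [fmo_threshold()].
#' @param loading Fluo-4 loading threshold.
#' @return a [gating_scheme()].
#' @export
gating_scheme_from_fmo <- function(fmo, q = 0.995, loading = 10) {
  need <- c("CD19", "IgD", "CD27", "CD25")
  miss <- setdiff(need, names(fmo))
  if (length(miss)) stop("missing FMO control(s): ", paste(miss, collapse = ", "))
  gating_scheme(CD19 = fmo_threshold(fmo$CD19, q),
                IgD = fmo_threshold(fmo$IgD, q),
                CD27 = fmo_threshold(fmo$CD27, q),
                CD25 = fmo_threshold(fmo$CD25, q),
                loading = loading)
}

#' Gating scheme matching the default synthetic world
#'
#' Fixed thresholds at the geometric midpoint of the generator's negative
#' and positive marker populations (intensity 100), with the default
#' loading gate at 10.
#'
#' @return a [gating_scheme()].
#' @export
default_gating_scheme <- function() {
  mid <- exp((log(10) + log(1000)) / 2)
  gating_scheme(CD19 = mid, IgD = mid, CD27 = mid, CD25 = mid, loading = 10)
}

#' Classify events into B-cell subsets
#'
#' CD19-negative events are `non_b`; CD19-positive events are assigned by
#' their IgD/CD27 sign pattern, CD25 status by its own threshold, and
#' every event gets a viability flag from the Fluo-4 loading gate.
#'
#' @param events event table with the required channels.
#' @param scheme a [gating_scheme()].
#' @return `data.table` with columns `subset` (factor: naive, NSw, Sw, DN,
#'   non_b), `cd25` (logical) and `viable` (logical), one row per event.
#' @export
classify_events <- function(events, scheme) {
  stopifnot(inherits(scheme, "gating_scheme"))
  miss <- setdiff(c("CD19", "IgD", "CD27", "CD25", "Fluo4"), names(events))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  b <- events$CD19 > scheme$CD19
  igd <- events$IgD > scheme$IgD
  cd27 <- events$CD27 > scheme$CD27
  subset <- rep("non_b", nrow(events))
  subset[b & igd & !cd27] <- "naive"
  subset[b & igd & cd27] <- "NSw"
  subset[b & !igd & cd27] <- "Sw"
  subset[b & !igd & !cd27] <- "DN"
  data.table::data.table(
    subset = factor(subset, levels = c("naive", "NSw", "Sw", "DN", "non_b")),
    cd25 = events$CD25 > scheme$CD25,
    viable = events$Fluo4 > scheme$loading)
}

#' Subset prevalences among viable B cells
#'
#' Percentages of each IgD/CD27 subset among CD19-positive viable events,
#' plus the CD25-positive percentage within each subset.
#'
#' @param labels output of [classify_events()].
#' @return `data.table` with columns `subset`, `n`, `percent` (of B
#'   cells; sums to 100) and `cd25_percent` (within the subset).
#' @export
prevalence_table <- function(labels) {
  b <- labels[labels$subset != "non_b" & labels$viable, ]
  if (nrow(b) == 0) stop("no viable B-cell events to tabulate")
  subs <- c("naive", "NSw", "Sw", "DN")
  out <- data.table::data.table(
    subset = subs,
    n = vapply(subs, function(s) sum(b$subset == s), integer(1)))
  out$percent <- 100 * out$n / nrow(b)
  out$cd25_percent <- vapply(subs, function(s) {
    n <- sum(b$subset == s)
    if (n == 0) return(NA_real_)
    100 * sum(b$subset == s & b$cd25) / n
  }, numeric(1))
  out
}

#' Indicator-loading viability fraction
#'
#' Fraction of lymphocyte-gated events passing the Fluo-4 loading gate. In
#' the synthetic world (no scatter channels) the lymphocyte gate is the
#' all-events gate.
#'
#' @param events event table (nonempty).
#' @param scheme a [gating_scheme()].
#' @return fraction in `[0, 1]`.
#' @export
viability_fraction <- function(events, scheme) {
  if (nrow(events) == 0) stop("no events")
  mean(events$Fluo4 > scheme$loading)
}
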