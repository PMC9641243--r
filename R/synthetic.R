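#' Specification of one simulated cell subset
#'
#' Describes a mixture component of the synthetic event stream: its share of
#' events, its marker expression (log-normal on each panel channel), its true
#' Fluo-4 kinetic, and the fraction of its cells successfully loaded with
#' the calcium indicator.
#'
#' @param label unique component name, e.g. `"naive-"` or `"non_b"`.
#' @param subset biological subset: one of `"naive"`, `"NSw"`, `"Sw"`,
#'   `"DN"`, `"non_b"`.
#' @param cd25 logical CD25 status (`NA` for non-B events).
#' @param proportion fraction of all events drawn from this component.
#' @param marker_means,marker_sds named numeric vectors (natural-log scale)
#'   over the surface channels `CD19, IgD, CD27, CD25, CD5`.
#' @param kinetics a [kinetic_ground_truth()] for this component's Fluo-4
#'   signal.
#' @param loaded_fraction fraction of cells loaded with Fluo-4, in `[0, 1]`.
#' @return an object of class `subset_spec`.
#' @export
subset_spec <- function(label, subset, cd25, proportion,
                        marker_means, marker_sds, kinetics,
                        loaded_fraction = 0.98) {
  chans <- setdiff(panel_channels(), "Fluo4")
  stopifnot(all(chans %in% names(marker_means)),
            all(chans %in% names(marker_sds)),
            inherits(kinetics, "kinetic_ground_truth"))
  if (proportion < 0 || proportion > 1) stop("proportion must be in [0, 1]")
  if (loaded_fraction < 0 || loaded_fraction > 1)
    stop("loaded_fraction must be in [0, 1]")
  structure(list(label = label, subset = subset, cd25 = cd25,
                 proportion = proportion,
                 marker_means = marker_means[chans],
                 marker_sds = marker_sds[chans],
                 kinetics = kinetics,
                 loaded_fraction = loaded_fraction),
            class = "subset_spec")
}

# Log-scale locations for a cleanly separated synthetic panel: negative and
# positive populations sit ~13 population-SDs apart, comfortably beyond the
# >= 6 SD separation the gating-recovery tests assume.
.marker_pos <- log(1000)
.marker_neg <- log(10)
.marker_sd <- 0.35

.subset_pattern <- function(subset, cd25) {
  pos <- .marker_pos; neg <- .marker_neg
  if (subset == "non_b")
    return(c(CD19 = neg, IgD = neg, CD27 = neg, CD25 = neg, CD5 = neg))
  c(CD19 = pos,
    IgD  = if (subset %in% c("naive", "NSw")) pos else neg,
    CD27 = if (subset %in% c("NSw", "Sw")) pos else neg,
    CD25 = if (isTRUE(cd25)) pos else neg,
    CD5  = neg)
}

#' Default subset mixture for one simulated sample
#'
#' Builds the nine mixture components of the default synthetic world: the
#' four IgD/CD27 B-cell subsets, each split into a CD25- majority and a
#' CD25+ minority, plus non-B lymphocytes. B cells are 20% of events
#' (naive 60%, non-switched 20%, switched 12%, double-negative 8% of B
#' cells); 12% of each subset is CD25+. The shared base kinetic rises from
#' S = 100 with amplitude 1.2 S (rise midpoint 90 s post-stimulation,
#' r1 = 0.05/s) and decays by 55% of the rise toward the plateau
#' (tau2 = 420 s, r2 = 0.015/s); CD25+ compartments respond 1.4x more
#' strongly, and non-B cells do not respond at all.
#'
#' @param baseline_mult multiplier on the resting level S (group or sample
#'   effect on basal calcium).
#' @param amplitude_mult multiplier on both amplitudes A1, A2 (scales the
#'   standardised AUC excess over baseline proportionally).
#' @param loaded_fraction Fluo-4 loading success per cell; the default 0.98
#'   leaves the simulated cohorts above the 95% loading-viability gate.
#' @param b_fraction fraction of events that are B cells.
#' @param cd25_fraction CD25+ fraction within each B subset.
#' @return list of [subset_spec()] objects whose proportions sum to 1.
#' @export
default_subset_specs <- function(baseline_mult = 1, amplitude_mult = 1,
                                 loaded_fraction = 0.98, b_fraction = 0.2,
                                 cd25_fraction = 0.12) {
  stopifnot(b_fraction >= 0, b_fraction <= 1,
            cd25_fraction >= 0, cd25_fraction <= 1)
  S <- 100 * baseline_mult
  base_A1 <- 1.2 * 100
  subset_factor <- c(naive = 1.0, NSw = 1.1, Sw = 1.0, DN = 0.95)
  b_share <- c(naive = 0.60, NSw = 0.20, Sw = 0.12, DN = 0.08)
  specs <- list()
  for (ss in names(b_share)) {
    for (pos in c(FALSE, TRUE)) {
      A1 <- base_A1 * subset_factor[[ss]] * (if (pos) 1.4 else 1) *
        amplitude_mult * baseline_mult
      g <- kinetic_ground_truth(S = S, A1 = A1, r1 = 0.05, tau1 = 210,
                                A2 = 0.55 * A1, r2 = 0.015, tau2 = 420)
      prop <- b_fraction * b_share[[ss]] *
        (if (pos) cd25_fraction else 1 - cd25_fraction)
      lab <- paste0(ss, if (pos) "+" else "-")
      specs[[lab]] <- subset_spec(
        label = lab, subset = ss, cd25 = pos, proportion = prop,
        marker_means = .subset_pattern(ss, pos),
        marker_sds = rep(.marker_sd, 5) |> stats::setNames(setdiff(panel_channels(), "Fluo4")),
        kinetics = g, loaded_fraction = loaded_fraction)
    }
  }
  g_flat <- kinetic_ground_truth(S = S, A1 = 0, r1 = 0.05, tau1 = 210,
                                 A2 = 0, r2 = 0.015, tau2 = 420)
  specs[["non_b"]] <- subset_spec(
    label = "non_b", subset = "non_b", cd25 = NA, proportion = 1 - b_fraction,
    marker_means = .subset_pattern("non_b", NA),
    marker_sds = rep(.marker_sd, 5) |> stats::setNames(setdiff(panel_channels(), "Fluo4")),
    kinetics = g_flat, loaded_fraction = loaded_fraction)
  specs
}

#' Generate one kinetic event stream
#'
#' Draws `n_events` cytometry events over a kinetic acquisition:
#' acquisition times uniform on `[0, duration]` (sorted, as an instrument
#' would record them), mixture membership by component proportion, surface
#' markers log-normal per component, and Fluo-4 log-normal around the
#' component's true curve after stimulation (around its resting level S
#' before). Cells that failed indicator loading get near-zero Fluo-4
#' (log-normal with median 1). Ground-truth columns (`truth_subset`,
#' `truth_cd25`, `truth_loaded`) travel with the table as extra channels.
#'
#' @param specs list of [subset_spec()]; proportions must sum to 1.
#' @param n_events number of events (>= 0).
#' @param duration acquisition length in seconds (default 1020 = 17 min).
#' @param stim_time stimulation time in seconds (default 120; the first two
#'   minutes are the unstimulated baseline).
#' @param seed integer seed; identical seeds give identical streams.
#' @param fluo_sigma log-scale SD of the multiplicative Fluo-4 noise. The
#'   default 0.06 is calibrated so that with a default acquisition
#'   (50,000 events, 5-s bins) every binned median sits within 2% of the
#'   true curve; biological variability enters between samples, not here.
#' @param sample_id sample identifier attached to the table.
#' @return a `data.table` with columns `time`, the five surface channels,
#'   `Fluo4`, and the three `truth_*` columns.
#' @export
generate_event_stream <- function(specs, n_events, duration = 1020,
                                  stim_time = 120, seed = 1,
                                  fluo_sigma = 0.06, sample_id = "sample") {
  stopifnot(n_events >= 0, duration > 0, stim_time >= 0)
  props <- vapply(specs, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-6)
    stop("subset proportions must sum to 1 (got ", format(sum(props)), ")")
  chans <- setdiff(panel_channels(), "Fluo4")
  empty <- data.table::data.table(
    time = numeric(0), CD19 = numeric(0), IgD = numeric(0),
    CD27 = numeric(0), CD25 = numeric(0), CD5 = numeric(0),
    Fluo4 = numeric(0), truth_subset = character(0),
    truth_cd25 = logical(0), truth_loaded = logical(0))
  if (n_events == 0) {
    data.table::setattr(empty, "sample_id", sample_id)
    return(empty)
  }
  local_seed(seed, {
    tm <- sort(stats::runif(n_events, 0, duration))
    comp <- sample.int(length(specs), n_events, replace = TRUE, prob = props)
    mu <- t(vapply(specs, `[[`, numeric(5), "marker_means"))[comp, , drop = FALSE]
    sd <- t(vapply(specs, `[[`, numeric(5), "marker_sds"))[comp, , drop = FALSE]
    markers <- exp(matrix(stats::rnorm(n_events * 5), ncol = 5) * sd + mu)
    colnames(markers) <- chans
    loaded <- stats::runif(n_events) <
      vapply(specs, `[[`, numeric(1), "loaded_fraction")[comp]
    med <- numeric(n_events)
    for (i in seq_along(specs)) {
      sel <- comp == i
      if (!any(sel)) next
      g <- specs[[i]]$kinetics
      med[sel] <- ifelse(tm[sel] < stim_time, g$S, true_curve(g, tm[sel]))
    }
    fluo <- numeric(n_events)
    fluo[loaded] <- med[loaded] * exp(stats::rnorm(sum(loaded), 0, fluo_sigma))
    fluo[!loaded] <- exp(stats::rnorm(sum(!loaded), 0, 0.5))
    out <- data.table::data.table(
      time = tm, markers,
      Fluo4 = fluo,
      truth_subset = vapply(specs, `[[`, character(1), "subset")[comp],
      truth_cd25 = vapply(specs, function(s) isTRUE(s$cd25), logical(1))[comp],
      truth_loaded = loaded)
    data.table::setattr(out, "sample_id", sample_id)
    out[]
  })
}

#' Simulate an FMO control for one channel
#'
#' Regenerates the mixture with the named channel's antibody omitted (every
#' component's location on that channel collapses to the negative
#' population), and returns that channel's intensities — the distribution a
#' Fluorescence-Minus-One control measures.
#'
#' @inheritParams generate_event_stream
#' @param channel one of the surface channels.
#' @return numeric vector of `n_events` intensities.
#' @export
fmo_control_stream <- function(specs, channel, n_events, seed = 1) {
  stopifnot(channel %in% setdiff(panel_channels(), "Fluo4"))
  specs <- lapply(specs, function(s) {
    s$marker_means[channel] <- .marker_neg
    s
  })
  generate_event_stream(specs, n_events, seed = seed)[[channel]]
}

#' Cohort simulation design
#'
#' One row of `groups` per study arm, with per-group multipliers applied on
#' top of the default subset kinetics; between-sample biological variation
#' is log-normal on both the resting level and the amplitudes. A paired
#' pre/post arm (the levothyroxine design) shares subject identifiers
#' between two groups.
#'
#' @param groups data.frame with columns `group`, `n_samples`,
#'   `baseline_mult`, `amplitude_mult`.
#' @param paired `NULL`, or `c(pre = "<group>", post = "<group>")`; the post
#'   group's subjects are the first `n_samples` subjects of the pre group,
#'   so the post arm may be smaller (missed follow-up samples).
#' @param events_per_sample events per simulated acquisition.
#' @param duration,stim_time acquisition window in seconds.
#' @param unloaded_fraction per-sample fraction of indicator-negative cells
#'   (default 0.02, so cohorts sit above the 95% loading-viability gate).
#' @param between_sd_baseline,between_sd_amplitude log-scale SDs of the
#'   between-sample multipliers.
#' @param fluo_sigma within-sample Fluo-4 noise (log-scale SD).
#' @param b_fraction,cd25_fraction passed to [default_subset_specs()].
#' @param seed master seed; all per-sample streams are split from it.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(groups, paired = NULL, events_per_sample = 100000,
                          duration = 1020, stim_time = 120,
                          unloaded_fraction = 0.02,
                          between_sd_baseline = 0.10,
                          between_sd_amplitude = 0.15,
                          fluo_sigma = 0.06,
                          b_fraction = 0.2, cd25_fraction = 0.12, seed = 1) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n_samples", "baseline_mult", "amplitude_mult")
                %in% names(groups)))
  if (anyDuplicated(groups$group)) stop("duplicate group names")
  if (duration < stim_time) stop("duration must be >= stim_time")
  if (!is.null(paired)) {
    if (!all(c("pre", "post") %in% names(paired)) ||
        !all(paired %in% groups$group))
      stop("paired must name existing 'pre' and 'post' groups")
    n_pre <- groups$n_samples[groups$group == paired[["pre"]]]
    n_post <- groups$n_samples[groups$group == paired[["post"]]]
    if (n_post > n_pre)
      stop("paired post group cannot have more subjects than the pre group")
  }
  structure(list(groups = groups, paired = paired,
                 events_per_sample = events_per_sample,
                 duration = duration, stim_time = stim_time,
                 unloaded_fraction = unloaded_fraction,
                 between_sd_baseline = between_sd_baseline,
                 between_sd_amplitude = between_sd_amplitude,
                 fluo_sigma = fluo_sigma,
                 b_fraction = b_fraction, cd25_fraction = cd25_fraction,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' The default synthetic cohort: 12 replicate samples
#'
#' Twelve samples of 100,000 events each from the default world (the
#' replicate count the power analysis fixed for each study arm).
#'
#' @param n_samples,events_per_sample,seed overrides.
#' @param ... further arguments to [cohort_design()].
#' @return a `cohort_design`.
#' @export
default_cohort_design <- function(n_samples = 12, events_per_sample = 100000,
                                  seed = 1, ...) {
  cohort_design(
    data.frame(group = "HC", n_samples = n_samples,
               baseline_mult = 1, amplitude_mult = 1),
    events_per_sample = events_per_sample, seed = seed, ...)
}

#' The four-arm study layout
#'
#' Healthy controls (n=12), hypothyroid patients before treatment (H1,
#' n=14), the same subjects after levothyroxine (H2, n=12, paired with H1),
#' and euthyroid ATA-positive infertile patients (HIE, n=14). Default
#' effect multipliers encode the study's qualitative findings: elevated
#' basal calcium and amplified flux in HIE, slightly lowered basal level
#' after treatment.
#'
#' @param events_per_sample,seed overrides.
#' @param ... further arguments to [cohort_design()].
#' @return a `cohort_design`.
#' @export
study_cohort_design <- function(events_per_sample = 100000, seed = 1, ...) {
  cohort_design(
    data.frame(group = c("HC", "H1", "H2", "HIE"),
               n_samples = c(12, 14, 12, 14),
               baseline_mult = c(1, 1, 0.9, 1.25),
               amplitude_mult = c(1, 1, 1, 1.3)),
    paired = c(pre = "H1", post = "H2"),
    events_per_sample = events_per_sample, seed = seed, ...)
}

#' Generate a cohort of sample files plus manifest and ground truth
#'
#' Writes one event table per sample (CSV dialect or FCS 3.0), a
#' `manifest.csv` (sample, group, subject, pairing, path, per-sample seed
#' and realised effect multipliers) and a `truth.csv` holding the full
#' per-sample, per-component double-logistic ground truth. Regeneration
#' with the same design is byte-identical.
#'
#' @param design a [cohort_design()].
#' @param out_dir output directory (created if missing).
#' @param format `"csv"` or `"fcs"`.
#' @return invisibly, a list with `manifest` (data.frame), `truth`
#'   (data.frame) and `dir`.
#' @export
generate_cohort <- function(design, out_dir, format = c("csv", "fcs")) {
  stopifnot(inherits(design, "cohort_design"))
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  manifest <- list(); truth <- list()
  idx <- 0L
  for (gi in seq_len(nrow(design$groups))) {
    grp <- design$groups$group[gi]
    is_post <- !is.null(design$paired) && grp == design$paired[["post"]]
    subj_group <- if (is_post) design$paired[["pre"]] else grp
    for (si in seq_len(design$groups$n_samples[gi])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", grp, si)
      subject <- sprintf("%s_subj%02d", subj_group, si)
      sseed <- split_seed(design$seed, idx)
      mults <- local_seed(sseed, {
        c(base = exp(stats::rnorm(1, 0, design$between_sd_baseline)),
          amp = exp(stats::rnorm(1, 0, design$between_sd_amplitude)))
      })
      bmult <- design$groups$baseline_mult[gi] * mults[["base"]]
      amult <- design$groups$amplitude_mult[gi] * mults[["amp"]]
      specs <- default_subset_specs(
        baseline_mult = bmult, amplitude_mult = amult,
        loaded_fraction = 1 - design$unloaded_fraction,
        b_fraction = design$b_fraction,
        cd25_fraction = design$cd25_fraction)
      ev <- generate_event_stream(
        specs, design$events_per_sample, duration = design$duration,
        stim_time = design$stim_time, seed = split_seed(sseed, 1L),
        fluo_sigma = design$fluo_sigma, sample_id = sid)
      path <- file.path(out_dir, paste0(sid, ".", format))
      if (format == "csv") write_event_table(ev, path)
      else suppressWarnings(write_fcs(ev, path))  # FCS carries numeric only

      manifest[[idx]] <- data.frame(
        sample_id = sid, group = grp, subject_id = subject,
        path = basename(path), seed = sseed,
        baseline_mult = bmult, amplitude_mult = amult)
      truth[[idx]] <- do.call(rbind, lapply(specs, function(s) data.frame(
        sample_id = sid, label = s$label, subset = s$subset,
        cd25 = s$cd25, proportion = s$proportion,
        loaded_fraction = s$loaded_fraction,
        S = s$kinetics$S, A1 = s$kinetics$A1, r1 = s$kinetics$r1,
        tau1 = s$kinetics$tau1, A2 = s$kinetics$A2, r2 = s$kinetics$r2,
        tau2 = s$kinetics$tau2)))
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  data.table::fwrite(truth, file.path(out_dir, "truth.csv"))
  invisible(list(manifest = manifest, truth = truth, dir = out_dir))
}
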