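#' Gate one sample and extract its kinetic parameters
#'
#' Classifies events, applies the loading-viability gate, and for each
#' B-cell subset (optionally split by CD25) computes the binned median
#' series, the raw baseline MFI, the double-logistic fit and the derived
#' parameter set. Subsets whose curves cannot be fitted (too few events,
#' or a non-converging fit) are excluded with a recorded reason, never
#' silently dropped.
#'
#' @param events event table for one sample.
#' @param scheme a [gating_scheme()].
#' @param sample_id sample identifier for the output rows.
#' @param bin_width,min_per_bin,stim_time,t_end kinetic settings, see
#'   [bin_median_series()] and [derive_parameters()].
#' @param split_cd25 also analyse each subset's CD25- and CD25+
#'   compartments.
#' @return list with `parameters` (long data.table: `sample_id`,
#'   `subset`, `parameter`, `value`), `prevalence`, `viability`,
#'   `exclusions` (`sample_id`, `subset`, `reason`).
#' @export
analyze_sample <- function(events, scheme, sample_id = "sample",
                           bin_width = 5, min_per_bin = 5,
                           stim_time = 120, t_end = 1020,
                           split_cd25 = FALSE) {
  labels <- classify_events(events, scheme)
  viab <- viability_fraction(events, scheme)
  prev <- prevalence_table(labels)
  prev <- data.table::data.table(sample_id = sample_id, prev)

  subsets <- c("naive", "NSw", "Sw", "DN")
  sel <- stats::setNames(
    lapply(subsets, function(s) labels$subset == s & labels$viable), subsets)
  if (split_cd25) {
    for (s in subsets) {
      sel[[paste0(s, "_CD25-")]] <- sel[[s]] & !labels$cd25
      sel[[paste0(s, "_CD25+")]] <- sel[[s]] & labels$cd25
    }
  }
  params <- list(); excl <- list()
  for (nm in names(sel)) {
    sub_ev <- events[sel[[nm]], c("time", "Fluo4"), with = FALSE]
    res <- tryCatch({
      series <- bin_median_series(sub_ev, bin_width = bin_width,
                                  min_per_bin = min_per_bin,
                                  stim_time = stim_time)
      base <- baseline_mfi(sub_ev, stim_time = stim_time)
      fit <- fit_double_logistic(series)
      derive_parameters(fit, t_end = t_end, baseline = base)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excl[[length(excl) + 1L]] <- data.table::data.table(
        sample_id = sample_id, subset = nm, reason = res)
    } else {
      vals <- unlist(res[1, kinetic_parameter_names()])
      params[[length(params) + 1L]] <- data.table::data.table(
        sample_id = sample_id, subset = nm,
        parameter = kinetic_parameter_names(), value = unname(vals))
    }
  }
  list(parameters = if (length(params)) data.table::rbindlist(params)
       else data.table::data.table(sample_id = character(0),
                                   subset = character(0),
                                   parameter = character(0),
                                   value = numeric(0)),
       prevalence = prev,
       viability = data.table::data.table(sample_id = sample_id,
                                          viability = viab),
       exclusions = if (length(excl)) data.table::rbindlist(excl)
       else data.table::data.table(sample_id = character(0),
                                   subset = character(0),
                                   reason = character(0)))
}

.resolve_scheme <- function(cfg) {
  g <- cfg$gating
  if (!is.null(g$thresholds)) {
    do.call(gating_scheme, c(g$thresholds,
                             list(loading = g$loading_threshold %||% 10)))
  } else if (!is.null(g$fmo_files)) {
    fmo <- lapply(g$fmo_files, function(p) data.table::fread(p)[[1]])
    gating_scheme_from_fmo(fmo, q = g$fmo_quantile %||% 0.995,
                           loading = g$loading_threshold %||% 10)
  } else {
    default_gating_scheme()
  }
}

#' Run the full analysis pipeline
#'
#' read/compensate, gate, bin/fit/derive, then cohort statistics, writing
#' a machine-readable results bundle: `parameters.csv`, `prevalence.csv`,
#' `viability.csv`, `exclusions.csv`, `outliers.csv`,
#' `comparisons_groups.csv`, `comparisons_paired.csv` (for a paired
#' config) and `run.json`. Re-running with identical inputs produces an
#' identical bundle.
#'
#' @param config configuration list ([default_run_config()] shape) or the
#'   path of a YAML file for [read_run_config()].
#' @param quiet suppress per-sample progress on stderr.
#' @return invisibly, a list of the bundle tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config)
  else merge_config(config, default_run_config())
  if (is.null(cfg$manifest)) stop("config$manifest is required")
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- read_manifest(cfg$manifest)
  scheme <- .resolve_scheme(cfg)
  spill <- NULL
  if (!is.null(cfg$compensation)) {
    m <- as.matrix(data.table::fread(cfg$compensation), rownames = 1)
    spill <- spillover_matrix(m)
  }
  kin <- cfg$kinetics
  per <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    if (!quiet) message("[fluxkin] sample ", sid, " (", i, "/", nrow(man), ")")
    ev <- read_event_table(man$path[i], channel_map = cfg$channel_map)
    if (!is.null(spill)) ev <- apply_compensation(ev, spill)
    per[[i]] <- analyze_sample(
      ev, scheme, sample_id = sid,
      bin_width = kin$bin_width, min_per_bin = kin$min_per_bin,
      stim_time = kin$stim_time, t_end = kin$t_end,
      split_cd25 = isTRUE(kin$split_cd25))
  }
  pull <- function(what) data.table::rbindlist(lapply(per, `[[`, what))
  params <- pull("parameters")
  key <- man[, c("sample_id", "group", "subject_id")]
  params <- merge(key, params, by = "sample_id")
  data.table::setorderv(params, c("group", "sample_id", "subset", "parameter"))
  prevalence <- merge(key, pull("prevalence"), by = "sample_id")
  viability <- merge(key, pull("viability"), by = "sample_id")
  exclusions <- pull("exclusions")
  data.table::setorderv(prevalence, c("group", "sample_id", "subset"))
  data.table::setorderv(viability, c("group", "sample_id"))

  # Grubbs screen per group x subset x parameter (finest exchangeable stratum)
  outliers <- data.table::data.table(sample_id = character(0),
                                     group = character(0),
                                     subset = character(0),
                                     parameter = character(0),
                                     value = numeric(0))
  if (isTRUE(cfg$stats$grubbs)) {
    grp <- paste(params$group, params$subset, params$parameter, sep = "\r")
    drop <- logical(nrow(params))
    for (g in unique(grp)) {
      ii <- which(grp == g)
      if (length(ii) >= 3)
        drop[ii[grubbs_outliers(params$value[ii],
                                alpha = cfg$stats$grubbs_alpha %||% 0.01)]] <- TRUE
    }
    outliers <- params[drop, c("sample_id", "group", "subset", "parameter",
                               "value"), with = FALSE]
    params_clean <- params[!drop, ]
  } else params_clean <- params

  pars <- cfg$stats$parameters %||% kinetic_parameter_names()
  pars <- intersect(pars, unique(params_clean$parameter))
  cmp_groups <- cmp_paired <- NULL
  unpaired_groups <- setdiff(unique(params_clean$group),
                             cfg$stats$paired[["post"]] %||% character(0))
  if (length(unpaired_groups) >= 2) {
    cmp_groups <- data.table::rbindlist(lapply(pars, function(p) {
      d <- params_clean[params_clean$group %in% unpaired_groups, ]
      data.table::data.table(parameter = p, group_subset_comparisons(d, p))
    }))
  }
  if (!is.null(cfg$stats$paired)) {
    pr <- cfg$stats$paired
    cmp_paired <- data.table::rbindlist(lapply(pars, function(p) {
      data.table::data.table(
        parameter = p,
        paired_mixed_comparisons(params_clean, pr[["pre"]], pr[["post"]], p))
    }))
  }

  out <- list(parameters = params, prevalence = prevalence,
              viability = viability, exclusions = exclusions,
              outliers = outliers, comparisons_groups = cmp_groups,
              comparisons_paired = cmp_paired)
  wr <- function(x, f) if (!is.null(x))
    data.table::fwrite(x, file.path(cfg$out_dir, f))
  wr(params, "parameters.csv")
  wr(prevalence, "prevalence.csv")
  wr(viability, "viability.csv")
  wr(exclusions, "exclusions.csv")
  wr(outliers, "outliers.csv")
  wr(cmp_groups, "comparisons_groups.csv")
  wr(cmp_paired, "comparisons_paired.csv")
  run <- list(package = "fluxkin",
              version = as.character(utils::packageVersion("fluxkin")),
              seed = cfg$seed,
              n_samples = nrow(man),
              n_analyzed = length(unique(params$sample_id)),
              n_excluded_rows = nrow(exclusions),
              config = cfg[c("gating", "kinetics", "stats")])
  jsonlite::write_json(run, file.path(cfg$out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

#' Write a Markdown summary report for a results bundle
#'
#' Per-group prevalence means, viability range, exclusion accounting and
#' the significant comparisons, mirroring the structure of a cohort
#' figure panel.
#'
#' @param bundle_dir directory written by [run_pipeline()].
#' @param alpha significance highlight level.
#' @return the report path, invisibly.
#' @export
write_report <- function(bundle_dir, alpha = 0.05) {
  rd <- function(f) {
    p <- file.path(bundle_dir, f)
    if (file.exists(p)) data.table::fread(p) else NULL
  }
  prev <- rd("prevalence.csv"); viab <- rd("viability.csv")
  excl <- rd("exclusions.csv"); cmp <- rd("comparisons_groups.csv")
  cmp_p <- rd("comparisons_paired.csv")
  lines <- c("# fluxkin run report", "")
  if (!is.null(viab))
    lines <- c(lines, sprintf(
      "Loading viability across %d samples: min %.1f%%, median %.1f%%.",
      nrow(viab), 100 * min(viab$viability),
      100 * stats::median(viab$viability)), "")
  if (!is.null(prev)) {
    lines <- c(lines, "## Subset prevalence (% of viable B cells, group means)",
               "", "| group | subset | mean % | mean CD25+ % |",
               "|---|---|---|---|")
    agg <- prev[, list(percent = mean(percent),
                       cd25 = mean(cd25_percent)), by = c("group", "subset")]
    lines <- c(lines, sprintf("| %s | %s | %.1f | %.1f |",
                              agg$group, agg$subset, agg$percent, agg$cd25))
    lines <- c(lines, "")
  }
  if (!is.null(excl)) {
    lines <- c(lines, sprintf(
      "## Exclusions: %d sample x subset curves could not be fitted",
      nrow(excl)), "")
    if (nrow(excl))
      lines <- c(lines, sprintf("- %s / %s: %s", excl$sample_id,
                                excl$subset, excl$reason), "")
  }
  sig_block <- function(d, title) {
    if (is.null(d)) return(character(0))
    s <- d[is.finite(d$p_adj) & d$p_adj < alpha, ]
    c(sprintf("## %s (adjusted p < %g: %d of %d)", title, alpha,
              nrow(s), nrow(d)), "",
      if (nrow(s)) sprintf("- %s [%s%s] %s: estimate %.4g, p_adj %.4g",
                           s$parameter, s$level,
                           ifelse(s$within == "", "", paste0(" ", s$within)),
                           s$comparison, s$estimate, s$p_adj),
      "")
  }
  lines <- c(lines, sig_block(cmp, "Group comparisons (Tukey)"),
             sig_block(cmp_p, "Paired comparisons (Sidak)"))
  path <- file.path(bundle_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
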