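# Shared fixtures: everything is generated in code at test time.

# canonical ground truth used across kinetic tests
gt_default <- function() {
  kinetic_ground_truth(S = 100, A1 = 120, r1 = 0.05, tau1 = 210,
                       A2 = 66, r2 = 0.015, tau2 = 420)
}

# Random but invariant-respecting ground truths (fixed seed per call
# site). The decay rate is kept well below the rise rate, as in the
# physiology (fast store release, slow extrusion); that is also the regime
# in which the curve is rise-peak-plateau shaped.
gt_random <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    S <- runif(1, 50, 200)
    A1 <- S * runif(1, 0.5, 2)
    tau1 <- runif(1, 150, 300)
    r1 <- runif(1, 0.03, 0.1)
    kinetic_ground_truth(
      S = S, A1 = A1, r1 = r1, tau1 = tau1,
      A2 = A1 * runif(1, 0.3, 0.8), r2 = r1 * runif(1, 0.1, 0.4),
      tau2 = tau1 + runif(1, 100, 400))
  }))
}

# a noiseless or log-normally noisy binned series sampled from a curve
make_series <- function(g, n_bins = 204, t_end = 1020, noise = 0,
                        seed = 1, stim_time = 120) {
  w <- t_end / n_bins
  t <- (seq_len(n_bins) - 0.5) * w
  y <- true_curve(g, t)
  if (noise > 0)
    y <- withr::with_seed(seed, y * exp(rnorm(length(y), 0, noise)))
  ser <- data.frame(time = t, median = y, n = 50L)
  attr(ser, "stim_time") <- stim_time
  ser
}

# build a double_logistic_fit object directly (bypasses the optimizer)
as_fit <- function(g, rss = 0, n_bins = 204) {
  structure(c(unclass(g), list(rss = rss, converged = TRUE,
                               n_bins = n_bins)),
            class = "double_logistic_fit")
}

# mixture with custom B-subset shares (CD25 ignored: one component per
# subset), everything else as in the default world
make_mixture <- function(shares = c(naive = 0.6, NSw = 0.2, Sw = 0.15,
                                    DN = 0.05),
                         b_fraction = 1, loaded_fraction = 0.98) {
  specs <- default_subset_specs(b_fraction = 0.5)
  out <- list()
  for (s in names(shares)) {
    sp <- specs[[paste0(s, "-")]]
    sp$proportion <- b_fraction * shares[[s]]
    out[[s]] <- sp
    out[[s]]$loaded_fraction <- loaded_fraction
  }
  if (b_fraction < 1) {
    nb <- specs[["non_b"]]
    nb$proportion <- 1 - b_fraction
    nb$loaded_fraction <- loaded_fraction
    out[["non_b"]] <- nb
  }
  out
}

# end-to-end run scaled for test budgets: two arms of 12 samples,
# 6000 events each with B cells at 50%, 15-s bins
e2e_run <- function(seed, amplitude_mult = 1.3, events = 6000,
                    n_samples = 12, parameter = "auc") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  des <- cohort_design(
    data.frame(group = c("CTRL", "EFF"), n_samples = n_samples,
               baseline_mult = 1, amplitude_mult = c(1, amplitude_mult)),
    events_per_sample = events, b_fraction = 0.5, seed = seed)
  generate_cohort(des, dir)
  cfg <- default_run_config()
  cfg$manifest <- file.path(dir, "manifest.csv")
  cfg$out_dir <- file.path(dir, "out")
  cfg$kinetics$bin_width <- 15
  cfg$kinetics$min_per_bin <- 3
  cfg$stats$parameters <- parameter
  cfg$seed <- seed
  run_pipeline(cfg, quiet = TRUE)
}

# Tukey-adjusted p of the overall group contrast for one parameter
e2e_overall_p <- function(res, parameter = "auc") {
  cg <- as.data.frame(res$comparisons_groups)
  cg$p_adj[cg$level == "groups-overall" & cg$parameter == parameter]
}
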