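test_that("binning: medians, bin filter, exclusion rule", {
  ev <- data.frame(time = c(1, 2, 3, 6, 7, 8, 12),
                   Fluo4 = c(5, 5, 5, 7, 7, 7, 9))
  ser <- bin_median_series(ev, bin_width = 5, min_per_bin = 3)
  expect_equal(ser$median, c(5, 7))       # the lone event at t=12 dropped
  expect_equal(ser$time, c(2.5, 7.5))
  ser2 <- bin_median_series(ev, bin_width = 5, min_per_bin = 1)
  expect_equal(nrow(ser2), 3)
  expect_error(bin_median_series(ev, bin_width = 5, min_per_bin = 10),
               "too few events")
  expect_error(bin_median_series(ev[0, ], 5, 1), "too few events")
})

test_that("baseline MFI is the raw pre-stimulation median", {
  ev <- data.frame(time = c(10, 30, 50, 70, 90, 500),
                   Fluo4 = c(1, 2, 3, 4, 100, 999))
  expect_equal(baseline_mfi(ev, stim_time = 120), 3)
  expect_equal(baseline_mfi(data.frame(time = 1:3, Fluo4 = 7), 120), 7)
  expect_error(baseline_mfi(data.frame(time = 500, Fluo4 = 1), 120),
               "no pre-stimulation")
  # log-normal oracle: median -> exp(mu)
  x <- withr::with_seed(31, exp(rnorm(50000, log(120), 0.4)))
  ev2 <- data.frame(time = rep(50, 50000), Fluo4 = x)
  expect_equal(baseline_mfi(ev2), 120, tolerance = 0.02)
})

test_that("noiseless series: all seven coefficients recovered < 1e-3", {
  for (g in gt_random(5, seed = 32)) {
    fit <- fit_double_logistic(make_series(g))
    rel <- abs(unlist(fit[c("S", "A1", "r1", "tau1", "A2", "r2", "tau2")]) /
                 unlist(g) - 1)
    expect_lt(max(rel), 1e-3)
    expect_true(fit$converged)
  }
})

test_that("constant series yields a flat fit", {
  ser <- data.frame(time = seq(2.5, 1017.5, 5), median = 42)
  attr(ser, "stim_time") <- 120
  fit <- fit_double_logistic(ser)
  expect_equal(fit$S, 42, tolerance = 1e-3)
  expect_lt(fit$A1, 42 * 1e-3)
  expect_lt(fit$A2, 42 * 1e-3)
  p <- derive_parameters(fit, baseline = 42)
  expect_equal(p$max_value, 1, tolerance = 1e-3)
  expect_equal(p$ending_value, 1, tolerance = 1e-3)
  expect_equal(p$auc, 1020, tolerance = 1)
})

test_that("fit preconditions: bins and time span", {
  g <- gt_default()
  short <- make_series(g)[1:5, ]
  attr(short, "stim_time") <- 120
  expect_error(fit_double_logistic(short), "8 retained bins")
  post_only <- make_series(g)
  post_only <- post_only[post_only$time > 200, ]
  attr(post_only, "stim_time") <- 120
  expect_error(fit_double_logistic(post_only), "span")
})

test_that("fit is deterministic", {
  ser <- make_series(gt_default(), noise = 0.05, seed = 33)
  f1 <- fit_double_logistic(ser)
  f2 <- fit_double_logistic(ser)
  expect_identical(f1, f2)
})

test_that("5% noise, 180 bins: fitted AUC within 2% of truth", {
  g <- gt_default()
  truth <- double_logistic_auc(0, 1020, g$S, g$A1, g$r1, g$tau1,
                               g$A2, g$r2, g$tau2) / g$S
  fit <- fit_double_logistic(make_series(g, n_bins = 180, noise = 0.05,
                                         seed = 34))
  expect_equal(area_under_curve(fit, 0, 1020), truth, tolerance = 0.02)
})

test_that("pure rise: closed-form midpoint time and slope", {
  g <- kinetic_ground_truth(S = 100, A1 = 150, r1 = 0.04, tau1 = 260,
                            A2 = 0, r2 = 0.01, tau2 = 500)
  p <- derive_parameters(as_fit(g))
  # max sits at the domain boundary: descending phase flagged undefined
  expect_false(p$descending)
  expect_true(is.na(p$slope_second_50))
  expect_equal(p$time_to_max, 1020)
  expect_equal(p$time_to_first_50, g$tau1, tolerance = 1e-4)
  expect_equal(p$slope_first_50, (g$A1 / g$S) * g$r1 / 4, tolerance = 1e-4)
})

test_that("derived parameters agree with a 0.01-s brute-force scan", {
  for (g in gt_random(5, seed = 35)) {
    p <- derive_parameters(as_fit(g))
    grid <- seq(0, 1020, by = 0.01)
    v <- true_curve(g, grid) / g$S
    i_max <- which.max(v)
    expect_lt(abs(p$time_to_max - grid[i_max]), 0.05)
    expect_equal(p$max_value, v[i_max], tolerance = 1e-6)
    L1 <- (1 + p$max_value) / 2
    t1_scan <- grid[min(which(v >= L1))]
    expect_lt(abs(p$time_to_first_50 - t1_scan), 0.05)
    L2 <- (p$max_value + p$ending_value) / 2
    post <- grid > grid[i_max]
    t2_scan <- grid[post][min(which(v[post] <= L2))]
    expect_lt(abs(p$time_to_max + p$time_max_to_second_50 - t2_scan), 0.05)
  }
})

test_that("closed-form AUC matches quadrature through the fit interface", {
  for (g in gt_random(4, seed = 36)) {
    fit <- as_fit(g)
    q <- stats::integrate(function(t) true_curve(g, t) / g$S, 0, 1020,
                          rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(area_under_curve(fit, 0, 1020), q, tolerance = 1e-6)
    expect_equal(area_under_curve(fit, 0, 1020),
                 area_under_curve(fit, 0, 500) +
                   area_under_curve(fit, 500, 1020), tolerance = 1e-12)
  }
  expect_equal(area_under_curve(as_fit(gt_default()), 300, 300), 0)
})

test_that("standardisation, sign and ordering invariants", {
  for (g in gt_random(20, seed = 37)) {
    p <- derive_parameters(as_fit(g))
    expect_identical(p$starting_value, 1)
    expect_gt(p$slope_first_50, 0)
    expect_gte(p$max_value, p$ending_value)
    expect_gte(p$ending_value, 1)
    expect_lte(p$time_to_first_50, p$time_to_max)
    if (p$descending) {
      expect_lt(p$slope_second_50, 0)
      expect_gt(p$time_max_to_second_50, 0)
    }
  }
})

test_that("derive_parameters refuses a non-converged fit", {
  bad <- as_fit(gt_default())
  bad$converged <- FALSE
  expect_error(derive_parameters(bad), "converge")
})

test_that("parameter recovery across noise levels (scaled-down property)", {
  # 20 series per level here; the acceptance suite runs the full 100
  for (noise in c(0, 0.02, 0.05)) {
    errs <- vapply(seq_len(20), function(i) {
      g <- gt_random(1, seed = 380 + i)[[1]]
      truth <- derive_parameters(as_fit(g))
      fit <- fit_double_logistic(make_series(g, n_bins = 180, noise = noise,
                                             seed = 500 + i))
      est <- derive_parameters(fit)
      max(abs(est$max_value / truth$max_value - 1),
          abs(est$ending_value / truth$ending_value - 1),
          abs(est$auc / truth$auc - 1))
    }, numeric(1))
    bound <- c(`0` = 1e-6, `0.02` = 0.02, `0.05` = 0.05)[[as.character(noise)]]
    expect_lte(median(errs), bound)
  }
})
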