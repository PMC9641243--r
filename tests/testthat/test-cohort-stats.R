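test_that("Grubbs: trivial cases and t-quantile oracle", {
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
  expect_length(grubbs_outliers(rep(5, 10)), 0)

  x <- c(1:10, 50)
  # oracle: critical value recomputed from the t quantile
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tc <- qt(1 - 0.01 / (2 * n), n - 2)
  Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tc^2 / (n - 2 + tc^2))
  expect_gt(G, Gcrit)           # 50 must be flaggable at alpha 0.01
  expect_equal(grubbs_outliers(x, alpha = 0.01), 11L)
  expect_length(grubbs_outliers(1:10, alpha = 0.01), 0)
})

test_that("Grubbs type-I rate is close to alpha", {
  hits <- withr::with_seed(41, vapply(seq_len(1000), function(i)
    length(grubbs_outliers(rnorm(12), alpha = 0.05)) > 0, logical(1)))
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("removing a flagged point shrinks the Grubbs statistic", {
  gstat <- function(x) max(abs(x - mean(x))) / sd(x)
  withr::with_seed(42, for (i in 1:20) {
    x <- c(rnorm(12), rnorm(1, 8))
    out <- grubbs_outliers(x, alpha = 0.01)
    if (length(out))
      expect_lte(gstat(x[-out[1]]), gstat(x) + 1e-12)
  })
})

test_that("Sidak adjustment properties", {
  p <- c(0.001, 0.04, 0.5)
  adj <- sidak_adjust(p, m = 4)
  expect_equal(adj, pmin(1, 1 - (1 - p)^4))
  expect_true(all(adj >= p))
  expect_equal(sidak_adjust(0.2, m = 1), 0.2)
})

test_that("balanced single-subset design reduces to one-way Tukey", {
  d <- withr::with_seed(43, data.frame(
    sample_id = sprintf("s%d", 1:36),
    group = rep(c("A", "B", "C"), each = 12), subject_id = NA,
    subset = "naive", parameter = "auc",
    value = rnorm(36, rep(c(0, 0.6, 1.8), each = 12))))
  ours <- group_subset_comparisons(d, "auc")
  ours <- ours[ours$level == "groups-within-subset", ]
  ref <- TukeyHSD(aov(value ~ group, data = d))$group
  key <- c("A-B" = "B-A", "A-C" = "C-A", "B-C" = "C-B")
  for (k in names(key)) {
    row <- ours[ours$comparison == k, ]
    expect_equal(row$estimate, -ref[key[[k]], "diff"], tolerance = 1e-12)
    expect_equal(row$p_adj, ref[key[[k]], "p adj"], tolerance = 1e-9)
  }
  # overall level equals the within-subset level when there is one subset
  ov <- group_subset_comparisons(d, "auc")
  expect_equal(ov$p_adj[ov$level == "groups-overall"],
               ours$p_adj, tolerance = 1e-12)
})

test_that("self-comparison estimates exactly zero; symmetric relabeling", {
  base <- withr::with_seed(44, data.frame(
    sample_id = sprintf("s%d", 1:12), group = "A", subject_id = NA,
    subset = rep(c("naive", "Sw"), 6), parameter = "auc",
    value = rnorm(12)))
  twin <- base; twin$group <- "B"; twin$sample_id <- sprintf("t%d", 1:12)
  cmp <- group_subset_comparisons(rbind(base, twin), "auc")
  expect_true(all(cmp$estimate[cmp$level != "subsets-within-group"] == 0))

  # swapping group labels flips the estimates, keeps the p-values
  d <- rbind(base, twin)
  d$value <- d$value + ifelse(d$group == "B", 1, 0)
  fwd <- group_subset_comparisons(d, "auc")
  d2 <- d; d2$group <- ifelse(d$group == "A", "B", "A")
  rev <- group_subset_comparisons(d2, "auc")
  i <- fwd$level == "groups-overall"
  expect_equal(fwd$estimate[i], -rev$estimate[i])
  expect_equal(fwd$p_adj[i], rev$p_adj[i], tolerance = 1e-12)
})

test_that("cells with < 2 observations are flagged not-estimable", {
  d <- data.frame(sample_id = sprintf("s%d", 1:7),
                  group = c("A", "A", "A", "B", "B", "B", "B"),
                  subject_id = NA,
                  subset = c("naive", "naive", "Sw", "naive", "naive",
                             "Sw", "Sw"),
                  parameter = "auc", value = c(1, 2, 3, 2, 3, 4, 5))
  cmp <- group_subset_comparisons(d, "auc")
  row <- cmp[cmp$level == "groups-within-subset" & cmp$within == "Sw", ]
  expect_false(row$estimable)
  expect_true(is.na(row$p_adj))
  expect_false(is.na(row$estimate))  # still reported, just not tested
})

test_that("two-way null design: family-wise error controlled", {
  fw <- withr::with_seed(45, vapply(seq_len(400), function(i) {
    d <- data.frame(sample_id = sprintf("s%d", 1:48),
                    group = rep(c("A", "B", "C", "D"), each = 12),
                    subject_id = NA,
                    subset = rep(rep(c("naive", "NSw", "Sw", "DN"), each = 3), 4),
                    parameter = "auc", value = rnorm(48))
    cmp <- group_subset_comparisons(d, "auc")
    any(cmp$p_adj[cmp$level == "groups-overall"] < 0.05, na.rm = TRUE)
  }, logical(1)))
  mc <- sqrt(0.05 * 0.95 / 400)
  expect_lte(mean(fw), 0.05 + 3 * mc)
})

test_that("+3 SD shifted group is detected essentially always", {
  hit <- withr::with_seed(46, vapply(seq_len(200), function(i) {
    d <- data.frame(sample_id = sprintf("s%d", 1:48),
                    group = rep(c("A", "B", "C", "D"), each = 12),
                    subject_id = NA, subset = "naive", parameter = "auc",
                    value = rnorm(48) + rep(c(3, 0, 0, 0), each = 12))
    cmp <- group_subset_comparisons(d, "auc")
    i <- cmp$level == "groups-overall" & grepl("A", cmp$comparison)
    all(cmp$p_adj[i] < 0.05)
  }, logical(1)))
  expect_gte(mean(hit), 0.99)
})

test_that("paired mixed model: degenerate and invariance cases", {
  base <- withr::with_seed(47, rnorm(10, 100, 10))
  d <- data.frame(sample_id = sprintf("s%d", 1:20),
                  group = rep(c("H1", "H2"), each = 10),
                  subject_id = rep(sprintf("p%d", 1:10), 2),
                  subset = "naive", parameter = "auc",
                  value = c(base, base))
  r <- paired_mixed_comparisons(d, "H1", "H2", "auc")
  within <- r[r$level == "groups-within-subset", ]
  expect_equal(within$estimate, 0)
  expect_equal(within$p_adj, 1)

  d2 <- d
  d2$value <- c(base, base + withr::with_seed(48, rnorm(10, 5, 3)))
  r2 <- paired_mixed_comparisons(d2, "H1", "H2", "auc")
  d3 <- d2; d3$value <- d3$value + 1000  # location shift
  r3 <- paired_mixed_comparisons(d3, "H1", "H2", "auc")
  expect_equal(r2$estimate, r3$estimate, tolerance = 1e-8)
  expect_error(paired_mixed_comparisons(d2[1:2, ], "H1", "H2", "auc"),
               "3 subjects")
})

test_that("paired detection rate tracks the paired-t oracle", {
  # the study's shape: 15 subjects, one missing pre, three missing post
  sim <- withr::with_seed(49, lapply(seq_len(200), function(i) {
    subj <- sprintf("p%02d", 1:15)
    b <- rnorm(15, 100, 15)                      # subject intercepts
    pre <- b + rnorm(15, 0, 5)
    post <- b + 5 + rnorm(15, 0, 5)              # shift = 1 within-subject SD
    d <- rbind(
      data.frame(sample_id = paste0(subj, "_1"), group = "H1",
                 subject_id = subj, subset = "naive", parameter = "auc",
                 value = pre)[-15, ],
      data.frame(sample_id = paste0(subj, "_2"), group = "H2",
                 subject_id = subj, subset = "naive", parameter = "auc",
                 value = post)[-(12:14), ])
    lme_p <- paired_mixed_comparisons(d, "H1", "H2", "auc")
    lme_hit <- lme_p$p_adj[lme_p$level == "groups-within-subset"] < 0.05
    t_hit <- t.test(post[1:11], pre[1:11], paired = TRUE)$p.value < 0.05
    c(lme_hit, t_hit)
  }))
  rates <- rowMeans(do.call(cbind, sim))
  expect_lt(abs(rates[1] - rates[2]), 0.10)
})

test_that("required sample size: noncentral-t oracle and monotonicity", {
  for (d in c(0.5, 0.8, 1.2, 2)) {
    oracle <- ceiling(power.t.test(delta = d, sd = 1, power = 0.8,
                                   sig.level = 0.05)$n)
    expect_equal(required_sample_size(d, 1), oracle)
  }
  expect_equal(required_sample_size(1.2, 1), 12)  # the study's pilot answer
  expect_equal(required_sample_size(10, 1), 2)    # saturation floor
  expect_gt(required_sample_size(0.5, 1), required_sample_size(1.0, 1))
  expect_error(required_sample_size(0, 1), "zero pilot effect")
  expect_error(required_sample_size(1, 0), "pilot_sd")
})

test_that("percentage formatting follows the mixed integer/.5 style", {
  expect_equal(percentage(2, 7), "29%")
  expect_equal(percentage(5, 7), "71%")
  expect_equal(percentage(3, 8), "37.5%")
  expect_equal(percentage(2, 8), "25%")
  expect_equal(percentage(3, 3), "100%")
  expect_equal(percentage(0, 7), "0%")
  expect_equal(percentage(1, 16), "6%")    # 6.25 is not an exact .5 case
  expect_equal(percentage(1, 8), "12.5%")
  expect_error(percentage(1, 0), "denominator")
  expect_error(percentage(5, 3), "between")
})
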