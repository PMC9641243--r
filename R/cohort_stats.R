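#' Iterative two-sided Grubbs outlier screen
#'
#' Repeatedly tests the most extreme point with the two-sided Grubbs
#' statistic \eqn{G = \max_i |x_i - \bar x| / s} against its t-based
#' critical value
#' \eqn{\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n-2+t^2)}},
#' removing it while significant. Only extreme outliers are flagged
#' (default alpha 0.01) and removals are capped at `floor(n/5)` so small
#' samples cannot be hollowed out.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha significance level of each Grubbs test (default 0.01).
#' @return integer indices (into `values`) of flagged outliers, possibly
#'   empty, in removal order.
#' @export
grubbs_outliers <- function(values, alpha = 0.01) {
  n0 <- length(values)
  if (n0 < 3) stop("Grubbs test needs at least 3 values")
  idx <- seq_len(n0)
  keep <- !is.na(values)
  idx <- idx[keep]; x <- values[keep]
  out <- integer(0)
  max_rm <- floor(n0 / 5)
  while (length(out) < max_rm && length(x) >= 3) {
    n <- length(x)
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
    Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G <= Gcrit) break
    out <- c(out, idx[i])
    x <- x[-i]; idx <- idx[-i]
  }
  out
}

#' Sidak multiple-comparison adjustment
#'
#' @param p vector of unadjusted p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return adjusted p-values `1 - (1 - p)^m`, never below the input.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmax(p, pmin(1, 1 - (1 - p)^m))
}

# Cell summaries for a group x subset two-way layout.
.cell_stats <- function(d) {
  agg <- stats::aggregate(value ~ group + subset, data = d,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              ss = sum((v - mean(v))^2)))
  cells <- data.frame(group = agg$group, subset = agg$subset,
                      n = agg$value[, "n"], mean = agg$value[, "mean"],
                      ss = agg$value[, "ss"])
  N <- sum(cells$n)
  C <- nrow(cells)
  df <- N - C
  mse <- if (df > 0) sum(cells$ss) / df else NA_real_
  list(cells = cells, mse = mse, df = df)
}

.tukey_p <- function(est, se, nmeans, df) {
  if (!is.finite(se) || se <= 0 || df <= 0) return(NA_real_)
  stats::ptukey(sqrt(2) * abs(est) / se, nmeans, df, lower.tail = FALSE)
}

#' Two-way ANOVA with Tukey contrasts at the three comparison levels
#'
#' Fits the fixed-effects group x subset cell-means model (pooled
#' within-cell variance; unbalanced designs handled) and reports
#' Tukey-adjusted pairwise contrasts at three levels: (1) between patient
#' groups ignoring the subset structure (unweighted marginal means over
#' subsets), (2) between groups within each subset, and (3) between
#' subsets within each group. A contrast touching a cell with fewer than
#' two observations is reported but flagged not-estimable (`p_adj = NA`).
#'
#' @param table long-format cohort table with columns `sample_id`,
#'   `group`, `subset`, `parameter`, `value` (a `subject_id` column is
#'   allowed and ignored here).
#' @param parameter which parameter to analyse.
#' @return data.frame of comparisons: `level`, `within`, `comparison`,
#'   `estimate`, `se`, `p_adj`, `method`, `estimable`.
#' @export
group_subset_comparisons <- function(table, parameter) {
  d <- as.data.frame(table)
  d <- d[d$parameter == parameter & is.finite(d$value), ]
  if (nrow(d) == 0) stop("no data for parameter ", parameter)
  d$group <- as.character(d$group); d$subset <- as.character(d$subset)
  groups <- sort(unique(d$group)); subsets <- sort(unique(d$subset))
  if (length(groups) < 2) stop("need at least two groups")
  cs <- .cell_stats(d)
  cells <- cs$cells; mse <- cs$mse; df <- cs$df
  cell <- function(g, s) cells[cells$group == g & cells$subset == s, ]
  res <- list()
  add <- function(level, within, comparison, estimate, se, nmeans, estimable) {
    p <- if (estimable) .tukey_p(estimate, se, nmeans, df) else NA_real_
    res[[length(res) + 1L]] <<- data.frame(
      level = level, within = within, comparison = comparison,
      estimate = estimate, se = se, p_adj = p, method = "Tukey",
      estimable = estimable)
  }
  kg <- length(groups); ks <- length(subsets)
  # (1) groups overall: unweighted marginal means over subsets
  for (i in seq_len(kg - 1)) for (j in (i + 1):kg) {
    g1 <- groups[i]; g2 <- groups[j]
    c1 <- lapply(subsets, function(s) cell(g1, s))
    c2 <- lapply(subsets, function(s) cell(g2, s))
    n1 <- vapply(c1, function(x) if (nrow(x)) x$n else 0L, numeric(1))
    n2 <- vapply(c2, function(x) if (nrow(x)) x$n else 0L, numeric(1))
    ok <- all(n1 >= 2) && all(n2 >= 2) && is.finite(mse)
    est <- se <- NA_real_
    if (all(n1 >= 1) && all(n2 >= 1)) {
      m1 <- mean(vapply(c1, function(x) x$mean, numeric(1)))
      m2 <- mean(vapply(c2, function(x) x$mean, numeric(1)))
      est <- m1 - m2
      if (is.finite(mse))
        se <- sqrt(mse * (sum(1 / n1) + sum(1 / n2)) / ks^2)
    }
    add("groups-overall", "", paste0(g1, "-", g2), est, se, kg, ok)
  }
  # (2) groups within each subset
  for (s in subsets) for (i in seq_len(kg - 1)) for (j in (i + 1):kg) {
    c1 <- cell(groups[i], s); c2 <- cell(groups[j], s)
    est <- se <- NA_real_
    ok <- FALSE
    if (nrow(c1) && nrow(c2)) {
      est <- c1$mean - c2$mean
      ok <- c1$n >= 2 && c2$n >= 2 && is.finite(mse)
      if (is.finite(mse)) se <- sqrt(mse * (1 / c1$n + 1 / c2$n))
    }
    add("groups-within-subset", s, paste0(groups[i], "-", groups[j]),
        est, se, kg, ok)
  }
  # (3) subsets within each group
  if (ks >= 2) {
    for (g in groups) for (i in seq_len(ks - 1)) for (j in (i + 1):ks) {
      c1 <- cell(g, subsets[i]); c2 <- cell(g, subsets[j])
      est <- se <- NA_real_
      ok <- FALSE
      if (nrow(c1) && nrow(c2)) {
        est <- c1$mean - c2$mean
        ok <- c1$n >= 2 && c2$n >= 2 && is.finite(mse)
        if (is.finite(mse)) se <- sqrt(mse * (1 / c1$n + 1 / c2$n))
      }
      add("subsets-within-group", g, paste0(subsets[i], "-", subsets[j]),
          est, se, ks, ok)
    }
  }
  do.call(rbind, res)
}

# one paired mixed-model comparison; returns c(estimate, p)
.paired_one <- function(d, pre_group, post_group) {
  d$visit <- factor(ifelse(d$group == post_group, "post", "pre"),
                    levels = c("pre", "post"))
  d$subject_id <- factor(d$subject_id)
  cp <- merge(d[d$visit == "pre", c("subject_id", "value")],
              d[d$visit == "post", c("subject_id", "value")],
              by = "subject_id")
  diffs <- cp$value.y - cp$value.x
  if (nrow(cp) >= 2 && stats::sd(diffs) == 0)
    return(c(estimate = mean(diffs), p = if (all(diffs == 0)) 1 else 0))
  fit <- tryCatch(
    nlme::lme(value ~ visit, random = ~ 1 | subject_id, data = d,
              na.action = stats::na.omit, method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    return(c(estimate = unname(tt["visitpost", "Value"]),
             p = unname(tt["visitpost", "p-value"])))
  }
  if (nrow(cp) >= 2) {  # fallback: paired t on complete pairs
    tst <- stats::t.test(diffs)
    return(c(estimate = mean(diffs), p = tst$p.value))
  }
  c(estimate = NA_real_, p = NA_real_)
}

#' Paired mixed-effects comparison with Sidak adjustment
#'
#' Compares a pre-treatment and a post-treatment group that sample the
#' same subjects (randomly missing visits allowed) with a linear mixed
#' model per subset: random subject intercept, fixed visit effect (REML
#' via `nlme`). Subjects with only one visit still inform the variance
#' components. P-values are Sidak-adjusted across the subsets analysed.
#'
#' @param table long-format cohort table (see
#'   [group_subset_comparisons()]); needs `subject_id`.
#' @param pre_group,post_group group labels of the paired visits.
#' @param parameter which parameter to analyse.
#' @return data.frame with one row per subset plus an `overall` row
#'   (subsets pooled): `level`, `within`, `comparison`, `estimate`, `p`,
#'   `p_adj`, `method`.
#' @export
paired_mixed_comparisons <- function(table, pre_group, post_group, parameter) {
  d <- as.data.frame(table)
  d <- d[d$parameter == parameter & d$group %in% c(pre_group, post_group) &
           is.finite(d$value), ]
  if (!"subject_id" %in% names(d)) stop("table needs a subject_id column")
  if (length(unique(d$subject_id)) < 3)
    stop("need at least 3 subjects for the paired analysis")
  subsets <- sort(unique(as.character(d$subset)))
  rows <- lapply(subsets, function(s) {
    r <- .paired_one(d[d$subset == s, ], pre_group, post_group)
    data.frame(level = "groups-within-subset", within = s,
               comparison = paste0(post_group, "-", pre_group),
               estimate = r[["estimate"]], p = r[["p"]],
               method = "Sidak")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- sidak_adjust(out$p, m = nrow(out))
  overall <- .paired_one(d, pre_group, post_group)
  out <- rbind(out, data.frame(
    level = "groups-overall", within = "",
    comparison = paste0(post_group, "-", pre_group),
    estimate = overall[["estimate"]], p = overall[["p"]],
    method = "Sidak", p_adj = overall[["p"]]))
  out[, c("level", "within", "comparison", "estimate", "p", "p_adj",
          "method")]
}

#' Sample size for a two-sample comparison of a pilot effect
#'
#' Smallest per-group n giving a two-sided two-sample t-test the requested
#' power against the standardised pilot effect
#' `d = pilot_mean_diff / pilot_sd`, by iterating the exact noncentral-t
#' power (noncentrality `d * sqrt(n/2)`, `2n - 2` df).
#'
#' @param pilot_mean_diff pilot estimate of the group mean difference
#'   (nonzero).
#' @param pilot_sd pilot pooled standard deviation (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return integer n per group (floor 2).
#' @export
required_sample_size <- function(pilot_mean_diff, pilot_sd,
                                 alpha = 0.05, power = 0.80) {
  if (pilot_sd <= 0) stop("pilot_sd must be > 0")
  if (pilot_mean_diff == 0) stop("zero pilot effect: requested power unreachable")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  d <- abs(pilot_mean_diff) / pilot_sd
  for (n in 2:1e6) {
    df <- 2 * n - 2
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n / 2)
    pow <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
    if (pow >= power) return(n)
  }
  stop("no attainable n below 1e6")
}

#' Report-style percentage formatting
#'
#' `100 * numerator / denominator`, rounded to the nearest integer except
#' when the value has an exact one-decimal representation ending in .5,
#' which keeps the single decimal (the mixed "29%" / "37.5%" style of
#' clinical tables).
#'
#' @param numerator,denominator counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @return formatted string, e.g. `"29%"` or `"37.5%"`.
#' @export
#' @examples
#' percentage(2, 7)   # "29%"
#' percentage(3, 8)   # "37.5%"
percentage <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must be between 0 and denominator")
  v <- 100 * numerator / denominator
  v10 <- v * 10
  if (abs(v10 - round(v10)) < 1e-9 && round(v10) %% 10 == 5)
    sprintf("%.1f%%", v)
  else
    sprintf("%d%%", as.integer(round(v)))
}
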