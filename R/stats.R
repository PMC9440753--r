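#' Spearman rank correlation
#'
#' Rank correlation with midrank ties, used for pairwise comparison of
#' tracing results from two methods on the same images. The p-value uses
#' the t approximation `t = rho sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A `stats_result` with `statistic` (rho) and `p_value`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("rank correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  new_stats_result("spearman", unname(ct$estimate), ct$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank tie handling; `U` is reported for
#' the first group (the smaller of the two mass orientations can be read
#' off as `min(U, n1 n2 - U)`). Bonferroni adjustment over `m_comparisons`
#' caps the adjusted p at 1. A paired alternative (Wilcoxon signed rank) is
#' available for trace pairs measured on the same images.
#'
#' @param a,b numeric vectors (non-empty).
#' @param m_comparisons Bonferroni divisor (default 1 = no adjustment).
#' @param paired use the paired signed-rank test instead.
#' @return A `stats_result` with `statistic` (U), `p_value` and
#'   `p_adjusted`.
#' @export
mann_whitney <- function(a, b, m_comparisons = 1, paired = FALSE) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE,
                                     correct = TRUE))
  res <- new_stats_result(if (paired) "wilcoxon_signed_rank" else "mann_whitney",
                          unname(wt$statistic), wt$p.value)
  res$p_adjusted <- min(1, m_comparisons * wt$p.value)
  res$adjust_method <- "bonferroni"
  res$group_summaries <- list(a = group_summary(a), b = group_summary(b))
  res
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn's pairwise z statistics on the pooled midranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`. Pairwise p-values are two-sided
#' normal, Bonferroni-adjusted over all pairs by default.
#'
#' @param groups list of at least 3 non-empty numeric vectors (named names
#'   are kept).
#' @param adjust multiplicity adjustment for the Dunn comparisons (any
#'   method of [stats::p.adjust()]; default `"bonferroni"`).
#' @return A `stats_result` with `statistic` (H), `p_value`, and a
#'   `pairwise` data frame (z, raw and adjusted p per pair).
#' @export
kruskal_dunn <- function(groups, adjust = "bonferroni") {
  if (length(groups) < 3) stop("need at least 3 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("all groups must be non-empty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  res <- new_stats_result("kruskal_wallis", unname(kw$statistic), kw$p.value)

  pooled <- unlist(groups, use.names = FALSE)
  gid <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(pooled)
  rk <- rank(pooled)
  rbar <- tapply(rk, gid, mean)
  n <- tabulate(gid)
  ties <- table(pooled)
  Tt <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - Tt) * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
  }
  praw <- 2 * pnorm(-abs(z))
  padj <- p.adjust(praw, method = adjust)
  res$pairwise <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    z = z, p_value = praw, p_adjusted = padj,
    stars = signif_stars(padj),
    stringsAsFactors = FALSE)
  res$adjust_method <- adjust
  res$group_summaries <- lapply(groups, group_summary)
  res
}

#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance two-sample t-test; the statistic's sign follows
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors with at least 2 observations each.
#' @return A `stats_result` with `statistic` (t), `p_value` and degrees of
#'   freedom `df`.
#' @export
t_test_unpaired <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 observations")
  if (sd(c(a - mean(a), b - mean(b))) == 0)
    stop("zero pooled variance: t statistic undefined")
  tt <- t.test(a, b, var.equal = TRUE)
  res <- new_stats_result("t_test_unpaired", unname(tt$statistic), tt$p.value)
  res$df <- unname(tt$parameter)
  res$group_summaries <- list(a = group_summary(a), b = group_summary(b))
  res
}

#' Summarize ordinal index scores
#'
#' Mean and s.d. of 1-3 ordinal scores (such as gel stability or neurite
#' spreading indices) plus per-category percentages, with counts reported
#' as `count/total` and percentages rounded half away from zero to integers
#' (3 of 18 partially degraded gels reports as 17%).
#'
#' @param scores integer vector of scores in 1..3.
#' @return List with `n`, `mean`, `sd` and a `categories` data frame
#'   (`score`, `count`, `percent`).
#' @export
summarize_index <- function(scores) {
  if (length(scores) == 0) stop("empty score group")
  if (any(!scores %in% 1:3)) stop("scores must be integers in 1..3")
  n <- length(scores)
  cat_counts <- vapply(1:3, function(s) sum(scores == s), integer(1))
  list(n = n, mean = mean(scores), sd = if (n > 1) sd(scores) else 0,
       categories = data.frame(
         score = 1:3, count = cat_counts,
         percent = round_half_away(100 * cat_counts / n)))
}

#' Tukey box-plot summary
#'
#' Median, quartiles (linear-interpolation quantiles), whiskers at the most
#' extreme data within 1.5 IQR of the quartiles, and the outliers beyond
#' them.
#'
#' @param values numeric vector (n >= 1).
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
tukey_box_summary <- function(values) {
  if (length(values) == 0) stop("need at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

group_summary <- function(v) {
  tb <- tukey_box_summary(v)
  c(list(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0),
    tb)
}

signif_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

new_stats_result <- function(test, statistic, p_value) {
  structure(list(test = test, statistic = statistic, p_value = p_value),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n", x$test, x$statistic,
              x$p_value, signif_stars(x$p_value)))
  if (!is.null(x$p_adjusted))
    cat(sprintf("adjusted p (%s) = %.4g\n", x$adjust_method, x$p_adjusted))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Dunn):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Compare experimental conditions on network metrics
#'
#' Assembles the final group-comparison report: for every metric column,
#' per-group Tukey summaries, the design-matched test (unpaired two-tailed
#' t-test for 2 conditions; Kruskal-Wallis with Dunn's post hoc for 3 or
#' more), and the percent reduction of each treated group mean relative to
#' control.
#'
#' @param metrics data frame with a `condition` column and numeric metric
#'   columns (one row per sample).
#' @param control name of the control condition (default: first level
#'   encountered).
#' @param metrics_cols metric columns to analyse (default: all numeric).
#' @return A list of class `condition_report`: per-metric entries with
#'   `summaries`, `test` and `percent_reduction`.
#' @export
compare_conditions <- function(metrics, control = NULL, metrics_cols = NULL) {
  if (!"condition" %in% names(metrics)) stop("missing 'condition' column")
  conds <- unique(as.character(metrics$condition))
  if (length(conds) < 2) stop("need at least 2 conditions")
  if (is.null(control)) control <- conds[1]
  if (!control %in% conds) stop("control condition not present")
  if (is.null(metrics_cols)) {
    metrics_cols <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
    metrics_cols <- setdiff(metrics_cols, "sholl_radius_um")
  }
  missing_cols <- setdiff(metrics_cols, names(metrics))
  if (length(missing_cols))
    stop("missing metric column(s): ", paste(missing_cols, collapse = ", "))

  report <- list()
  for (m in metrics_cols) {
    groups <- lapply(conds, function(cc)
      metrics[[m]][metrics$condition == cc & !is.na(metrics[[m]])])
    names(groups) <- conds
    groups <- groups[vapply(groups, length, 1L) > 0]
    if (length(groups) < 2) next
    test <- if (length(groups) == 2) {
      tryCatch(t_test_unpaired(groups[[1]], groups[[2]]),
               error = function(e) NULL)
    } else {
      tryCatch(kruskal_dunn(groups), error = function(e) NULL)
    }
    ctrl_mean <- mean(groups[[control]])
    pr <- vapply(setdiff(names(groups), control), function(cc) {
      if (ctrl_mean > 0) percent_reduction(ctrl_mean, mean(groups[[cc]]))
      else NA_real_
    }, numeric(1))
    report[[m]] <- list(
      summaries = lapply(groups, group_summary),
      test = test,
      percent_reduction = pr)
  }
  structure(list(metrics = report, control = control,
                 conditions = conds),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("condition report: %s vs %s (control = %s)\n",
              paste(x$conditions, collapse = ", "), "", x$control))
  for (m in names(x$metrics)) {
    e <- x$metrics[[m]]
    means <- vapply(e$summaries, function(s) s$mean, numeric(1))
    cat(sprintf("- %s: means %s", m,
                paste(sprintf("%s=%.3g", names(means), means), collapse = ", ")))
    if (!is.null(e$test))
      cat(sprintf("; %s p = %.3g %s", e$test$test, e$test$p_value,
                  signif_stars(e$test$p_value)))
    if (length(e$percent_reduction))
      cat(sprintf("; reduction vs control: %s",
                  paste(sprintf("%s %d%%", names(e$percent_reduction),
                                as.integer(e$percent_reduction)),
                        collapse = ", ")))
    cat("\n")
  }
  invisible(x)
}
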