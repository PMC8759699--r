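#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile()` type 7, the common default).
#'
#' @param x Numeric sample (NA dropped), n >= 1.
#' @return Named vector `(median, q25, q75)`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("validation error: empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

new_comparison <- function(endpoint, group_summaries, statistic,
                           statistic_name, df, p_value, note = NULL) {
  structure(list(endpoint = endpoint, group_summaries = group_summaries,
                 statistic = statistic, statistic_name = statistic_name,
                 df = df, p_value = p_value, note = note),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g%s, p = %.4g\n", x$endpoint,
              x$statistic_name, x$statistic,
              if (!is.na(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value))
  for (g in names(x$group_summaries)) {
    s <- x$group_summaries[[g]]
    if (!is.null(s["median"]) && !is.na(s["median"])) {
      cat(sprintf("  %s: %.4g [%.4g-%.4g]\n", g, s["median"], s["q25"],
                  s["q75"]))
    } else {
      cat(sprintf("  %s: mean %.4g [%.4g-%.4g]\n", g, s["mean"],
                  s["ci_lo"], s["ci_hi"]))
    }
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison. The exact null distribution is used
#' when `n_x + n_y <= 25` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. The reported U
#' counts pairs in which x exceeds y (0 <= U <= n_x n_y).
#'
#' @param x,y Numeric samples (NA dropped).
#' @param endpoint Label carried into the result.
#' @param labels Group labels, in (x, y) order.
#' @return A `cohort_comparison` with median/IQR summaries.
#' @export
mann_whitney_u <- function(x, y, endpoint = "endpoint",
                           labels = c("x", "y")) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    stop("validation error: both samples must be non-empty", call. = FALSE)
  }
  note <- NULL
  if (length(unique(c(x, y))) == 1) {
    warning("all values identical across both groups", call. = FALSE)
    u <- length(x) * length(y) / 2
    p <- 1
    note <- "degenerate: all values identical"
  } else {
    has_ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 25) && !has_ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    u <- unname(wt$statistic)
    p <- wt$p.value
  }
  gs <- list(median_iqr(x), median_iqr(y))
  names(gs) <- labels
  new_comparison(endpoint, gs, u, "U", NA_real_, p, note)
}

#' Spearman rank correlation
#'
#' Rho is computed on average ranks. The two-sided p-value is exact (full
#' enumeration of all n! pairings) for n < 10, and uses the t
#' approximation `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees of
#' freedom otherwise.
#'
#' @param x,y Paired samples, n >= 3 (pairs with NA dropped).
#' @param endpoint Label carried into the result.
#' @return A `cohort_comparison` with `statistic_name = "rho"`.
#' @export
spearman_cor <- function(x, y, endpoint = "endpoint") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("validation error: need n >= 3 pairs", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("undefined correlation: zero rank variance", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    p <- spearman_perm_pvalue_cpp(rx, ry)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  gs <- list(x = median_iqr(x), y = median_iqr(y))
  new_comparison(endpoint, gs, rho, "rho", n - 2, min(p, 1))
}

#' Pooled-variance two-sample t-test
#'
#' Student's independent t-test (equal variances), df = n_x + n_y - 2,
#' with per-group means and t-based 95% confidence intervals — the
#' convention for normally distributed AUC endpoints.
#'
#' @param x,y Numeric samples, n >= 2 each (NA dropped).
#' @param endpoint Label carried into the result.
#' @param labels Group labels, in (x, y) order.
#' @param conf_level Confidence level for group means.
#' @return A `cohort_comparison` with mean/CI summaries.
#' @export
students_t <- function(x, y, endpoint = "endpoint", labels = c("x", "y"),
                       conf_level = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("validation error: need n >= 2 per group", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("degenerate samples: zero pooled variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  mean_ci <- function(v) {
    m <- mean(v)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = length(v) - 1) *
      stats::sd(v) / sqrt(length(v))
    c(mean = m, ci_lo = m - half, ci_hi = m + half,
      median = NA_real_, q25 = NA_real_, q75 = NA_real_)
  }
  gs <- list(mean_ci(x), mean_ci(y))
  names(gs) <- labels
  new_comparison(endpoint, gs, unname(tt$statistic), "t",
                 unname(tt$parameter), tt$p.value)
}

#' Friedman test with Dunn's post hoc comparisons versus baseline
#'
#' Within-subject comparison of repeated measurements against the
#' baseline column. Subjects with any missing value are dropped listwise
#' (count reported). The Friedman chi-square is computed on within-subject
#' ranks; each non-baseline time is then compared to baseline with Dunn's
#' z statistic
#' \deqn{z_j = (\bar R_j - \bar R_b) / \sqrt{k(k+1)/(6n)}}
#' and the two-sided p-values are Bonferroni-adjusted over the k - 1
#' comparisons against baseline.
#'
#' @param block_matrix Numeric matrix, subjects in rows, time points in
#'   columns (column names used as time labels).
#' @param baseline_col Index of the baseline column.
#' @return A list of class `friedman_dunns` with elements `friedman` (a
#'   `cohort_comparison` with Q and its asymptotic p), `dunn` (data frame
#'   with columns `time`, `mean_rank_diff`, `z`, `p_adj`, `direction`),
#'   `n_complete` and `n_dropped`.
#' @export
friedman_with_dunns <- function(block_matrix, baseline_col = 1) {
  m <- as.matrix(block_matrix)
  if (ncol(m) < 3) {
    stop("validation error: need >= 3 time points", call. = FALSE)
  }
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) {
    stop("validation error: need >= 2 complete subjects", call. = FALSE)
  }
  ft <- stats::friedman.test(m)
  if (is.nan(ft$statistic)) {
    # every block fully tied: average ranks everywhere, no evidence of a
    # time effect (the tie correction degenerates to 0/0)
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  idx <- setdiff(seq_len(k), baseline_col)
  z <- (rbar[idx] - rbar[baseline_col]) / se
  p_adj <- pmin(1, (k - 1) * 2 * stats::pnorm(-abs(z)))
  labels <- colnames(m)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  dunn <- data.frame(
    time = labels[idx],
    mean_rank_diff = unname(rbar[idx] - rbar[baseline_col]),
    z = unname(z), p_adj = unname(p_adj),
    direction = ifelse(z > 0, "above baseline", "below baseline"),
    stringsAsFactors = FALSE)
  fr <- new_comparison(
    "within-subject time effect", list(), unname(ft$statistic), "Q",
    unname(ft$parameter), ft$p.value,
    note = if (n_dropped > 0)
      sprintf("%d incomplete subject(s) dropped", n_dropped) else NULL)
  structure(list(friedman = fr, dunn = dunn, n_complete = n,
                 n_dropped = n_dropped),
            class = "friedman_dunns")
}

#' @export
print.friedman_dunns <- function(x, ...) {
  cat(sprintf("Friedman Q = %.4g (df = %g), p = %.4g; %d complete subjects",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value,
              x$n_complete))
  if (x$n_dropped > 0) cat(sprintf(" (%d dropped)", x$n_dropped))
  cat("\nDunn's comparisons vs baseline (Bonferroni-adjusted):\n")
  print(x$dunn, row.names = FALSE, digits = 4)
  invisible(x)
}
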