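# Reproducibility statistics: pooled two-sample Student t-tests (raw samples
# or summary statistics), day-centered two-tailed variance F-tests,
# Benjamini-Hochberg correction and pooled mean/SD summaries.

#' Group summary (n, mean, SD)
#' @param n number of observations (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param label optional day/experiment identifier.
#' @export
group_summary <- function(n, mean, sd, label = NA_character_) {
  if (n < 2L) .helixreg_error("helixreg_stats_error", "group needs n >= 2")
  if (sd < 0) .helixreg_error("helixreg_stats_error", "sd must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd, label = label),
            class = "group_summary")
}

.as_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  x <- as.numeric(x)
  group_summary(length(x), mean(x), stats::sd(x))
}

#' Two-tailed unpaired Student t-test
#'
#' Pooled-variance two-sample t with `df = n1 + n2 - 2`, accepting either
#' raw samples or [group_summary()] objects, plus the 95% CI of the mean
#' difference.
#'
#' @param a,b numeric samples or `group_summary` objects.
#' @return list of class `helixreg_test` with `statistic`, `df`, `p_value`,
#'   `mean_difference` and `ci95`.
#' @export
unpaired_t_test <- function(a, b) {
  a <- .as_summary(a); b <- .as_summary(b)
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  diff <- a$mean - b$mean
  if (se == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    ci <- c(diff, diff)
  } else {
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
    ci <- diff + c(-1, 1) * stats::qt(0.975, df) * se
  }
  structure(list(statistic = t, df = df, p_value = p,
                 mean_difference = diff, ci95 = ci,
                 infinite_statistic = !is.finite(t)),
            class = "helixreg_test")
}

.center_by_day <- function(groups) {
  if (is.numeric(groups)) groups <- list(groups)
  unlist(lapply(groups, function(g) g - mean(g)), use.names = FALSE)
}

#' Day-centered two-tailed variance F-test
#'
#' Compares single-user against multi-user variability: each day's mean is
#' subtracted from that day's measurements, then
#' `F = var(single centered) / var(multi centered)` with
#' `df = (N_single - 1, N_multi - 1)` and a two-tailed p-value doubling the
#' smaller tail. The day-centering slightly inflates the nominal degrees of
#' freedom; the printed convention (per-experiment N - 1) is kept.
#'
#' @param multi multi-user samples: numeric vector (one day) or list of
#'   per-day numeric vectors.
#' @param single single-user samples, same structure.
#' @return list of class `helixreg_test` with `statistic`, `df` (numerator,
#'   denominator) and `p_value`.
#' @export
centered_variance_f_test <- function(multi, single) {
  cm <- .center_by_day(multi)
  cs <- .center_by_day(single)
  if (length(cs) < 2L || length(cm) < 2L)
    .helixreg_error("helixreg_stats_error", "each experiment needs n >= 2")
  vm <- stats::var(cm)
  if (vm == 0)
    .helixreg_error("helixreg_stats_error", "zero denominator variance")
  f <- stats::var(cs) / vm
  df <- c(length(cs) - 1L, length(cm) - 1L)
  p <- min(1, 2 * min(stats::pf(f, df[1], df[2]),
                      stats::pf(f, df[1], df[2], lower.tail = FALSE)))
  structure(list(statistic = f, df = df, p_value = p), class = "helixreg_test")
}

#' Benjamini-Hochberg false-discovery-rate procedure
#'
#' Standard step-up rule: sort the p-values ascending and reject all
#' hypotheses up to the largest `i` with `p_(i) <= i * alpha / m`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return list with `reject` (logical, in input order) and `threshold`
#'   (the largest rejected p-value; 0 if none).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1))
    .helixreg_error("helixreg_stats_error", "p-values must lie in [0, 1]")
  reject <- stats::p.adjust(p_values, method = "BH") <= alpha
  threshold <- if (any(reject)) max(p_values[reject]) else 0
  list(reject = reject, threshold = threshold)
}

#' Pool per-group summaries into one
#'
#' The pooled mean is the n-weighted mean of group means; the pooled SD
#' combines within- and between-group variability with an `N - 1`
#' denominator, so it equals the SD of the concatenated raw observations.
#'
#' @param groups list of `group_summary` objects.
#' @return a `group_summary` for the pooled data.
#' @export
pooled_summary <- function(groups) {
  if (inherits(groups, "group_summary")) return(groups)
  stopifnot(length(groups) >= 1L, all(vapply(groups, inherits, TRUE, "group_summary")))
  if (length(groups) == 1L) return(groups[[1]])
  n <- vapply(groups, `[[`, 0L, "n")
  m <- vapply(groups, `[[`, 0, "mean")
  s <- vapply(groups, `[[`, 0, "sd")
  N <- sum(n)
  gm <- sum(n * m) / N
  ss <- sum((n - 1) * s^2 + n * (m - gm)^2)
  group_summary(N, gm, sqrt(ss / (N - 1)), label = "pooled")
}

#' @export
print.helixreg_test <- function(x, ...) {
  if (length(x$df) == 2L)
    cat(sprintf("F(%d,%d) = %.3f, p = %.4g\n", x$df[1], x$df[2], x$statistic, x$p_value))
  else
    cat(sprintf("t(%d) = %.3f, p = %.4g\n", x$df, x$statistic, x$p_value))
  invisible(x)
}
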