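# Group comparisons and correlations for vortex and physiological
# parameters.

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two groups: exact-distribution p-value
#' when the combined sample size is at most 20 and there are no ties, normal
#' approximation (with tie correction, and continuity correction by default)
#' otherwise.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param continuity apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return list with `statistic` (Mann-Whitney U of the first group), `p`,
#'   `n` (per-group sizes) and `method`.
#' @export
rank_sum_test <- function(group_a, group_b, continuity = TRUE) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b) <= 20) && !ties
  res <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = continuity))
  list(statistic = unname(res$statistic), p = res$p.value,
       n = c(length(group_a), length(group_b)),
       method = if (exact) "exact" else "normal approximation")
}

#' Linear correlation analysis
#'
#' Ordinary least squares of `y` on `x`; reports the slope, intercept,
#' squared Pearson correlation and the two-sided p-value from the t
#' distribution on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3; `x` must vary.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
linear_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("linear correlation needs at least 3 points")
  if (var(x) == 0) stop("x has zero variance")
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  n <- length(x)
  tval <- sqrt(pmax(r2, 0) * (n - 2) / max(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, p = p, n = n)
}

#' Bonferroni family-wise threshold
#'
#' @param alpha nominal significance level, in (0,1).
#' @param n_tests number of analyses in the family (>= 1).
#' @return the corrected per-test threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Correlation battery over a metrics table
#'
#' Declarative reproduction of a covariates-by-outcomes-by-groups battery of
#' linear correlations with a shared Bonferroni threshold: each combination
#' of covariate, outcome and group contributes one analysis.
#'
#' @param data data frame with one row per subject.
#' @param covariates,outcomes column names.
#' @param group_col column holding the group labels (optional; `NULL` runs a
#'   single pooled battery).
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame of class `stats_report` with one row per analysis
#'   (`covariate`, `outcome`, `group`, `n`, `slope`, `r_squared`, `p`,
#'   `significant`) and attributes `n_tests` and `threshold`.
#' @export
correlation_battery <- function(data, covariates, outcomes, group_col = NULL,
                                alpha = 0.05) {
  groups <- if (is.null(group_col)) list(all = rep(TRUE, nrow(data)))
            else split(seq_len(nrow(data)), data[[group_col]])
  rows <- list()
  for (g in names(groups)) {
    sub <- data[unlist(groups[[g]]), , drop = FALSE]
    for (oc in outcomes) for (cv in covariates) {
      res <- tryCatch(linear_correlation(sub[[cv]], sub[[oc]]),
                      error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, outcome = oc, group = g,
        n = if (is.null(res)) nrow(sub) else res$n,
        slope = if (is.null(res)) NA_real_ else res$slope,
        r_squared = if (is.null(res)) NA_real_ else res$r_squared,
        p = if (is.null(res)) NA_real_ else res$p)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)
  thr <- bonferroni_threshold(alpha, n_tests)
  out$significant <- !is.na(out$p) & out$p < thr
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  class(out) <- c("stats_report", "data.frame")
  out
}
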