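# The statistical battery used across the validation protocol: model II
# (reduced major axis) regression, paired tests, Pearson correlation and
# fixed-effects factorial ANOVA. Standard tests delegate to stats::; the
# RMA estimator is implemented here (closed form).

#' Model II (reduced major axis) regression
#'
#' For method-comparison settings where both variables carry error, the
#' reduced-major-axis estimate: `slope = sign(r) * sd(y) / sd(x)`,
#' `intercept = mean(y) - slope * mean(x)`, with Pearson `r^2`. The slope
#' is scale-equivariant (`slope(cx, y) = slope(x, y) / c`) and free of the
#' attenuation bias of ordinary least squares under error in x.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, both with positive
#'   variance.
#' @return object of class `model2_fit` (list: `slope`, `intercept`,
#'   `r_squared`, `r`, `n`). `tidy()` gives term estimates, `glance()` the
#'   fit summary.
#' @export
model2_regression <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (slope == 0) slope <- sd(y) / sd(x)   # r exactly 0: sign convention +
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r_squared = r^2, r = r, n = length(x)),
            class = "model2_fit")
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("<model2_fit (RMA)> slope %.4g, intercept %.4g, r^2 %.4f, n %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.model2_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.model2_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, r = x$r, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' Paired t-test, Wilcoxon signed-rank and Pearson correlation
#'
#' Thin wrappers around [stats::t.test()], [stats::wilcox.test()] and
#' [stats::cor.test()] returning tidy one-row tibbles with two-sided
#' p-values. `paired_t()` rejects all-constant differences (t undefined);
#' the signed-rank test returns its statistic trivially in that case.
#'
#' @param a,b equal-length paired samples (`n >= 3`).
#' @return one-row tibble of statistic and p-value.
#' @export
paired_t <- function(a, b) {
  check_paired(a, b)
  d <- a - b
  if (sd(d) == 0) {
    # identical samples carry no evidence of a difference; a constant
    # non-zero difference leaves t genuinely undefined
    if (all(d == 0))
      return(tibble(t = 0, df = length(a) - 1, p_value = 1))
    abort("zero variance of paired differences: t statistic undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' @rdname paired_t
#' @export
wilcoxon_signed_rank <- function(a, b) {
  check_paired(a, b)
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  tibble(W = unname(ht$statistic), p_value = ht$p.value)
}

#' @rdname paired_t
#' @param x,y vectors for the correlation.
#' @export
pearson <- function(x, y) {
  check_paired(x, y)
  ht <- stats::cor.test(x, y)
  tibble(r = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value)
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) abort("samples must have equal length")
  if (length(a) < 3) abort("need at least 3 pairs")
  invisible(TRUE)
}

#' Fixed-effects factorial ANOVA
#'
#' Fits `response ~ factor1 + factor2 + ...` (main effects; interactions
#' added with `interactions = TRUE` when replicates exist) with
#' [stats::aov()] and returns per-factor F and p. Every factor-level cell
#' must be non-empty.
#'
#' @param table data frame with a numeric `response` column and factor
#'   columns named in `factors`.
#' @param factors character vector of factor column names.
#' @param response name of the response column (default `"response"`).
#' @param interactions include all interaction terms (default `FALSE`;
#'   with one observation per cell only main effects are estimable).
#' @return `anova_result` tibble: `term`, `df`, `sum_sq`, `statistic`
#'   (F), `p_value`.
#' @export
factorial_anova <- function(table, factors, response = "response",
                            interactions = FALSE) {
  miss <- setdiff(c(response, factors), names(table))
  if (length(miss))
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  for (f in factors) table[[f]] <- factor(table[[f]])
  cells <- table(interaction(table[factors], drop = FALSE))
  if (any(cells == 0))
    abort(paste0("empty design cells: ",
                 paste(utils::head(names(cells)[cells == 0], 5),
                       collapse = ", ")))
  if (var(table[[response]]) == 0) {
    # a constant response carries no effects: report F = 0, p = 1 for every
    # factor rather than the 0/0 ratio of round-off sums of squares
    out <- tibble(term = factors, df = NA_integer_, sum_sq = 0,
                  statistic = 0, p_value = 1)
    class(out) <- c("anova_result", class(out))
    return(out)
  }
  op <- if (interactions) " * " else " + "
  fm <- stats::as.formula(paste(response, "~",
                                paste(factors, collapse = op)))
  fit <- stats::aov(fm, data = table)
  sm <- summary(fit)[[1]]
  out <- tibble(term = trimws(rownames(sm)), df = sm$Df,
                sum_sq = sm$`Sum Sq`, statistic = sm$`F value`,
                p_value = sm$`Pr(>F)`)
  # a constant response has zero sums of squares everywhere: F is 0/0;
  # report no effect rather than NaN
  degen <- !is.finite(out$statistic) & out$sum_sq < .Machine$double.eps
  out$statistic[degen] <- 0
  out$p_value[degen] <- 1
  class(out) <- c("anova_result", class(out))
  out
}

#' Align two series by cross-correlation, then correlate and regress
#'
#' Finds the lag (within `+-max_lag` samples) maximizing the normalized
#' cross-correlation of the mean-removed series, shifts `series_b` by that
#' lag, and on the overlapping samples computes Pearson `r^2` and a model
#' II (RMA) regression of `b` on `a`. Used to compare twitch series
#' estimated under two detection conditions.
#'
#' @param series_a,series_b equal-rate numeric series.
#' @param max_lag maximum lag magnitude in samples (< half the series
#'   length).
#' @return one-row tibble: `lag`, `r`, `r_squared`, `slope`, `intercept`,
#'   `n_overlap`.
#' @export
align_and_compare <- function(series_a, series_b, max_lag = 40) {
  if (max_lag >= min(length(series_a), length(series_b)) / 2)
    abort("`max_lag` must be below half the series length")
  if (sd(series_a) == 0 || sd(series_b) == 0)
    abort("constant series: correlation undefined")
  a <- series_a - mean(series_a)
  b <- series_b - mean(series_b)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    # positive lag: b delayed by l relative to a
    if (l >= 0) { ai <- seq_len(length(a) - l); bi <- ai + l }
    else { bi <- seq_len(length(b) + l); ai <- bi - l }
    if (sd(a[ai]) == 0 || sd(b[bi]) == 0) return(-Inf)
    cor(a[ai], b[bi])
  }, numeric(1))
  lag <- lags[which.max(cc)]
  if (lag >= 0) { ai <- seq_len(length(a) - lag); bi <- ai + lag }
  else { bi <- seq_len(length(b) + lag); ai <- bi - lag }
  fit <- model2_regression(series_a[ai], series_b[bi])
  tibble(lag = lag, r = fit$r, r_squared = fit$r_squared, slope = fit$slope,
         intercept = fit$intercept, n_overlap = length(ai))
}
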