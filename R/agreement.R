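#' Pearson correlation with ordinary least-squares regression
#'
#' The correlation/regression pair used for method comparison: Pearson's r
#' with its two-tailed p-value, and the OLS fit of `y` on `x`.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must not be
#'   constant.
#' @return a list with `n`, `r`, `r_squared`, `slope`, `intercept`,
#'   `p_value` (two-tailed, for the correlation).
#' @examples
#' pearson_regression(1:10, 2 * (1:10) + 1)  # r = 1, slope = 2, intercept = 1
#' @export
pearson_regression <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (sd(x) == 0) stopf("`x` is constant; correlation and slope are undefined")
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  list(n = n, r = r, r_squared = r^2,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       p_value = ct$p.value)
}

#' Bland-Altman method agreement
#'
#' Compares two measurement methods on paired data via the differences
#' `d = a - b`: mean difference (bias), SD of the differences (sample,
#' n - 1 denominator), limits of agreement at mean +/- 2 SD, the
#' percentage of pairs falling within those limits, and a
#' proportional-error regression of the differences on the pairwise means
#' `(a + b) / 2` (a nonzero slope indicates magnitude-dependent bias).
#'
#' @param a,b numeric vectors of equal length, n >= 3 (method A and
#'   method B on the same subjects, in the same units).
#' @return an object of class `bland_altman`: list with `n`,
#'   `mean_difference`, `sd_difference`, `loa_low`, `loa_high`,
#'   `pct_within_2sd`, `prop_error_slope`, `prop_error_intercept`,
#'   `differences`, `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stopf("need at least 3 complete pairs")
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- sd(d)
  within <- abs(d - md) <= 2 * sdd
  if (sd(m) > 0) {
    fit <- coef(lm(d ~ m))
    slope <- unname(fit[2L]); icpt <- unname(fit[1L])
  } else {
    slope <- NA_real_; icpt <- NA_real_
  }
  structure(list(n = n, mean_difference = md, sd_difference = sdd,
                 loa_low = md - 2 * sdd, loa_high = md + 2 * sdd,
                 pct_within_2sd = 100 * mean(within),
                 prop_error_slope = slope, prop_error_intercept = icpt,
                 differences = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  mean difference %.3f, SD %.3f, limits [%.3f, %.3f]\n",
              x$mean_difference, x$sd_difference, x$loa_low, x$loa_high))
  cat(sprintf("  %.1f%% of pairs within mean +/- 2 SD\n", x$pct_within_2sd))
  if (is.finite(x$prop_error_slope))
    cat(sprintf("  proportional error: d = %.3f * mean + %.3f\n",
                x$prop_error_slope, x$prop_error_intercept))
  invisible(x)
}

#' Unpaired two-sample t test (pooled variance, two-tailed)
#'
#' Classic pooled-variance t statistic with a two-tailed p-value. The
#' degenerate case of zero pooled variance returns `t = 0, p = 1` when the
#' group means are equal (no evidence of a difference from identical
#' constants) and `t = +/-Inf, p = 0` when they differ.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return a list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
unpaired_t_test <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 observations")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    dm <- mean(a) - mean(b)
    tval <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
    return(list(t = tval, df = df, p_value = p, mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Complication rates stratified by risk band
#'
#' Tabulates event rates per risk band and overall. Bands with no patients
#' are absent from the table (an undefined rate is not reported as 0).
#' Rates are kept at full precision; the print method rounds to one
#' decimal.
#'
#' @param bands vector (factor or character) of band labels, one per
#'   patient.
#' @param events logical vector of the same length: did the patient have
#'   the complication.
#' @return an object of class `rate_table`: data frame with columns
#'   `band`, `n`, `events`, `rate_pct`; the final row (`band = "overall"`)
#'   covers all patients.
#' @examples
#' complication_rates(c("a", "a", "b", "b"), c(TRUE, FALSE, FALSE, FALSE))
#' @export
complication_rates <- function(bands, events) {
  if (length(bands) != length(events))
    stopf("`bands` and `events` must have equal length")
  if (!is.logical(events)) stopf("`events` must be logical")
  if (anyNA(bands) || anyNA(events)) stopf("missing band labels or event flags")
  f <- if (is.factor(bands)) bands else factor(bands)
  lv <- levels(f)[tabulate(f, nbins = nlevels(f)) > 0L]
  rows <- lapply(lv, function(l) {
    sel <- f == l
    data.frame(band = l, n = sum(sel), events = sum(events[sel]),
               rate_pct = 100 * sum(events[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(band = "overall", n = length(f),
                               events = sum(events),
                               rate_pct = 100 * mean(events),
                               stringsAsFactors = FALSE))
  structure(out, class = c("rate_table", "data.frame"))
}

#' @export
print.rate_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$rate_pct <- round(y$rate_pct, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Overall, respiratory and cardiovascular complication rates
#'
#' Convenience summary over a cohort table carrying
#' `complication_respiratory` and `complication_cardiovascular` flags:
#' the rate of any complication, of respiratory complications, and of
#' cardiovascular complications, as percentages of the cohort.
#'
#' @param cohort data frame with logical columns `complication_respiratory`
#'   and `complication_cardiovascular` (and optionally `complication_any`;
#'   recomputed as the union when absent).
#' @return a data frame with columns `category`, `n`, `events`, `rate_pct`.
#' @export
complication_summary <- function(cohort) {
  need <- c("complication_respiratory", "complication_cardiovascular")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L)
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  resp <- as.logical(cohort$complication_respiratory)
  card <- as.logical(cohort$complication_cardiovascular)
  any_ <- if ("complication_any" %in% names(cohort))
    as.logical(cohort$complication_any) else (resp | card)
  n <- nrow(cohort)
  data.frame(
    category = c("any", "respiratory", "cardiovascular"),
    n = n,
    events = c(sum(any_), sum(resp), sum(card)),
    rate_pct = 100 * c(sum(any_), sum(resp), sum(card)) / n,
    stringsAsFactors = FALSE
  )
}
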