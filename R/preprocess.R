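#' Tukey 3xIQR fences for extreme outliers
#'
#' Extreme outliers are values below `Q1 - 3 * (Q3 - Q1)` or above
#' `Q3 + 3 * (Q3 - Q1)`, where Q1 and Q3 are the 25th and 75th percentiles of
#' the non-missing values. Percentiles use linear interpolation between order
#' statistics by default (`stats::quantile()` type 7); the `type` argument
#' makes the estimator explicit because the fences depend on it.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param multiplier IQR multiplier; 3 flags *extreme* outliers (1.5 would
#'   flag ordinary Tukey outliers).
#' @param type Quantile estimation type passed to [stats::quantile()].
#' @return `outlier_bounds()`: a one-row tibble with `q1`, `q3`, `lower`,
#'   `upper`. `flag_extreme_outliers()`: a logical inclusion mask the length
#'   of `x` - `TRUE` for values inside the fences, `FALSE` for outliers, and
#'   `NA` wherever `x` is missing (missing values are never flagged).
#' @examples
#' flag_extreme_outliers(c(1:10, 100))
#' @export
outlier_bounds <- function(x, multiplier = 3, type = 7) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0)
    abort_eaa("All values are missing; cannot compute outlier bounds.", "empty_input")
  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE, type = type)
  iqr <- q[2] - q[1]
  if (is.finite(multiplier)) {
    lower <- q[1] - multiplier * iqr
    upper <- q[2] + multiplier * iqr
  } else {
    lower <- -Inf
    upper <- Inf
  }
  tibble::tibble(q1 = q[1], q3 = q[2], lower = lower, upper = upper)
}

#' @rdname outlier_bounds
#' @param bounds Optional precomputed bounds (as returned by
#'   `outlier_bounds()`); used to re-apply fences estimated on a reference
#'   sample.
#' @export
flag_extreme_outliers <- function(x, multiplier = 3, type = 7, bounds = NULL) {
  if (sum(!is.na(x)) > 0 && sum(!is.na(x)) < 4 && is.null(bounds))
    abort_eaa("Need at least 4 non-missing values to estimate quartile fences.",
              "insufficient_data")
  if (is.null(bounds)) bounds <- outlier_bounds(x, multiplier, type)
  ifelse(is.na(x), NA, x >= bounds$lower & x <= bounds$upper)
}

#' Log-transform and z-score an outcome
#'
#' Right-skewed outcomes (fasting glucose, HbA1c) are natural-log transformed
#' to meet the normality assumption of the linear models; all outcomes are
#' then standardised as z-scores. Standardisation uses the sample SD (n - 1
#' denominator) of the reference values. Missing values are preserved.
#'
#' @param x Numeric vector.
#' @param log_transform Apply `log()` before standardising? Requires strictly
#'   positive values.
#' @param standardize Standardise to mean 0, SD 1?
#' @param reference Values defining the standardisation mean/SD (default `x`
#'   itself); they receive the same log transform.
#' @return Numeric vector the length of `x`.
#' @examples
#' transform_outcome(c(1, exp(1), exp(2)), log_transform = TRUE)
#' @export
transform_outcome <- function(x, log_transform = FALSE, standardize = TRUE,
                              reference = x) {
  force(reference)  # default must bind pre-transform values
  if (log_transform) {
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad) > 0)
      abort_eaa(paste0("Nonpositive value under log transform at position ",
                       bad[1], "."), "domain_error")
    x <- log(x)
    reference <- log(reference)
  }
  if (!standardize) return(x)
  mu <- mean(reference, na.rm = TRUE)
  s <- stats::sd(reference, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    abort_eaa("Zero variance in reference sample; cannot standardise.",
              "degenerate_input")
  (x - mu) / s
}

#' Sample skewness (Fisher-Pearson g1)
#'
#' Returns the standardised third central moment
#' `g1 = m3 / m2^(3/2)` with population moments `mk = mean((x - mean(x))^k)`.
#' This is the plain (unadjusted) convention; the small-sample adjusted G1
#' equals `g1 * sqrt(n (n - 1)) / (n - 2)`.
#'
#' @param x Numeric vector; `NA` dropped.
#' @return A single numeric.
#' @examples
#' sample_skewness(c(-2, -1, 0, 1, 2))  # 0
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3)
    abort_eaa("Need at least 3 non-missing values for skewness.", "insufficient_data")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    abort_eaa("Zero variance; skewness undefined.", "degenerate_input")
  mean((x - m)^3) / m2^1.5
}
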