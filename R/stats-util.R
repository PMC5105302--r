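# Closed-form statistical kernel shared by the analysis modules.

#' Two-sample t test assuming equal variances
#'
#' Pooled-variance (Student) two-sample t test with a two-tailed p value,
#' the test used throughout for comparing engineered strains against the
#' wild type (growth rates, photosynthetic yield, normalized fluorescence,
#' and light-vs-dark delta-CT values).
#'
#' The p value is computed in closed form from the regularized incomplete
#' beta function: for t with `df` degrees of freedom,
#' `p = I_x(df/2, 1/2)` with `x = df / (df + t^2)`.
#'
#' @param a,b Numeric vectors of measurements (each of length >= 2).
#' @return A one-row tibble with columns `t_statistic`,
#'   `degrees_of_freedom`, `p_two_tail`, `mean_a`, `mean_b`.
#' @examples
#' two_sample_ttest_equal_var(c(0.031, 0.035, 0.040), c(0.033, 0.036, 0.042))
#' @export
two_sample_ttest_equal_var <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2 || n2 < 2) {
    abort("both samples need at least 2 observations")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (!is.finite(sp2) || sp2 <= 0) {
    abort("pooled variance must be positive (degenerate samples)")
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- pbeta(df / (df + t_stat^2), df / 2, 0.5)
  tibble(
    t_statistic = t_stat,
    degrees_of_freedom = df,
    p_two_tail = p,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}

#' Ordinary least-squares line through (x, y)
#'
#' Closed-form simple linear regression, used for the
#' fluorescence-versus-OD730 slopes that define regulatory patterns.
#'
#' @param x,y Numeric vectors of equal length (>= 2); `x` must vary.
#' @return A named numeric vector with elements `slope` and `intercept`.
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) abort("need at least 2 finite (x, y) points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("x values are all equal; slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Pearson product-moment correlation
#'
#' Used to compare reporter-fluorescence profiles against transcript
#' abundance profiles across the growth curve.
#'
#' @param x,y Numeric vectors of equal length (>= 3 finite pairs).
#' @return Correlation coefficient in \[-1, 1\], or `NA` when either
#'   vector has zero variance.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 finite (x, y) pairs")
  dx <- x - mean(x)
  dy <- y - mean(y)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0) {
    return(NA_real_)
  }
  r <- sum(dx * dy) / denom
  max(-1, min(1, r))
}

#' Mean and sample standard deviation
#'
#' Replicate aggregation convention used for every reported value:
#' arithmetic mean with the n-1 (sample) standard deviation as error.
#'
#' @param x Numeric vector (length >= 1; the SD needs >= 2).
#' @return A named numeric vector with elements `mean` and `sd` (`sd` is
#'   `NA` for a single observation).
#' @export
mean_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("empty sample")
  c(mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_)
}
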