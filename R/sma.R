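#' Standardized major axis (SMA) regression
#'
#' Fits a line symmetric in x and y: slope `sign(r) * sd(y)/sd(x)`, intercept
#' through the means. SMA is the appropriate line for allometric slopes where
#' both variables carry error; ordinary least squares attenuates the slope by
#' a factor |r|. The confidence interval and the correlation test use the
#' standard F statistic with `n - 2` df (Warton et al. 2006, Biol. Rev.).
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval) holding the x and y values, typically
#'   already log-transformed.
#' @param alpha Confidence level is `1 - alpha` (default 95%).
#' @param method `"sma"` (default) or `"ols"` (ordinary least squares; kept
#'   for the attenuation comparison).
#' @return An object of class `sma_fit` with elements `slope`, `intercept`,
#'   `n`, `r`, `r_squared`, `ci_lower`, `ci_upper`, `p_correlation`, `method`,
#'   and the data used. [tidy()] and [glance()] methods are provided.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + rnorm(10, sd = 0.1))
#' sma_fit(d, x, y)
#' @export
sma_fit <- function(data, x, y, alpha = 0.05, method = c("sma", "ols")) {
  method <- match.arg(method)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  x_lab <- rlang::as_label(rlang::enquo(x))
  y_lab <- rlang::as_label(rlang::enquo(y))
  if (!is.numeric(xv) || !is.numeric(yv)) stop("x and y must be numeric", call. = FALSE)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  sx <- stats::sd(xv); sy <- stats::sd(yv)
  if (sx == 0 || sy == 0) stop("zero variance in ", if (sx == 0) x_lab else y_lab,
                               call. = FALSE)
  r <- stats::cor(xv, yv)
  s <- if (r < 0) -1 else 1

  if (method == "sma") {
    slope <- s * sy / sx
    # CI: slope * (sqrt(B + 1) +/- sqrt(B)), B = F(1-alpha; 1, n-2) (1-r^2)/(n-2)
    B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
    ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  } else {
    slope <- r * sy / sx
    se <- sqrt((1 - r^2) / (n - 2)) * sy / sx
    ci <- slope + c(-1, 1) * stats::qt(1 - alpha / 2, n - 2) * se
  }
  intercept <- mean(yv) - slope * mean(xv)
  if (abs(r) >= 1) {
    p_cor <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p_cor <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(
    slope = slope, intercept = intercept, n = n, r = r, r_squared = r^2,
    ci_lower = ci[1], ci_upper = ci[2], p_correlation = p_cor,
    alpha = alpha, method = method, x = xv, y = yv,
    x_label = x_lab, y_label = y_lab
  ), class = "sma_fit")
}

#' Ordinary least squares fit (attenuation reference)
#'
#' Convenience wrapper around [sma_fit()] with `method = "ols"`. OLS slopes on
#' allometric data with error in both axes are attenuated: exactly
#' `|slope_OLS| = |r| * |slope_SMA|`.
#'
#' @inheritParams sma_fit
#' @return An `sma_fit` object with `method = "ols"`.
#' @export
ols_fit <- function(data, x, y, alpha = 0.05) {
  sma_fit(data, {{ x }}, {{ y }}, alpha = alpha, method = "ols")
}

#' Test an SMA slope against a hypothesized value
#'
#' Tests H0: slope = `b0` (e.g. -1, inverse proportionality in the
#' size-number trade-off). The test correlates the residual axis
#' `y - b0 * x` with the fitted axis `y + b0 * x`; under H0 this correlation
#' is zero, and the F statistic `r_rf^2 (n-2) / (1 - r_rf^2)` has 1 and
#' `n - 2` df.
#'
#' @param fit An `sma_fit` object with `method = "sma"`.
#' @param b0 Hypothesized slope; must be nonzero (the rotation is undefined
#'   at 0 — use the correlation test for slope vs 0).
#' @return A list of class `sma_slope_test`: `b0`, `r`, `statistic` (F),
#'   `df`, `p_value`.
#' @examples
#' d <- data.frame(x = 1:20, y = -(1:20) + rnorm(20, sd = 0.5))
#' test_sma_slope(sma_fit(d, x, y), b0 = -1)
#' @export
test_sma_slope <- function(fit, b0 = -1) {
  stopifnot(inherits(fit, "sma_fit"))
  if (fit$method != "sma") stop("slope test is defined for SMA fits", call. = FALSE)
  if (!is.numeric(b0) || length(b0) != 1 || b0 == 0 || !is.finite(b0)) {
    stop("b0 must be a single nonzero number", call. = FALSE)
  }
  res <- fit$y - b0 * fit$x
  fitax <- fit$y + b0 * fit$x
  scale <- abs(b0) * stats::sd(fit$x) + stats::sd(fit$y)
  if (stats::sd(res) <= 1e-10 * scale || stats::sd(fitax) <= 1e-10 * scale) {
    # data on the hypothesized line up to floating-point noise
    r_rf <- 0
  } else {
    r_rf <- stats::cor(res, fitax)
  }
  n <- fit$n
  if (abs(r_rf) >= 1) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- r_rf^2 * (n - 2) / (1 - r_rf^2)
    p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  }
  structure(list(b0 = b0, r = r_rf, statistic = Fstat, df = c(1, n - 2),
                 p_value = p),
            class = "sma_slope_test")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s ~ %s (n = %d)\n", toupper(x$method), x$y_label,
              x$x_label, x$n))
  cat(sprintf("  slope = %.4f [%.4f, %.4f], intercept = %.4f\n",
              x$slope, x$ci_lower, x$ci_upper, x$intercept))
  cat(sprintf("  r = %.4f, r^2 = %.4f, p(correlation) = %.3g\n",
              x$r, x$r_squared, x$p_correlation))
  invisible(x)
}

#' @export
print.sma_slope_test <- function(x, ...) {
  cat(sprintf("SMA slope test vs b0 = %g: F(%d, %d) = %.4g, p = %.3g\n",
              x$b0, x$df[1], x$df[2], x$statistic, x$p_value))
  invisible(x)
}
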