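#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SMA/OLS fit
#'
#' @param x An `sma_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per term (`intercept`, `slope`); the slope
#'   row carries the confidence interval.
#' @method tidy sma_fit
#' @export
tidy.sma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$ci_lower),
    conf.high = c(NA_real_, x$ci_upper)
  )
}

#' @rdname tidy.sma_fit
#' @method glance sma_fit
#' @export
glance.sma_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n, r = x$r, r.squared = x$r_squared,
    slope = x$slope, conf.low = x$ci_lower, conf.high = x$ci_upper,
    p.value = x$p_correlation
  )
}

#' Tidy a Pagel's lambda fit
#'
#' @param x A `lambda_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the estimate, rate, root state,
#'   log-likelihoods, LRT statistic and p value.
#' @method tidy lambda_fit
#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, root_state = x$root_state,
    logLik = x$logLik, logLik0 = x$logLik0, lrt = x$lrt, p.value = x$p_value,
    n = x$n, p.method = x$p_method
  )
}

#' @rdname tidy.lambda_fit
#' @method glance lambda_fit
#' @export
glance.lambda_fit <- function(x, ...) tidy.lambda_fit(x)

#' Tidy a trade-off report
#'
#' @param x A `tradeoff_report` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted variant: slope, CI, r^2, the
#'   correlation p value (slope vs 0) and the SMA test p value vs slope -1.
#' @method tidy tradeoff_report
#' @export
tidy.tradeoff_report <- function(x, ...) {
  purrr::map2_dfr(x$fits, x$tests, function(f, t) {
    tibble::tibble(
      slope = f$slope, conf.low = f$ci_lower, conf.high = f$ci_upper,
      intercept = f$intercept, r = f$r, r.squared = f$r_squared,
      p.correlation = f$p_correlation, p.vs.minus1 = t$p_value, n = f$n
    )
  }, .id = "variant")
}

#' @rdname tidy.tradeoff_report
#' @method glance tradeoff_report
#' @export
glance.tradeoff_report <- function(x, ...) {
  tibble::tibble(
    n_points = x$n_points, correction = x$correction, alpha = x$alpha,
    slope_uncorrected = x$fits$uncorrected$slope,
    p_uncorrected = x$fits$uncorrected$p_correlation,
    pic_run = !is.null(x$pic)
  )
}

#' Tidy a scaling report
#'
#' @param x A `scaling_report` object.
#' @param ... Unused.
#' @return A tibble with one row per scaling fit.
#' @method tidy scaling_report
#' @export
tidy.scaling_report <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(
      slope = f$slope, conf.low = f$ci_lower, conf.high = f$ci_upper,
      intercept = f$intercept, r = f$r, r.squared = f$r_squared,
      p.correlation = f$p_correlation, n = f$n
    )
  }, .id = "relationship")
}

#' @rdname tidy.scaling_report
#' @method glance scaling_report
#' @export
glance.scaling_report <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, beta_hat = x$beta_hat,
                 log10_sigma_hat = x$log10_sigma_hat)
}
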