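# Core: the four ECDF-distance indices for one (beta, alpha) on one sample.
# S(x_i) is the right-continuous empirical CDF evaluated at each observed
# value (ties share one value, so S(x_i) >= 1/n and the percentage
# denominators are never zero); F-hat is the fitted Pareto CDF, clamped to 0
# below the fitted scale.
gof_indices <- function(x, beta, alpha) {
  s <- stats::ecdf(x)(x)
  f <- ppareto(x, beta, alpha)
  d <- s - f
  tibble::tibble(
    mae = mean(abs(d)),
    mape = mean(abs(d / s)) * 100,
    rmse = sqrt(mean(d^2)),
    rmspe = sqrt(mean((d / s)^2)) * 100
  )
}

#' Empirical-CDF goodness-of-fit indices for a fitted Pareto model
#'
#' Compares the sample's empirical distribution function \eqn{S(x_i)} with
#' the fitted CDF \eqn{\hat F(x_i) = 1 - (\hat\beta/x_i)^{\hat\alpha}} at
#' each observed point, and reports four distances used to rank competing
#' fits when the true parameters are unknown:
#' mean absolute error \eqn{MAE = \sum |S(x_i) - \hat F(x_i)| / n},
#' mean absolute percentage error (MAPE, in percent of \eqn{S(x_i)}),
#' root mean square error (RMSE), and root mean square percentage error
#' (RMSPE, in percent). Smaller is better on all four.
#'
#' Observations below the fitted scale (possible when a method overestimates
#' \eqn{\hat\beta}) get \eqn{\hat F = 0}, the model's own value on that
#' region, keeping the indices well defined.
#'
#' @inheritParams pareto_summaries
#' @param fit Either a `pareto_fit` object (indices are computed for every
#'   non-degenerate method in it) or `NULL`, in which case `beta` and
#'   `alpha` give a single model to score.
#' @param beta,alpha Parameters of a single model to score when `fit` is
#'   `NULL`.
#'
#' @return A tibble with columns `method` (or `"model"`), `mae`, `mape`,
#'   `rmse`, `rmspe`.
#' @examples
#' pareto_gof(c(1, 2), beta = 1, alpha = 1)  # MAE 0.5, MAPE 75
#' fit <- fit_pareto(data.frame(value = c(1, 2, 3, 4, 5)))
#' pareto_gof(fit)
#' @export
pareto_gof <- function(data, col, fit = NULL, beta = NULL, alpha = NULL) {
  if (inherits(data, "pareto_fit") && is.null(fit)) {
    fit <- data
    data <- fit$values
  }
  if (inherits(fit, "pareto_fit")) {
    g <- glance(fit)
    return(g[!is.na(g$mae), c("method", "mae", "mape", "rmse", "rmspe")])
  }
  x <- resolve_values(data, {{ col }})
  if (is.null(beta) || is.null(alpha)) {
    abort("supply a `pareto_fit` or both `beta` and `alpha`.",
          class = "paretile_error_input")
  }
  check_params(beta, alpha)
  dplyr::bind_cols(tibble::tibble(method = "model"), gof_indices(x, beta, alpha))
}
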