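#' The two-parameter Pareto distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Pareto distribution with scale `beta` (the support minimum) and
#' shape `alpha` (the tail index):
#' \deqn{f(x) = \alpha \beta^\alpha / x^{\alpha+1}, \qquad
#'       F(x) = 1 - (\beta/x)^\alpha, \qquad x \ge \beta.}
#' The support boundary `x = beta` is inside the support: `dpareto(beta, ...)`
#' equals `alpha/beta` and `ppareto(beta, ...)` equals 0. Below the support
#' the density and distribution function are 0 (not an error); non-positive
#' `x` is a domain error because the model only describes positive quantities.
#'
#' Random generation uses inverse-transform sampling,
#' `x = beta * (1 - U)^(-1/alpha)` with `U ~ Unif[0, 1)`, so a fixed `seed`
#' reproduces the sample exactly. The optional `seed` is applied in a local
#' RNG scope that does not disturb the caller's random stream.
#'
#' @param x Vector of positive quantiles.
#' @param q Vector of positive quantiles.
#' @param p Vector of probabilities in `[0, 1)`.
#' @param n Number of draws (a single positive integer).
#' @param beta Scale parameter, `beta > 0`; same units as the data.
#' @param alpha Shape parameter, `alpha > 0`; dimensionless.
#' @param seed Optional integer seed for reproducible draws.
#'
#' @return `dpareto`, `ppareto` and `qpareto` return numeric vectors;
#'   `rpareto` returns `n` draws, all `>= beta`.
#'
#' @examples
#' dpareto(4, beta = 2, alpha = 1)     # 0.125
#' ppareto(2, beta = 1, alpha = 2)     # 0.75
#' qpareto(0.75, beta = 1, alpha = 1)  # 4
#' rpareto(5, beta = 1, alpha = 2, seed = 7)
#' @name pareto
NULL

check_params <- function(beta, alpha) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` (scale) must be a single positive number.",
          class = "paretile_error_params")
  }
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` (shape) must be a single positive number.",
          class = "paretile_error_params")
  }
  invisible(NULL)
}

#' @rdname pareto
#' @export
dpareto <- function(x, beta, alpha) {
  check_params(beta, alpha)
  if (any(!is.finite(x) | x <= 0)) {
    abort("`x` must be positive.", class = "paretile_error_domain")
  }
  ifelse(x >= beta, alpha * beta^alpha / x^(alpha + 1), 0)
}

#' @rdname pareto
#' @export
ppareto <- function(q, beta, alpha) {
  check_params(beta, alpha)
  if (any(!is.finite(q) | q <= 0)) {
    abort("`q` must be positive.", class = "paretile_error_domain")
  }
  ifelse(q >= beta, 1 - (beta / q)^alpha, 0)
}

#' @rdname pareto
#' @export
qpareto <- function(p, beta, alpha) {
  check_params(beta, alpha)
  if (any(!is.finite(p) | p < 0 | p >= 1)) {
    abort("`p` must lie in [0, 1).", class = "paretile_error_domain")
  }
  beta * (1 - p)^(-1 / alpha)
}

#' @rdname pareto
#' @export
rpareto <- function(n, beta, alpha, seed = NULL) {
  check_params(beta, alpha)
  if (length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a positive integer.", class = "paretile_error_domain")
  }
  with_local_seed(seed, qpareto(runif(n), beta, alpha))
}

#' Population summaries of a Pareto distribution
#'
#' Closed-form population quantities used by the percentile-type estimators:
#' the median \eqn{\beta \, 2^{1/\alpha}} and the geometric mean
#' \eqn{\beta \, e^{1/\alpha}} (the latter from
#' \eqn{E[\ln X] = \ln\beta + 1/\alpha}).
#'
#' @inheritParams pareto
#' @return A single positive number.
#' @examples
#' pareto_median(beta = 1, alpha = 2)  # sqrt(2)
#' pareto_gmean(beta = 1, alpha = 1)   # e
#' @export
pareto_median <- function(beta, alpha) {
  check_params(beta, alpha)
  beta * 2^(1 / alpha)
}

#' @rdname pareto_median
#' @export
pareto_gmean <- function(beta, alpha) {
  check_params(beta, alpha)
  beta * exp(1 / alpha)
}
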