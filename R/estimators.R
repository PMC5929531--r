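#' Closed-form estimator kernels
#'
#' The six fitting methods reduce to closed forms in a handful of sample
#' summaries; these kernels expose the forms directly, vectorised over their
#' arguments. They power [fit_pareto()] and the Monte Carlo engine, and they
#' recover the true parameters exactly when fed the corresponding population
#' quantities.
#'
#' \describe{
#'   \item{`est_pe`}{Traditional percentile estimator from the two sample
#'     quartiles: \eqn{\hat\alpha = \log 3 / (\log P_{75} - \log P_{25})},
#'     \eqn{\hat\beta = P_{25}\, 0.75^{1/\hat\alpha}}.}
#'   \item{`est_pe1`}{Median modification: the lower-quartile equation is
#'     replaced by the Pareto median \eqn{\beta 2^{1/\alpha}};
#'     \eqn{\hat\alpha = \log 0.5 / (\log \tilde X - \log P_{75})},
#'     \eqn{\hat\beta = \tilde X / 2^{1/\hat\alpha}}.}
#'   \item{`est_pe2`}{Geometric-mean modification, using
#'     \eqn{GM = \beta e^{1/\alpha}}:
#'     \eqn{\hat\alpha = (\log 0.25 + 1)/(\log GM - \log P_{75})},
#'     \eqn{\hat\beta = GM\, e^{-1/\hat\alpha}}. The constant 1 is
#'     \eqn{\ln e}, so natural logarithms are required here.}
#'   \item{`est_pe3`}{Minimum-based modification, using the expected
#'     empirical CDF of the first order statistic,
#'     \eqn{E[F(x_{(1)})] = 1/(n+1)}:
#'     \eqn{\hat\alpha = (\log 0.25 - \log n + \log(n+1)) /
#'          (\log x_{(1)} - \log P_{75})},
#'     \eqn{\hat\beta = x_{(1)} (n/(n+1))^{1/\hat\alpha}}.}
#'   \item{`est_ml`}{Maximum likelihood: \eqn{\hat\beta = x_{(1)}},
#'     \eqn{\hat\alpha = n / (\sum \ln x_i - n \ln \hat\beta)}.}
#'   \item{`est_mm`}{Method of moments:
#'     \eqn{\hat\alpha = 1 + \sqrt{1 + \bar X^2 / S^2}} (always `> 2`),
#'     \eqn{\hat\beta = \bar X (\hat\alpha - 1)/\hat\alpha}.}
#' }
#'
#' Degenerate inputs (zero denominators, non-positive or non-finite
#' estimates) yield `NA` in both columns; [fit_pareto()] reports these as
#' failed fits and the Monte Carlo engine counts them.
#'
#' @param p25,p75 Lower and upper sample (or population) quartiles.
#' @param median Sample (or population) median.
#' @param gmean Sample (or population) geometric mean.
#' @param xmin Sample minimum (first order statistic).
#' @param n Sample size.
#' @param mean_log Mean of the log observations, \eqn{\sum \ln x_i / n}.
#' @param mean,sd Sample mean and standard deviation.
#'
#' @return A tibble with columns `beta_hat`, `alpha_hat` (one row per input
#'   element; `NA` where the method degenerates).
#' @examples
#' est_pe(p25 = 2, p75 = 6)                      # alpha_hat 1, beta_hat 1.5
#' est_pe3(xmin = 4/3, p75 = 4, n = 3)           # recovers beta 1, alpha 1
#' est_ml(xmin = 1, mean_log = log(120) / 5, n = 5)
#' @name estimator-kernels
NULL

# Common sanitation: a fit is valid only with finite positive parameters.
kernel_result <- function(beta_hat, alpha_hat) {
  ok <- is.finite(beta_hat) & is.finite(alpha_hat) & beta_hat > 0 & alpha_hat > 0
  beta_hat[!ok] <- NA_real_
  alpha_hat[!ok] <- NA_real_
  tibble::tibble(beta_hat = beta_hat, alpha_hat = alpha_hat)
}

#' @rdname estimator-kernels
#' @export
est_pe <- function(p25, p75) {
  alpha_hat <- log(3) / (log(p75) - log(p25))
  kernel_result(p25 * 0.75^(1 / alpha_hat), alpha_hat)
}

#' @rdname estimator-kernels
#' @export
est_pe1 <- function(median, p75) {
  alpha_hat <- (log(0.25) + log(2)) / (log(median) - log(p75))
  kernel_result(median / 2^(1 / alpha_hat), alpha_hat)
}

#' @rdname estimator-kernels
#' @export
est_pe2 <- function(gmean, p75) {
  alpha_hat <- (log(0.25) + 1) / (log(gmean) - log(p75))
  kernel_result(gmean * exp(-1 / alpha_hat), alpha_hat)
}

#' @rdname estimator-kernels
#' @export
est_pe3 <- function(xmin, p75, n) {
  alpha_hat <- (log(0.25) - log(n) + log(n + 1)) / (log(xmin) - log(p75))
  kernel_result(xmin * (n / (n + 1))^(1 / alpha_hat), alpha_hat)
}

#' @rdname estimator-kernels
#' @export
est_ml <- function(xmin, mean_log, n) {
  alpha_hat <- 1 / (mean_log - log(xmin))
  kernel_result(xmin + 0 * alpha_hat, alpha_hat)
}

#' @rdname estimator-kernels
#' @export
est_mm <- function(mean, sd) {
  alpha_hat <- 1 + sqrt(1 + mean^2 / sd^2)
  kernel_result(mean * (alpha_hat - 1) / alpha_hat, alpha_hat)
}

pareto_methods <- c("PE", "PE-I", "PE-II", "PE-III", "ML", "MM")

# Accept spec-style codes (pe, pe1, ...) or display labels, case-insensitive.
match_methods <- function(methods) {
  codes <- c(pe = "PE", `pe-i` = "PE-I", pe1 = "PE-I", `pe-ii` = "PE-II",
             pe2 = "PE-II", `pe-iii` = "PE-III", pe3 = "PE-III",
             ml = "ML", mm = "MM")
  out <- vapply(methods, function(m) {
    key <- tolower(m)
    if (!is.na(codes[key])) codes[[key]] else NA_character_
  }, character(1))
  if (anyNA(out)) {
    abort(paste0("unknown method(s): ",
                 paste(methods[is.na(out)], collapse = ", "),
                 ". Choose from pe, pe1, pe2, pe3, ml, mm."),
          class = "paretile_error_input")
  }
  unique(unname(out))
}

# Evaluate one method from a summaries row; NA columns signal degeneracy.
fit_from_summaries <- function(s, method) {
  switch(method,
    "PE"     = est_pe(s$p25, s$p75),
    "PE-I"   = est_pe1(s$median, s$p75),
    "PE-II"  = est_pe2(s$gmean, s$p75),
    "PE-III" = est_pe3(s$min, s$p75, s$n),
    "ML"     = est_ml(s$min, s$mean_log, s$n),
    "MM"     = est_mm(s$mean, s$sd)
  )
}

#' Fit a Pareto distribution by percentile, likelihood and moment methods
#'
#' Fits the two-parameter Pareto model to a positive sample by any subset of
#' six methods: the traditional percentile estimator (`"pe"`), its three
#' modifications based on the median (`"pe1"`), the geometric mean (`"pe2"`)
#' and the expected empirical CDF of the sample minimum (`"pe3"`), maximum
#' likelihood (`"ml"`) and the method of moments (`"mm"`). See
#' [estimator-kernels] for the closed forms.
#'
#' A method that degenerates on the given sample (for example, tied quartiles
#' make the percentile denominator zero, or a constant sample) is reported
#' with `NA` estimates and a note rather than aborting the remaining methods;
#' set `strict = TRUE` to turn any degeneracy into a classed error
#' (`paretile_error_degenerate`) instead.
#'
#' @inheritParams pareto_summaries
#' @param methods Methods to fit; any of `"pe"`, `"pe1"`, `"pe2"`, `"pe3"`,
#'   `"ml"`, `"mm"` (display labels such as `"PE-III"` also work).
#' @param strict If `TRUE`, abort with a `paretile_error_degenerate` error
#'   when any requested method degenerates on the sample.
#'
#' @return An object of class `pareto_fit`: a list with `estimates` (a tibble
#'   with columns `method`, `beta_hat`, `alpha_hat`, `note`), the sample
#'   `values`, and the conventions used. Supports [tidy()], [glance()]
#'   (which attaches goodness-of-fit indices) and [autoplot()].
#'
#' @examples
#' fit <- fit_pareto(data.frame(value = c(1, 2, 3, 4, 5)))
#' tidy(fit)
#' glance(fit)
#' @export
fit_pareto <- function(data, col, methods = c("pe", "pe1", "pe2", "pe3", "ml", "mm"),
                       quantile_type = 7, sd_denom = c("n-1", "n"),
                       strict = FALSE) {
  x <- resolve_values(data, {{ col }})
  sd_denom <- match.arg(sd_denom)
  if (length(x) < 2L) {
    abort("at least two observations are required to fit.",
          class = "paretile_error_input")
  }
  methods <- match_methods(methods)
  s <- pareto_summaries(x, quantile_type = quantile_type, sd_denom = sd_denom)
  est <- purrr::map_dfr(methods, function(m) {
    r <- fit_from_summaries(s, m)
    tibble::tibble(
      method = m, beta_hat = r$beta_hat, alpha_hat = r$alpha_hat,
      note = if (is.na(r$beta_hat)) "degenerate" else NA_character_
    )
  })
  if (strict && anyNA(est$beta_hat)) {
    abort(paste0("degenerate fit for method(s): ",
                 paste(est$method[is.na(est$beta_hat)], collapse = ", ")),
          class = "paretile_error_degenerate")
  }
  structure(
    list(estimates = est, values = x, summaries = s,
         quantile_type = quantile_type, sd_denom = sd_denom),
    class = "pareto_fit"
  )
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat("Pareto fit (n = ", x$summaries$n, ", quantile type ", x$quantile_type,
      ")\n\n", sep = "")
  print(x$estimates, ...)
  invisible(x)
}

#' Tidy a Pareto fit
#'
#' @param x A `pareto_fit` object from [fit_pareto()].
#' @param ... Unused.
#' @return For `tidy()`, the per-method estimates tibble (`method`,
#'   `beta_hat`, `alpha_hat`, `note`). For `glance()`, one row per method
#'   with the estimates plus the four goodness-of-fit indices of
#'   [pareto_gof()] and the sample size.
#' @export
tidy.pareto_fit <- function(x, ...) x$estimates

#' @rdname tidy.pareto_fit
#' @export
glance.pareto_fit <- function(x, ...) {
  est <- x$estimates
  gof <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    if (is.na(est$beta_hat[i])) {
      tibble::tibble(mae = NA_real_, mape = NA_real_,
                     rmse = NA_real_, rmspe = NA_real_)
    } else {
      gof_indices(x$values, est$beta_hat[i], est$alpha_hat[i])
    }
  })
  dplyr::bind_cols(est[c("method", "beta_hat", "alpha_hat")], gof,
                   tibble::tibble(n = length(x$values)))
}
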