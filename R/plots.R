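#' Plot Pareto density and distribution curves
#'
#' Overlays the closed-form PDF or CDF for a set of (scale, shape) pairs —
#' the standard way to show how the shape parameter controls tail weight at
#' a common scale.
#'
#' @param params A data frame with columns `beta`, `alpha` (one curve per
#'   row); defaults to [default_param_grid()].
#' @param xlim Range of x to draw; defaults to `[min(beta), 5 * max(beta)]`.
#' @param what `"pdf"` or `"cdf"`.
#' @param n_points Curve resolution.
#' @return A ggplot object.
#' @examples
#' plot_pareto_curves(what = "cdf")
#' @export
plot_pareto_curves <- function(params = default_param_grid(),
                               xlim = NULL, what = c("pdf", "cdf"),
                               n_points = 400) {
  what <- match.arg(what)
  if (is.null(xlim)) xlim <- c(min(params$beta), 5 * max(params$beta))
  grid <- seq(xlim[1], xlim[2], length.out = n_points)
  curves <- purrr::map_dfr(seq_len(nrow(params)), function(i) {
    b <- params$beta[i]; a <- params$alpha[i]
    tibble::tibble(
      x = grid,
      y = if (what == "pdf") dpareto(grid, b, a) else ppareto(grid, b, a),
      pair = sprintf("beta = %g, alpha = %g", b, a)
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$x, .data$y, colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x", y = if (what == "pdf") "f(x)" else "F(x)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pareto Empirical CDF of the sample with each method's
#'   fitted CDF overlaid.
#' @param object A `pareto_fit` object.
#' @param ... Unused.
#' @export
autoplot.pareto_fit <- function(object, ...) {
  x <- sort(object$values)
  emp <- tibble::tibble(x = x, F = stats::ecdf(x)(x))
  est <- object$estimates[!is.na(object$estimates$beta_hat), ]
  grid <- seq(min(x), max(x), length.out = 300)
  fitted <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    tibble::tibble(x = grid,
                   F = ppareto(grid, est$beta_hat[i], est$alpha_hat[i]),
                   method = est$method[i])
  })
  ggplot2::ggplot(emp, ggplot2::aes(.data$x, .data$F)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_line(data = fitted,
                       ggplot2::aes(colour = .data$method)) +
    ggplot2::labs(x = "x", y = "F(x)", colour = "method") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_pareto_cell Total mean square error against sample
#'   size per method, log-log, facetted by true parameter pair.
#' @param object A `pareto_mc` tibble.
#' @param metric Column to display: `"tmse"` (default) or `"trd"`.
#' @param ... Unused.
#' @export
autoplot.pareto_mc <- function(object, metric = c("tmse", "trd"), ...) {
  metric <- match.arg(metric)
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    pair = sprintf("beta = %g, alpha = %g", .data$beta_true, .data$alpha_true)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data[[metric]],
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "sample size n", y = toupper(metric), colour = "method") +
    ggplot2::theme_minimal()
}
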