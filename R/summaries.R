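#' Sample summaries used by the Pareto estimators
#'
#' One place for the sample conventions every fitting method depends on:
#' quartiles and median under a configurable plotting-position rule
#' (`stats::quantile` types 4–9, default type 7 — linear interpolation at
#' plotting position (k-1)/(n-1), the R default), the geometric mean
#' `exp(mean(log(x)))`, and the standard deviation with a configurable
#' variance denominator (default `n - 1`).
#'
#' @param data A data frame or a positive numeric vector.
#' @param col If `data` is a data frame, the (unquoted) column holding the
#'   sample; may be omitted when exactly one column is numeric.
#' @param quantile_type Plotting-position rule passed to [stats::quantile()]
#'   (an integer 4–9). Default 7.
#' @param sd_denom Denominator of the sample variance: `"n-1"` (default) or
#'   `"n"`.
#'
#' @return A one-row tibble with columns `n`, `min`, `p25`, `median`, `p75`,
#'   `max`, `mean`, `sd`, `gmean`, `mean_log`.
#' @examples
#' pareto_summaries(c(1, 2, 3, 4, 5))
#' @export
pareto_summaries <- function(data, col, quantile_type = 7, sd_denom = c("n-1", "n")) {
  x <- resolve_values(data, {{ col }})
  sd_denom <- match.arg(sd_denom)
  if (length(x) < 2L) {
    abort("at least two observations are required.",
          class = "paretile_error_input")
  }
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  v <- stats::var(x)
  if (sd_denom == "n") v <- v * (length(x) - 1) / length(x)
  ml <- mean(log(x))
  tibble::tibble(
    n = length(x), min = min(x),
    p25 = qs[1], median = qs[2], p75 = qs[3],
    max = max(x), mean = mean(x), sd = sqrt(v),
    gmean = exp(ml), mean_log = ml
  )
}

# Interpolation positions of sample quantiles within the ascending order
# statistics: h such that Q(p) = x[floor(h)] + frac(h) * (x[floor(h)+1] -
# x[floor(h)]). Exploits quantile(1:n, p, type) == h, valid for the
# continuous types 4-9; lets the Monte Carlo engine evaluate any such rule
# on a whole matrix of sorted replicates at once.
quantile_positions <- function(n, probs, type) {
  if (!type %in% 4:9) {
    abort("`quantile_type` must be one of 4..9 (continuous rules).",
          class = "paretile_error_input")
  }
  quantile(seq_len(n), probs, type = type, names = FALSE)
}

# Row-interpolate a column-sorted matrix at position h (scalar).
interp_rows <- function(xs, h) {
  n <- nrow(xs)
  lo <- max(1L, min(n, floor(h)))
  g <- h - lo
  if (g <= 0 || lo == n) xs[lo, ] else (1 - g) * xs[lo, ] + g * xs[lo + 1L, ]
}
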