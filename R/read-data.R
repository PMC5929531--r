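#' Read a univariate positive sample from a text or CSV file
#'
#' Accepts the two plain-text layouts used for heavy-tailed loss and casualty
#' datasets: one value per line, or a single-column CSV with an optional
#' header. Values must all be strictly positive numbers; a violation is
#' reported with its line number. Order is preserved.
#'
#' @param path Path to the file.
#' @param header `NA` (default) to auto-detect a non-numeric header line,
#'   `TRUE`/`FALSE` to force.
#' @return A tibble with one column `value` and one row per observation.
#' @examples
#' f <- tempfile()
#' writeLines(c("1", "2.5", "3"), f)
#' read_numeric_series(f)
#' @export
read_numeric_series <- function(path, header = NA) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "paretile_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(sub(",+$", "", lines))   # tolerate trailing commas
  keep <- nzchar(lines_trim)
  if (!any(keep)) {
    abort(paste0("file is empty: ", path), class = "paretile_error_io")
  }
  lineno <- which(keep)
  vals_chr <- lines_trim[keep]

  first_num <- suppressWarnings(as.numeric(vals_chr[1]))
  skip_header <- isTRUE(header) || (is.na(header) && is.na(first_num))
  if (skip_header) {
    lineno <- lineno[-1]
    vals_chr <- vals_chr[-1]
    if (length(vals_chr) == 0L) {
      abort(paste0("no data rows after header in ", path),
            class = "paretile_error_io")
    }
  }

  vals <- suppressWarnings(as.numeric(vals_chr))
  if (anyNA(vals)) {
    bad <- lineno[which(is.na(vals))[1]]
    abort(paste0(path, ": line ", bad, " is not numeric (\"",
                 lines_trim[bad], "\")."), class = "paretile_error_io")
  }
  if (any(vals <= 0)) {
    bad <- lineno[which(vals <= 0)[1]]
    abort(paste0(path, ": line ", bad, " is not strictly positive (",
                 lines_trim[bad], ")."), class = "paretile_error_io")
  }
  tibble::tibble(value = vals)
}
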