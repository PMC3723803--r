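#' Non-parametric scatterplot smoother
#'
#' Locally weighted scatterplot smoothing (Cleveland's lowess: tricube
#' kernel, locally linear fits) of GJT on AOA, used to eyeball changes in
#' the slope of the age function before committing to a parametric shape.
#' Robustness iterations are off by default so the curve is the pure
#' locally-weighted fit.
#'
#' @param data an [aoa_data] object with at least 5 records.
#' @param span fraction of the data in each local window, in (0, 1].
#' @param iterations robustness (bisquare) iterations; 0 = plain fit.
#' @return data frame with columns `aoa` (sorted unique observed ages) and
#'   `fitted`.
#' @export
lowess_smooth <- function(data, span = 2 / 3, iterations = 0) {
  stopifnot(inherits(data, "aoa_data"))
  if (nrow(data) < 5L) {
    stop("smoothing needs at least 5 records", call. = FALSE)
  }
  if (!(span > 0 && span <= 1)) {
    stop("`span` must lie in (0, 1]", call. = FALSE)
  }
  if (floor(span * nrow(data)) < 3L) {
    stop("window underflow: `span` covers fewer than 3 points", call. = FALSE)
  }
  sm <- lowess(data$aoa, data$gjt, f = span, iter = iterations)
  out <- unique(data.frame(aoa = sm$x, fitted = sm$y))
  rownames(out) <- NULL
  out
}
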