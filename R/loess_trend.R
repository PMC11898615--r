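#' LOESS trend of a statistic versus cell length
#'
#' Local linear regression with tricube weights over the `span` fraction of
#' nearest neighbors (degree-1 LOESS), evaluated on a grid, with the
#' pointwise standard error of the local weighted fit. A thin wrapper around
#' [stats::loess()] with `degree = 1`.
#'
#' @param x predictor (e.g. cell lengths, um); n >= 10 required.
#' @param y response (e.g. midcell proportion per cell).
#' @param span neighborhood fraction (default 0.75).
#' @param grid evaluation points; defaults to 50 points spanning `range(x)`.
#' @return data.frame with `x`, `fit`, `se`.
#' @examples
#' x <- seq(1, 4, length.out = 30)
#' loess_trend(x, 2 * x)  # exact on linear data
#' @export
loess_trend <- function(x, y, span = 0.75, grid = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need at least 10 observations")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 50)
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  data.frame(x = grid, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
}
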