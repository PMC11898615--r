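#' Time- and ensemble-averaged mean squared displacement
#'
#' Computes the MSD at lags 1..`max_lag` averaged over all frame pairs of all
#' tracks, and fits the linear model `MSD(tau) = 4 D tau + b` over lags
#' 1..`fit_lags` (the intercept b absorbs localization error). Lags for which
#' no track is long enough are omitted from the curve.
#'
#' @param tracks track data.frame (`track_id`, `frame`, `x_um`, `y_um`).
#' @param dt frame interval (s).
#' @param max_lag maximum lag in frames (>= 1).
#' @param fit_lags number of initial lags used for the linear fit (default 4).
#' @return object of class `msd_curve`: `lag_s`, `msd`, `sem`, `n` (pairs per
#'   lag), fitted `D` (um^2/s) and `intercept` (um^2).
#' @examples
#' trk <- data.frame(track_id = 1, frame = 0:9, x_um = (0:9) * 0.013,
#'                   y_um = 0)  # ballistic, v = 1 um/s
#' compute_msd(trk, dt = 0.013, max_lag = 4)
#' @export
compute_msd <- function(tracks, dt, max_lag, fit_lags = 4L) {
  if (max_lag < 1L) stop("max_lag must be >= 1")
  if (dt <= 0) stop("dt must be positive")
  msd <- sem <- npairs <- rep(NA_real_, max_lag)
  for (lag in seq_len(max_lag)) {
    if (nrow(tracks) <= lag) break
    jd <- compute_jump_distances(tracks, dt = dt, lag = lag)
    if (length(jd$r2) == 0) next
    msd[lag] <- mean(jd$r2)
    sem[lag] <- stats::sd(jd$r2) / sqrt(length(jd$r2))
    npairs[lag] <- length(jd$r2)
  }
  present <- which(!is.na(msd))
  lag_s <- present * dt
  msd <- msd[present]; sem <- sem[present]; npairs <- npairs[present]

  D <- intercept <- NA_real_
  fit_sel <- present <= min(fit_lags, max_lag)
  if (sum(fit_sel) >= 2) {
    lm_fit <- stats::lm(msd[fit_sel] ~ lag_s[fit_sel])
    intercept <- unname(stats::coef(lm_fit)[1])
    D <- unname(stats::coef(lm_fit)[2]) / 4
  } else if (sum(fit_sel) == 1) {
    # single usable lag: assume zero intercept
    D <- msd[fit_sel][1] / (4 * lag_s[fit_sel][1])
    intercept <- 0
  }
  structure(list(lag_s = lag_s, msd = msd, sem = sem, n = npairs,
                 D = D, intercept = intercept, dt = dt),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve over %d lags; fitted D = %.4g um^2/s, intercept = %.3g um^2\n",
              length(x$lag_s), x$D, x$intercept))
  invisible(x)
}

#' @export
coef.msd_curve <- function(object, ...) {
  c(D = object$D, intercept = object$intercept)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag_s, x$msd, pch = 16,
                 xlab = "lag (s)", ylab = expression(MSD ~ (mu * m^2)), ...)
  graphics::arrows(x$lag_s, x$msd - x$sem, x$lag_s, x$msd + x$sem,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  if (is.finite(x$D))
    graphics::abline(x$intercept, 4 * x$D, col = "red2")
  invisible(x)
}
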