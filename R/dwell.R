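# Dwell-time extraction and exponential decomposition.

#' Extract dwell events from tracks
#'
#' A dwell event is a maximal run of consecutive frames whose positions all
#' lie within `r_dwell` of the run's first position (the anchor). When a
#' position leaves the radius, the current run ends and a new run is anchored
#' at that position. Events spanning fewer than 2 frames are discarded; the
#' duration of an event of n frames is `(n - 1) * dt` seconds.
#'
#' @param tracks track data.frame (`track_id`, `frame`, `x_um`, `y_um`).
#' @param dt frame interval (s).
#' @param r_dwell dwell radius (um); default 0.1.
#' @return data.frame with `track_id`, `duration_s`, `n_frames`.
#' @examples
#' trk <- data.frame(track_id = 1, frame = 0:9, x_um = 0, y_um = 0)
#' extract_dwell_events(trk, dt = 0.013)  # one event of 9 * dt
#' @export
extract_dwell_events <- function(tracks, dt, r_dwell = 0.1) {
  if (r_dwell <= 0) stop("r_dwell must be positive")
  if (dt <= 0) stop("dt must be positive")
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  out_id <- list(); out_n <- list()
  for (tid in unique(tracks$track_id)) {
    sel <- tracks$track_id == tid
    x <- tracks$x_um[sel]; y <- tracks$y_um[sel]
    n <- length(x)
    runs <- integer(0)
    i <- 1L
    while (i <= n) {
      ax <- x[i]; ay <- y[i]
      j <- i
      while (j < n &&
             (x[j + 1L] - ax)^2 + (y[j + 1L] - ay)^2 <= r_dwell^2) {
        j <- j + 1L
      }
      runs <- c(runs, j - i + 1L)
      i <- j + 1L
    }
    runs <- runs[runs >= 2L]
    if (length(runs)) {
      out_id[[length(out_id) + 1L]] <- rep(tid, length(runs))
      out_n[[length(out_n) + 1L]] <- runs
    }
  }
  nf <- unlist(out_n)
  if (is.null(nf)) nf <- integer(0)
  data.frame(track_id = unlist(out_id) %||% vector(typeof(tracks$track_id), 0),
             duration_s = (nf - 1L) * dt,
             n_frames = nf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit exponential components to dwell-time durations
#'
#' Maximum-likelihood fit of a left-truncated exponential (order 1) or a
#' two-component left-truncated exponential mixture (order 2) to dwell
#' durations. Truncation at `t_min` models the shortest observable event.
#' Order 1 has the closed form `tau = mean(d) - t_min`; order 2 is fitted by
#' EM with moment-based and spread multi-starts. Order-2 results report
#' `tau1 < tau2` and component percentages summing to 100. If the data are
#' degenerate (all durations equal), order 2 falls back to order 1 with a
#' warning.
#'
#' @param durations dwell durations (s), all >= `t_min`.
#' @param order 1 or 2 exponential components.
#' @param t_min left truncation point (s); e.g. 4 frames * dt for events that
#'   must span at least 5 frames.
#' @return object of class `dwell_fit`: `order`, `tau` (s, ascending),
#'   `percent`, `loglik`, `n`, `t_min`.
#' @export
fit_dwell_times <- function(durations, order = 2L, t_min = 0) {
  order <- as.integer(order)
  if (!order %in% 1:2) stop("order must be 1 or 2")
  durations <- durations[is.finite(durations)]
  if (any(durations < t_min - 1e-12)) stop("durations must be >= t_min")
  n <- length(durations)
  if (n < 20L) stop("need at least 20 durations")
  y <- pmax(durations - t_min, 0)

  if (order == 2L && stats::sd(y) == 0) {
    warning("degenerate durations (all equal); falling back to order 1")
    order <- 1L
  }
  if (order == 1L) {
    tau <- mean(y)
    ll <- sum(stats::dexp(y, 1 / tau, log = TRUE))
    return(structure(list(order = 1L, tau = tau, percent = 100,
                          loglik = ll, n = n, t_min = t_min),
                     class = "dwell_fit"))
  }

  em_fit <- function(tau0, p0) {
    tau <- tau0; p <- c(p0, 1 - p0)
    ll_old <- -Inf
    for (it in 1:500) {
      d1 <- p[1] / tau[1] * exp(-y / tau[1])
      d2 <- p[2] / tau[2] * exp(-y / tau[2])
      tot <- d1 + d2
      tot[tot <= 0] <- .Machine$double.xmin
      g <- d1 / tot
      ll <- sum(log(tot))
      p <- c(mean(g), 1 - mean(g))
      if (p[1] < 1e-8 || p[2] < 1e-8) break
      tau <- c(sum(g * y) / sum(g), sum((1 - g) * y) / sum(1 - g))
      tau <- pmax(tau, 1e-10)
      if (abs(ll - ll_old) < 1e-10 * (abs(ll) + 1)) break
      ll_old <- ll
    }
    list(tau = tau, p = p, ll = ll)
  }

  m <- mean(y)
  starts <- list(c(m / 3, 2 * m, 0.5), c(m / 5, 1.5 * m, 0.3),
                 c(m / 2, 3 * m, 0.7), c(m / 10, m, 0.2))
  best <- NULL
  for (s in starts) {
    fit <- em_fit(c(s[1], s[2]), s[3])
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  ord <- order(best$tau)
  structure(list(order = 2L, tau = best$tau[ord],
                 percent = 100 * best$p[ord], loglik = best$ll, n = n,
                 t_min = t_min),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  if (x$order == 1L) {
    cat(sprintf("Dwell-time fit (1 component, n = %d): tau = %.4g s\n",
                x$n, x$tau))
  } else {
    cat(sprintf(
      "Dwell-time fit (2 components, n = %d): tau1 = %.4g s (%.1f%%), tau2 = %.4g s (%.1f%%)\n",
      x$n, x$tau[1], x$percent[1], x$tau[2], x$percent[2]))
  }
  invisible(x)
}

#' @export
coef.dwell_fit <- function(object, ...) {
  if (object$order == 1L) c(tau = object$tau)
  else c(tau1 = object$tau[1], tau2 = object$tau[2],
         pct1 = object$percent[1], pct2 = object$percent[2])
}

#' @export
logLik.dwell_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$order == 1L) 1 else 3,
            nobs = object$n, class = "logLik")
}

#' Dwell-time table for several strains/conditions
#'
#' Convenience wrapper producing one row per condition with the one- and
#' two-component dwell fits side by side (tau, tau1, tau1%, tau2, tau2%).
#'
#' @param duration_list named list of duration vectors (s).
#' @param t_min left truncation point (s).
#' @return data.frame with columns `condition`, `n`, `tau_s`, `tau1_s`,
#'   `tau1_pct`, `tau2_s`, `tau2_pct`.
#' @export
dwell_time_table <- function(duration_list, t_min = 0) {
  rows <- lapply(names(duration_list), function(nm) {
    d <- duration_list[[nm]]
    f1 <- fit_dwell_times(d, order = 1L, t_min = t_min)
    f2 <- fit_dwell_times(d, order = 2L, t_min = t_min)
    data.frame(condition = nm, n = length(d), tau_s = f1$tau,
               tau1_s = f2$tau[1], tau1_pct = f2$percent[1],
               tau2_s = f2$tau[2], tau2_pct = f2$percent[2])
  })
  do.call(rbind, rows)
}
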