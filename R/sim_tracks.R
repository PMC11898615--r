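#' Configuration for the Brownian-mixture track generator
#'
#' Defines a k-component Brownian mixture (k in 1..3) diffusing inside
#' spherocylindrical cells with reflecting walls, imaged with Gaussian
#' localization error and bleaching-limited (geometric) track lengths.
#' Defaults are the fitted diffusion constants of the FtsK confined,
#' slow-mobile and fast-mobile populations (0.017, 0.0509, 0.394 um^2/s) at a
#' 13 ms frame interval.
#'
#' @param k number of components (1-3).
#' @param D diffusion coefficients, um^2/s, one per component.
#' @param f population fractions, summing to 1.
#' @param dt frame interval in seconds.
#' @param loc_sd localization error SD per axis (um).
#' @param p_survive per-frame fluorophore survival probability in (0, 1);
#'   track length is 1 + Geometric(1 - p_survive).
#' @param n_tracks number of molecules to simulate.
#' @param septal_bias probability that a confined (lowest-D) molecule starts
#'   at the septum plane of a septum-bearing cell (at a pole otherwise).
#' @param seed integer RNG seed.
#' @return an object of class `sim_mixture_config`.
#' @export
sim_mixture_config <- function(k = 3L, D = c(0.017, 0.0509, 0.394),
                               f = c(1, 1, 1.04) / 3.04, dt = 0.013,
                               loc_sd = 0.02, p_survive = 0.85,
                               n_tracks = 1000L, septal_bias = 0.5, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3")
  if (length(D) != k || length(f) != k) stop("D and f must have length k")
  if (any(D < 0)) stop("all D must be >= 0")
  if (abs(sum(f) - 1) > 1e-9) stop("fractions f must sum to 1")
  if (any(f < 0)) stop("all f must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  if (loc_sd < 0) stop("loc_sd must be non-negative")
  if (p_survive <= 0 || p_survive >= 1) stop("p_survive must be in (0, 1)")
  if (septal_bias < 0 || septal_bias > 1) stop("septal_bias must be in [0, 1]")
  ord <- order(D)
  structure(list(k = k, D = D[ord], f = f[ord], dt = dt, loc_sd = loc_sd,
                 p_survive = p_survive, n_tracks = as.integer(n_tracks),
                 septal_bias = septal_bias, seed = as.integer(seed)),
            class = "sim_mixture_config")
}

#' Simulate single-molecule tracks inside cells
#'
#' Each molecule is assigned a diffusive population by the mixture fractions
#' and a host cell uniformly at random. True positions evolve by per-axis
#' Gaussian steps of variance `2 * D * dt`, specularly reflected at the cell
#' wall (re-checked and re-reflected up to 10 times, then clamped to the
#' boundary). Confined molecules (the lowest-D component) are, with
#' probability `septal_bias`, started at the septum plane of septum-bearing
#' cells, and at a pole otherwise; all other molecules start uniformly inside
#' their cell. Observed positions add independent Gaussian localization noise
#' of SD `loc_sd` per axis. Track lengths are `1 + Geometric(1 - p_survive)`
#' frames; tracks shorter than 2 frames are discarded.
#'
#' @param cells list of cell outlines from [simulate_cell_population()].
#' @param mix a [sim_mixture_config()].
#' @param stagger_start if `TRUE`, track start frames are staggered (tracks
#'   sorted by id, `tracks_per_frame` new tracks begin every frame) so that a
#'   rendered movie has a realistic low spot density; if `FALSE` every track
#'   starts at frame 0.
#' @param tracks_per_frame new tracks starting per frame when staggering.
#' @return a list with `tracks` (data.frame: `track_id`, `frame`, `x_um`,
#'   `y_um`, `cell_id`, `true_x_um`, `true_y_um`, `true_population`) and
#'   `truth` (list: `population` per track, `D`, `f`, `dt`, plus the per-cell
#'   septum flags).
#' @examples
#' cells <- simulate_cell_population(sim_cell_config(n_cells = 5, seed = 1))
#' sim <- simulate_tracks(cells, sim_mixture_config(n_tracks = 50, seed = 2))
#' head(sim$tracks)
#' @export
simulate_tracks <- function(cells, mix, stagger_start = FALSE,
                            tracks_per_frame = 2L) {
  if (!inherits(mix, "sim_mixture_config"))
    stop("mix must be a sim_mixture_config")
  if (length(cells) == 0) stop("cells must be non-empty")
  set.seed(mix$seed)
  n <- mix$n_tracks
  if (n == 0L) {
    return(list(tracks = empty_tracks_df(), truth = list(
      population = integer(0), D = mix$D, f = mix$f, dt = mix$dt)))
  }
  pop <- sample.int(mix$k, n, replace = TRUE, prob = mix$f)
  cell_idx <- sample.int(length(cells), n, replace = TRUE)
  len <- 1L + stats::rgeom(n, 1 - mix$p_survive)
  keep <- len >= 2L
  pop <- pop[keep]; cell_idx <- cell_idx[keep]; len <- len[keep]
  n <- length(pop)
  if (n == 0L) {
    return(list(tracks = empty_tracks_df(), truth = list(
      population = integer(0), D = mix$D, f = mix$f, dt = mix$dt)))
  }

  cl <- vapply(cells, `[[`, numeric(1), "length")[cell_idx]
  cw <- vapply(cells, `[[`, numeric(1), "width")[cell_idx]
  ctr_x <- vapply(cells, function(c) c$center[1], numeric(1))[cell_idx]
  ctr_y <- vapply(cells, function(c) c$center[2], numeric(1))[cell_idx]
  has_septum <- vapply(cells, `[[`, logical(1), "septum")[cell_idx]
  septum_x <- vapply(cells, function(c) {
    if (is.null(c$septum_x) || is.na(c$septum_x)) 0 else c$septum_x
  }, numeric(1))[cell_idx]

  # initial positions in each cell's local frame
  x <- numeric(n); y <- numeric(n)
  placed <- rep(FALSE, n)
  confined <- pop == 1L
  at_septum <- confined & (stats::runif(n) < mix$septal_bias) & has_septum
  at_pole <- confined & (stats::runif(n) < mix$septal_bias) & !has_septum
  # septal placement: on the septum plane, y uniform within the local width
  if (any(at_septum)) {
    h <- sc_halfwidth(septum_x[at_septum], cl[at_septum], cw[at_septum])
    x[at_septum] <- septum_x[at_septum] +
      stats::rnorm(sum(at_septum), 0, 0.02)
    y[at_septum] <- stats::runif(sum(at_septum), -h, h) * 0.9
    placed[at_septum] <- TRUE
  }
  if (any(at_pole)) {
    side <- sample(c(-1, 1), sum(at_pole), replace = TRUE)
    x[at_pole] <- side * (cl[at_pole] / 2 - cw[at_pole] / 4)
    y[at_pole] <- stats::rnorm(sum(at_pole), 0, cw[at_pole] / 8)
    placed[at_pole] <- TRUE
  }
  # everyone else: rejection sample uniform in the spherocylinder
  todo <- which(!placed)
  while (length(todo) > 0) {
    xx <- stats::runif(length(todo), -cl[todo] / 2, cl[todo] / 2)
    yy <- stats::runif(length(todo), -cw[todo] / 2, cw[todo] / 2)
    ok <- sc_contains(xx, yy, cl[todo], cw[todo])
    x[todo[ok]] <- xx[ok]; y[todo[ok]] <- yy[ok]
    todo <- todo[!ok]
  }
  res <- reflect_into_cells(x, y, cl, cw)
  x <- res$x; y <- res$y

  # evolve; store per-frame positions in a (max_len x n) matrix pair
  max_len <- max(len)
  step_sd <- sqrt(2 * mix$D[pop] * mix$dt)
  X <- matrix(NA_real_, max_len, n)
  Y <- matrix(NA_real_, max_len, n)
  X[1, ] <- x; Y[1, ] <- y
  for (t in 2L:max_len) {
    act <- which(len >= t)
    if (length(act) == 0) break
    nx <- X[t - 1L, act] + stats::rnorm(length(act), 0, step_sd[act])
    ny <- Y[t - 1L, act] + stats::rnorm(length(act), 0, step_sd[act])
    r <- reflect_into_cells(nx, ny, cl[act], cw[act])
    X[t, act] <- r$x; Y[t, act] <- r$y
  }

  frame0 <- if (stagger_start) {
    ((seq_len(n) - 1L) %/% as.integer(tracks_per_frame))
  } else rep(0L, n)

  idx <- rep(seq_len(n), len)
  frame_in <- sequence(len) - 1L
  flat <- cbind(frame_in + 1L, idx)  # matrix-index into X/Y
  true_x <- X[flat] + ctr_x[idx]
  true_y <- Y[flat] + ctr_y[idx]
  obs_x <- true_x
  obs_y <- true_y
  if (mix$loc_sd > 0) {
    obs_x <- obs_x + stats::rnorm(length(idx), 0, mix$loc_sd)
    obs_y <- obs_y + stats::rnorm(length(idx), 0, mix$loc_sd)
  }
  tracks <- data.frame(
    track_id = idx,
    frame = frame0[idx] + frame_in,
    x_um = obs_x, y_um = obs_y,
    cell_id = vapply(cells, `[[`, numeric(1), "cell_id")[cell_idx][idx],
    true_x_um = true_x, true_y_um = true_y,
    true_population = pop[idx])
  list(tracks = tracks,
       truth = list(population = pop, cell_index = cell_idx,
                    track_length = len, D = mix$D, f = mix$f, dt = mix$dt,
                    septum = vapply(cells, `[[`, logical(1), "septum")))
}

empty_tracks_df <- function() {
  data.frame(track_id = integer(0), frame = integer(0), x_um = numeric(0),
             y_um = numeric(0), cell_id = numeric(0), true_x_um = numeric(0),
             true_y_um = numeric(0), true_population = integer(0))
}

# Reflect points into their (per-point) spherocylinders: up to 10 specular
# reflections, then clamp.
reflect_into_cells <- function(x, y, L, w) {
  for (i in 1:10) {
    out <- !sc_contains(x, y, L, w)
    if (!any(out)) return(list(x = x, y = y))
    r <- sc_reflect_once(x[out], y[out], L[out], w[out])
    x[out] <- r$x; y[out] <- r$y
  }
  out <- !sc_contains(x, y, L, w)
  if (any(out)) {
    cl <- sc_clamp(x[out], y[out], L[out], w[out])
    x[out] <- cl$x; y[out] <- cl$y
  }
  list(x = x, y = y)
}
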