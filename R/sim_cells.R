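#' Configuration for the synthetic cell-population generator
#'
#' @param n_cells number of cells to generate.
#' @param length_mean,length_sd mean and SD of the cell length distribution
#'   (um); lengths are Normal, truncated below at `width`.
#' @param width cell width (um), also the cap diameter.
#' @param septum_prob probability that a cell carries a division septum.
#' @param seed integer RNG seed.
#' @return an object of class `sim_cell_config`.
#' @export
sim_cell_config <- function(n_cells = 100L, length_mean = 2.5, length_sd = 0.4,
                            width = 1, septum_prob = 0.5, seed = 1L) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 0 ||
      n_cells != round(n_cells))
    stop("n_cells must be a non-negative integer")
  if (width <= 0) stop("width must be positive")
  if (length_mean <= width) stop("length_mean must exceed width")
  if (length_sd < 0) stop("length_sd must be non-negative")
  if (septum_prob < 0 || septum_prob > 1) stop("septum_prob must be in [0, 1]")
  structure(list(n_cells = as.integer(n_cells), length_mean = length_mean,
                 length_sd = length_sd, width = width,
                 septum_prob = septum_prob, seed = as.integer(seed)),
            class = "sim_cell_config")
}

#' Simulate a population of spherocylindrical cells
#'
#' Draws cell lengths from a truncated Normal distribution and builds, for
#' each cell, a closed spherocylinder outline (rectangle of length
#' `L - width` capped by two half-circles of diameter `width`), a Bernoulli
#' septum flag, and pole coordinates. By default every cell is centered at
#' the origin with its long axis on x; `layout = "grid"` instead places the
#' cells on a non-overlapping grid (required for track-to-cell assignment and
#' image rendering, where outlines must not overlap).
#'
#' @param config a [sim_cell_config()].
#' @param layout `"origin"` (all cells centered at 0,0) or `"grid"`.
#' @param grid_margin spacing added around each cell in grid layout (um).
#' @return a list of cell outlines; each element has `cell_id`, `vertices`
#'   (polygon matrix, um), `poles` (2x2 matrix), `length`, `width`, `center`,
#'   `septum` (logical) and `septum_x` (axial septum position, um, relative
#'   to the cell center; `NA` when no septum).
#' @examples
#' cells <- simulate_cell_population(sim_cell_config(n_cells = 3, seed = 42))
#' cells[[1]]$length
#' @export
simulate_cell_population <- function(config, layout = c("origin", "grid"),
                                     grid_margin = 0.5) {
  if (!inherits(config, "sim_cell_config"))
    stop("config must be a sim_cell_config")
  layout <- match.arg(layout)
  if (config$n_cells == 0L) return(list())
  set.seed(config$seed)
  n <- config$n_cells
  lengths <- stats::rnorm(n, config$length_mean, config$length_sd)
  # truncate below at width by redrawing
  for (it in 1:100) {
    bad <- lengths < config$width
    if (!any(bad)) break
    lengths[bad] <- stats::rnorm(sum(bad), config$length_mean, config$length_sd)
  }
  lengths[lengths < config$width] <- config$width
  septum <- stats::runif(n) < config$septum_prob

  if (layout == "origin") {
    centers <- matrix(0, n, 2)
  } else {
    # one row of cells per 10, stacked vertically
    per_row <- 10L
    row <- (seq_len(n) - 1L) %/% per_row
    col <- (seq_len(n) - 1L) %% per_row
    max_l <- max(lengths)
    pitch_x <- max_l + grid_margin
    pitch_y <- config$width + grid_margin
    centers <- cbind(col * pitch_x + max_l / 2 + grid_margin,
                     row * pitch_y + config$width / 2 + grid_margin)
  }

  lapply(seq_len(n), function(i) {
    L <- lengths[i]; w <- config$width; ctr <- centers[i, ]
    list(cell_id = i,
         vertices = spherocylinder_polygon(L, w, ctr),
         poles = rbind(c(-L / 2, 0) + ctr, c(L / 2, 0) + ctr),
         length = L,
         width = w,
         center = ctr,
         septum = septum[i],
         septum_x = if (septum[i]) 0 else NA_real_)
  })
}
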