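# Standardized-cell projection and spatial localization statistics.

#' Project localizations into the standardized 3 x 1 um cell
#'
#' The along-axis coordinate is the signed projection onto the pole-to-pole
#' axis, rescaled so the poles map to u = +/- 1.5; the across-axis coordinate
#' is the perpendicular offset rescaled so the local half-width of the
#' outline maps to v = +/- 0.5. The orientation is chosen so that the pole
#' with fewer localizations maps to negative u (the "pole 1 = lesser pole"
#' convention used by the pole-resolved statistics).
#'
#' @param locs localizations of one cell (`x_um`, `y_um`).
#' @param outline that cell's outline (see [cell_outline()]).
#' @param orient apply the lesser-pole orientation convention (default TRUE).
#' @return data.frame with `u` (um in [-1.5, 1.5]), `v` (um in [-0.5, 0.5]),
#'   `s` (raw axial position, um from cell center, same sign as u), and
#'   `cell_id`.
#' @export
normalize_to_standard_cell <- function(locs, outline, orient = TRUE) {
  p1 <- outline$poles[1, ]; p2 <- outline$poles[2, ]
  axis <- p2 - p1
  L <- sqrt(sum(axis^2))
  if (L < 1e-9) stop("degenerate outline: poles coincide")
  ax <- axis / L
  ctr <- (p1 + p2) / 2
  dx <- locs$x_um - ctr[1]; dy <- locs$y_um - ctr[2]
  s <- dx * ax[1] + dy * ax[2]            # axial position from center
  d <- -dx * ax[2] + dy * ax[1]           # perpendicular offset
  s <- pmin(pmax(s, -L / 2), L / 2)
  # local half-width from the outline polygon
  h <- local_halfwidth(s, outline, ax, ctr)
  v <- ifelse(h > 1e-9, d / h, 0) * 0.5
  v <- pmin(pmax(v, -0.5), 0.5)
  u <- s * (3 / L) / 1  # poles at +/- L/2 -> +/- 1.5
  if (orient) {
    n_neg <- sum(u < 0); n_pos <- sum(u > 0)
    if (n_neg > n_pos) { u <- -u; s <- -s }
  }
  data.frame(u = u, v = v, s = s,
             cell_id = rep(outline$cell_id, length(u)))
}

# Half-width of the outline polygon at axial positions s (distance from
# center along unit axis `ax`): maximum |perpendicular| coordinate of the
# polygon boundary at that axial station, found by intersecting polygon edges
# with the perpendicular line.
local_halfwidth <- function(s, outline, ax, ctr) {
  V <- outline$vertices
  vx <- V[, 1] - ctr[1]; vy <- V[, 2] - ctr[2]
  a <- vx * ax[1] + vy * ax[2]     # axial coordinate of each vertex
  b <- -vx * ax[2] + vy * ax[1]    # perpendicular coordinate
  n <- length(a)
  a2 <- a[c(2:n, 1)]; b2 <- b[c(2:n, 1)]
  vapply(s, function(si) {
    lo <- pmin(a, a2); hi <- pmax(a, a2)
    hit <- which(lo - 1e-12 <= si & si <= hi + 1e-12)
    if (!length(hit)) return(0)
    t <- ifelse(abs(a2[hit] - a[hit]) > 1e-12,
                (si - a[hit]) / (a2[hit] - a[hit]), 0)
    bb <- b[hit] + t * (b2[hit] - b[hit])
    max(abs(bb))
  }, numeric(1))
}

#' Standardized-cell heatmap
#'
#' Bins standardized points into a grid of `pixel` x `pixel` um cells over
#' the 3 x 1 um standardized frame (30 x 10 at the default 0.1 um) and
#' normalizes counts to proportions (grid sums to 1).
#'
#' @param points data.frame with `u`, `v` from [normalize_to_standard_cell()]
#'   (rows from many cells may be concatenated).
#' @param pixel grid pixel size (um); default 0.1.
#' @return matrix of class `std_heatmap` (rows = v bins from -0.5, columns =
#'   u bins from -1.5), summing to 1.
#' @export
build_heatmap <- function(points, pixel = 0.1) {
  if (nrow(points) == 0) stop("no points; proportions undefined")
  nu <- round(3 / pixel); nv <- round(1 / pixel)
  ui <- pmin(pmax(floor((points$u + 1.5) / pixel) + 1L, 1L), nu)
  vi <- pmin(pmax(floor((points$v + 0.5) / pixel) + 1L, 1L), nv)
  g <- matrix(0, nv, nu)
  for (i in seq_along(ui)) g[vi[i], ui[i]] <- g[vi[i], ui[i]] + 1
  g <- g / sum(g)
  structure(g, pixel = pixel, class = "std_heatmap")
}

#' Difference between two standardized-cell heatmaps
#'
#' @param grid_a,grid_b heatmaps from [build_heatmap()] on the same grid.
#' @return elementwise `grid_a - grid_b`.
#' @export
diff_heatmap <- function(grid_a, grid_b) {
  if (!all(dim(grid_a) == dim(grid_b)))
    stop("heatmaps must share the same grid")
  d <- unclass(grid_a) - unclass(grid_b)
  structure(d, pixel = attr(grid_a, "pixel"), class = "std_heatmap")
}

#' @export
plot.std_heatmap <- function(x, ...) {
  graphics::image(t(unclass(x)), xlab = "u (standardized)",
                  ylab = "v (standardized)", ...)
  invisible(x)
}

#' Demograph of along-axis localization density
#'
#' One row per cell: along-axis localization counts binned at `binwidth` over
#' the cell's actual length (not the standardized frame), normalized so each
#' row has maximum 1, rows sorted by ascending cell length and centered at
#' midcell. Columns outside a cell's extent are NA.
#'
#' @param cell_points list, one element per cell, each a data.frame with `s`
#'   (axial position, um from the cell center) and an attribute-free numeric
#'   `length` entry; see [normalize_to_standard_cell()]. Alternatively a list
#'   of lists `list(s = ..., length = ...)`.
#' @param binwidth bin width (um); default 0.1.
#' @return matrix (cells x bins) of class `demograph`, with attribute
#'   `lengths` (sorted cell lengths).
#' @export
build_demograph <- function(cell_points, binwidth = 0.1) {
  if (length(cell_points) == 0) stop("need at least one cell")
  lens <- vapply(cell_points, function(cp) cp$length, numeric(1))
  ord <- order(lens)
  cell_points <- cell_points[ord]
  lens <- lens[ord]
  max_bins <- ceiling(max(lens) / binwidth)
  # ensure odd bin count so a center bin straddles midcell
  if (max_bins %% 2 == 0) max_bins <- max_bins + 1L
  m <- matrix(NA_real_, length(cell_points), max_bins)
  mid <- (max_bins + 1) / 2
  for (i in seq_along(cell_points)) {
    s <- cell_points[[i]]$s
    L <- lens[i]
    nb <- ceiling(L / binwidth)
    if (nb %% 2 == 0) nb <- nb + 1L
    # bins centered on midcell
    edges <- (seq_len(nb + 1) - 1 - nb / 2) * binwidth
    cnt <- graphics::hist(pmin(pmax(s, edges[1] + 1e-12), edges[nb + 1] - 1e-12),
                          breaks = edges, plot = FALSE)$counts
    if (max(cnt) > 0) cnt <- cnt / max(cnt)
    cols <- mid - (nb - 1) / 2 + seq_len(nb) - 1
    m[i, cols] <- cnt
  }
  structure(m, lengths = lens, binwidth = binwidth, class = "demograph")
}

#' @export
plot.demograph <- function(x, ...) {
  graphics::image(t(unclass(x)), xlab = "axial position",
                  ylab = "cells (sorted by length)", ...)
  invisible(x)
}

#' Midcell/polar localization statistics of one cell
#'
#' The midcell region is the central `region_frac` (default 20%) of the cell
#' length; each polar region is the terminal `region_frac`. Reports the
#' fraction of the cell's localizations in the midcell region
#' (`midcell_prop`), in the two polar regions combined (`polar_prop`), the
#' polar ratio (count at the lesser pole / count at the greater pole; 0 when
#' the greater pole has counts and the lesser none; NA if both poles are
#' empty), and the center of the most-populated along-axis bin
#' (`max_location`, binwidth 0.1 um, ties broken toward midcell).
#'
#' @param points standardized points of one cell ([normalize_to_standard_cell()]).
#' @param outline the cell's outline (for length and septum flag).
#' @param region_frac fraction of cell length per region (default 0.2).
#' @param binwidth along-axis binwidth for `max_location` (um).
#' @return one-row data.frame: `cell_id`, `length_um`, `septum`,
#'   `midcell_prop`, `polar_prop`, `polar_ratio`, `max_location_um`, `n`.
#' @export
compute_localization_stats <- function(points, outline, region_frac = 0.2,
                                       binwidth = 0.1) {
  n <- nrow(points)
  if (n == 0) stop("no points in cell")
  L <- outline$length
  s <- points$s
  half_region <- region_frac * L / 2
  mid <- abs(s) <= half_region
  pole_neg <- s <= -L / 2 + region_frac * L
  pole_pos <- s >= L / 2 - region_frac * L
  midcell_prop <- mean(mid)
  polar_prop <- mean(pole_neg | pole_pos)
  c_neg <- sum(pole_neg); c_pos <- sum(pole_pos)
  lesser <- min(c_neg, c_pos); greater <- max(c_neg, c_pos)
  polar_ratio <- if (greater == 0) NA_real_ else lesser / greater

  nb <- max(1L, ceiling(L / binwidth))
  edges <- seq(-L / 2, L / 2, length.out = nb + 1)
  cnt <- graphics::hist(pmin(pmax(s, -L / 2 + 1e-12), L / 2 - 1e-12),
                        breaks = edges, plot = FALSE)$counts
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  best <- which(cnt == max(cnt))
  best <- best[which.min(abs(centers[best]))]  # tie toward midcell
  data.frame(cell_id = outline$cell_id, length_um = L,
             septum = isTRUE(outline$septum),
             midcell_prop = midcell_prop, polar_prop = polar_prop,
             polar_ratio = polar_ratio, max_location_um = centers[best],
             n = n)
}
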