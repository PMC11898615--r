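# Spherocylinder geometry and polygon utilities.
#
# Cells are modelled as 2D spherocylinders: a rectangle of length L - w capped
# by two half-discs of diameter w, long axis on x, centered at the origin
# (optionally offset). All coordinates in micrometers.

#' Spherocylinder outline polygon
#'
#' Build the closed polygon of a spherocylinder of total length `length` and
#' width `width` centered at `center`, long axis along x.
#'
#' @param length total pole-to-pole length (um); must exceed `width`... equal
#'   is allowed (degenerates to a circle).
#' @param width cell width / cap diameter (um).
#' @param center numeric length-2, center of the cell (um).
#' @param n_arc number of vertices per polar cap.
#' @return a matrix with columns `x`, `y`; closed implicitly (last vertex
#'   connects to the first).
#' @examples
#' plot(spherocylinder_polygon(3, 1), type = "l", asp = 1)
#' @export
spherocylinder_polygon <- function(length, width, center = c(0, 0), n_arc = 24L) {
  stopifnot(length >= width, width > 0)
  r <- width / 2
  a <- (length - width) / 2  # half-length of the cylindrical part
  th_right <- seq(-pi / 2, pi / 2, length.out = n_arc)
  th_left <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  x <- c(a + r * cos(th_right), -a + r * cos(th_left))
  y <- c(r * sin(th_right), r * sin(th_left))
  cbind(x = x + center[1], y = y + center[2])
}

# Containment test for the analytic spherocylinder (local frame, centered at 0).
sc_contains <- function(x, y, length, width, tol = 1e-12) {
  r <- width / 2
  a <- (length - width) / 2
  dx <- pmax(abs(x) - a, 0)
  dx * dx + y * y <= r * r + tol
}

# Specular reflection of points (x, y) that lie outside the spherocylinder,
# across the nearest wall. In the cylindrical part the walls are the lines
# y = +/- r; in the caps they are the cap circles. Vectorized; a single pass
# (callers iterate and finally clamp).
sc_reflect_once <- function(x, y, length, width) {
  r <- rep_len(width / 2, base::length(x))
  a <- rep_len((length - width) / 2, base::length(x))
  in_cyl <- abs(x) <= a
  # cylindrical walls
  hi <- in_cyl & y > r
  lo <- in_cyl & y < -r
  y[hi] <- 2 * r[hi] - y[hi]
  y[lo] <- -2 * r[lo] - y[lo]
  # cap circles: reflect radially about the circle of radius r centered at
  # (sign(x) * a, 0)
  cap <- which(!in_cyl)
  if (base::length(cap)) {
    cx <- sign(x[cap]) * a[cap]
    dx <- x[cap] - cx
    dy <- y[cap]
    d <- sqrt(dx * dx + dy * dy)
    rc <- r[cap]
    out <- d > rc & d > 0
    if (any(out)) {
      idx <- cap[out]
      scale <- (2 * rc[out] - d[out]) / d[out]
      x[idx] <- cx[out] + dx[out] * scale
      y[idx] <- dy[out] * scale
    }
  }
  list(x = x, y = y)
}

# Clamp points onto the nearest interior point of the spherocylinder
# (used after the reflection budget is exhausted).
sc_clamp <- function(x, y, length, width) {
  r <- width / 2 * (1 - 1e-9)
  a <- (length - width) / 2
  cx <- pmin(pmax(x, -a), a)  # nearest axis point
  dx <- x - cx
  dy <- y
  d <- sqrt(dx * dx + dy * dy)
  bad <- d > r
  if (any(bad)) {
    s <- r / d[bad]
    x[bad] <- cx[bad] + dx[bad] * s
    y[bad] <- dy[bad] * s
  }
  list(x = x, y = y)
}

# Local half-width of the spherocylinder at axial position s (distance from
# center along the long axis). Zero exactly at the poles.
sc_halfwidth <- function(s, length, width) {
  r <- width / 2
  a <- (length - width) / 2
  ds <- pmax(abs(s) - a, 0)
  h2 <- r * r - ds * ds
  sqrt(pmax(h2, 0))
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Ray-casting with an explicit on-segment check so that points lying exactly
#' on a polygon edge or vertex are classified as inside.
#'
#' @param px,py point coordinates (vectors).
#' @param poly polygon vertex matrix (columns x, y), implicitly closed.
#' @param tol absolute tolerance for the on-boundary test.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  np <- length(px)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- pmax(ex * ex + ey * ey, .Machine$double.xmin)
  # edges x points matrices
  DX <- outer(-x1, px, "+")  # px[j] - x1[i]
  DY <- outer(-y1, py, "+")
  t <- (DX * ex + DY * ey) / len2
  t <- pmin(pmax(t, 0), 1)
  ddx <- DX - t * ex
  ddy <- DY - t * ey
  on_boundary <- colSums(ddx * ddx + ddy * ddy <= tol * tol) > 0
  # ray casting (crossing number), ray towards +x
  Y1 <- matrix(y1, n, np); Y2 <- matrix(y2, n, np)
  PY <- matrix(py, n, np, byrow = TRUE)
  PX <- matrix(px, n, np, byrow = TRUE)
  denom <- Y2 - Y1
  denom[denom == 0] <- .Machine$double.xmin
  xint <- matrix(x1, n, np) + (PY - Y1) / denom * ex
  cross <- ((Y1 > PY) != (Y2 > PY)) & (PX < xint)
  inside <- colSums(cross) %% 2L == 1L
  inside | on_boundary
}

# Do two convex-ish polygons intersect? Conservative test used to detect
# overlapping cell outlines: any vertex of one inside the other, or any pair
# of edges crossing.
polygons_overlap <- function(pa, pb) {
  if (any(point_in_polygon(pa[, 1], pa[, 2], pb, tol = 0))) return(TRUE)
  if (any(point_in_polygon(pb[, 1], pb[, 2], pa, tol = 0))) return(TRUE)
  FALSE
}
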