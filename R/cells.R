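# Cell outlines: construction, IO and track-to-cell assignment.

#' Construct a cell outline
#'
#' @param cell_id identifier.
#' @param vertices closed polygon vertex matrix (columns x, y; um).
#' @param poles 2x2 matrix, one pole per row (um). Computed as the two most
#'   distant vertices when `NULL`.
#' @param length pole-to-pole length (um); computed from poles when `NULL`.
#' @param septum logical septum flag.
#' @param septum_x axial septum position relative to the cell center (um).
#' @return a list of class-free outline structure compatible with
#'   [simulate_cell_population()] output.
#' @export
cell_outline <- function(cell_id, vertices, poles = NULL, length = NULL,
                         septum = FALSE, septum_x = NA_real_) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("vertices must be an n x 2 matrix with n >= 3")
  if (is.null(poles)) {
    d <- as.matrix(stats::dist(vertices))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    poles <- vertices[ij, , drop = FALSE]
  }
  poles <- as.matrix(poles)
  if (is.null(length)) length <- sqrt(sum((poles[2, ] - poles[1, ])^2))
  if (length <= 0) stop("cell length must be positive")
  list(cell_id = cell_id, vertices = vertices, poles = poles,
       length = length, width = NA_real_,
       center = colMeans(poles), septum = isTRUE(septum),
       septum_x = septum_x)
}

#' Assign tracks to cells
#'
#' A track is assigned to a cell if and only if every one of its
#' localizations lies inside (or exactly on the boundary of) that cell's
#' outline polygon; tracks matching no cell — including tracks spanning two
#' cells — remain unassigned (`cell_id = NA`) and are excluded from per-cell
#' analyses.
#'
#' @param tracks track data.frame (`track_id`, `frame`, `x_um`, `y_um`).
#' @param outlines list of cell outlines; must be non-overlapping.
#' @return `tracks` with a `cell_id` column (NA for unassigned tracks).
#' @export
assign_tracks_to_cells <- function(tracks, outlines) {
  if (length(outlines) > 1) {
    for (i in seq_along(outlines)[-1]) {
      for (j in seq_len(i - 1)) {
        if (polygons_overlap(outlines[[i]]$vertices, outlines[[j]]$vertices))
          stop(sprintf("overlapping cell outlines: %s and %s",
                       outlines[[j]]$cell_id, outlines[[i]]$cell_id))
      }
    }
  }
  tracks$cell_id <- NA
  if (nrow(tracks) == 0) return(tracks)
  rows_by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  # bounding boxes for a cheap pre-filter
  bb <- t(vapply(outlines, function(o) {
    c(min(o$vertices[, 1]), max(o$vertices[, 1]),
      min(o$vertices[, 2]), max(o$vertices[, 2]))
  }, numeric(4)))
  tol <- 1e-9
  cell_id_col <- tracks$cell_id
  for (rows in rows_by_track) {
    x <- tracks$x_um[rows]; y <- tracks$y_um[rows]
    xr <- range(x); yr <- range(y)
    cand <- which(xr[1] >= bb[, 1] - tol & xr[2] <= bb[, 2] + tol &
                  yr[1] >= bb[, 3] - tol & yr[2] <= bb[, 4] + tol)
    for (k in cand) {
      if (all(point_in_polygon(x, y, outlines[[k]]$vertices))) {
        cell_id_col[rows] <- outlines[[k]]$cell_id
        break
      }
    }
  }
  tracks$cell_id <- cell_id_col
  tracks
}

#' Write / read cell outlines as JSON
#'
#' Outlines are serialized with fields `cell_id`, `vertices_um`, `length_um`,
#' `septum` and `septum_x_um`.
#'
#' @param outlines list of cell outlines.
#' @param path file path.
#' @return `read_outlines_json` returns a list of outlines.
#' @export
write_outlines_json <- function(outlines, path) {
  payload <- lapply(outlines, function(o) {
    list(cell_id = o$cell_id,
         vertices_um = unname(o$vertices),
         poles_um = unname(o$poles),
         length_um = o$length,
         septum = isTRUE(o$septum),
         septum_x_um = if (is.null(o$septum_x) || is.na(o$septum_x)) NULL
                       else o$septum_x)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_outlines_json
#' @export
read_outlines_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  as_mat <- function(v) {
    if (is.matrix(v)) v else do.call(rbind, lapply(v, unlist))
  }
  lapply(payload, function(o) {
    sx <- if (is.null(o$septum_x_um)) NA_real_ else o$septum_x_um
    cell_outline(o$cell_id, as_mat(o$vertices_um),
                 poles = if (!is.null(o$poles_um)) as_mat(o$poles_um)
                         else NULL,
                 length = o$length_um, septum = o$septum, septum_x = sx)
  })
}
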