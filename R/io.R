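# Plain-text and TIFF IO for tracks, localizations, profiles and stacks.

#' Write / read tracks as CSV
#'
#' Columns: `track_id`, `frame`, `x_um`, `y_um`, plus `cell_id` and
#' `true_population` when present.
#'
#' @param tracks track data.frame.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track CSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write / read localizations as CSV
#'
#' Columns: `frame`, `x_um`, `y_um`, `intensity`, `snr`.
#'
#' @param locs localization data.frame.
#' @param path file path.
#' @export
write_localizations_csv <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("localization CSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write / read a cell profile as CSV
#'
#' Columns: `position_um`, `phase`, `membrane`, `dna`.
#'
#' @param profile a `cell_profile`.
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(position_um = profile$position,
                              phase = profile$phase,
                              membrane = profile$membrane,
                              dna = profile$dna),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("position_um", "membrane")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV missing columns: ", paste(miss, collapse = ", "))
  structure(list(position = df$position_um,
                 phase = df$phase %||% rep(0, nrow(df)),
                 membrane = df$membrane,
                 dna = df$dna %||% rep(0, nrow(df)),
                 truth = NULL),
            class = "cell_profile")
}

#' Write / read an image stack as multi-frame TIFF
#'
#' Frames are written as 32-bit float TIFF pages; `pixel_size` and `origin`
#' are restored on read only if supplied.
#'
#' @param stack an `image_stack` array.
#' @param path file path.
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(stack, 1)
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixel_size,origin image geometry to attach to the returned stack.
#' @export
read_stack_tiff <- function(path, pixel_size = NULL, origin = c(0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  st <- simplify2array(pages)
  if (length(dim(st)) == 2) dim(st) <- c(dim(st), 1L)
  structure(st, pixel_size = pixel_size, origin = origin,
            class = "image_stack")
}

#' Write a diffusion mixture fit report as JSON
#'
#' @param fit an `sqd_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(k = fit$k, D_um2_s = fit$D, f = fit$f, se_D = fit$se_D,
         se_f = fit$se_f, rss = fit$rss, n_jumps = fit$n_jumps,
         dt_s = fit$dt, sigma_um = fit$sigma),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
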