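#' Render tracks into a synthetic SMLM image stack
#'
#' Each localization is rendered as an integrated 2D Gaussian point-spread
#' function (the Gaussian CDF integrated over each pixel), scaled to
#' `peak_photons` expected photons in total, on a constant `background`;
#' Poisson noise is applied to signal + background. The number of frames is
#' `max(frame) + 1`.
#'
#' Image coordinates: the pixel in column `i`, row `j` (1-based) has its
#' center at `origin + (i - 0.5, j - 0.5) * pixel_size` in um; `origin` is
#' the um-coordinate of the image's lower-left corner and defaults to a
#' margin below the minimum track coordinate.
#'
#' @param tracks track data.frame (`frame`, `x_um`, `y_um`), e.g. from
#'   [simulate_tracks()]. May be empty only if `dim_px` is given.
#' @param psf_sigma PSF standard deviation (um).
#' @param background expected background photons per pixel per frame.
#' @param peak_photons total expected photons per emitter per frame.
#' @param pixel_size pixel pitch (um); default 0.0968 um.
#' @param seed integer RNG seed for the Poisson noise; `NULL` renders the
#'   noiseless expectation image.
#' @param origin um-coordinates of the image corner; computed from the track
#'   extent when `NULL`.
#' @param dim_px integer `c(nx, ny)`; computed from the track extent when
#'   `NULL`.
#' @return 3D array `[ny, nx, n_frames]` of class `image_stack` with
#'   attributes `pixel_size` and `origin`.
#' @export
simulate_image_stack <- function(tracks, psf_sigma = 0.13, background = 2,
                                 peak_photons = 400, pixel_size = 0.0968,
                                 seed = 1L, origin = NULL, dim_px = NULL) {
  if (psf_sigma <= 0) stop("psf_sigma must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (background < 0 || peak_photons < 0)
    stop("photon counts must be non-negative")
  empty <- is.null(tracks) || nrow(tracks) == 0
  if (empty && (is.null(dim_px)))
    stop("dim_px required when tracks are empty")
  margin <- 4 * psf_sigma
  if (is.null(origin)) {
    origin <- if (empty) c(0, 0) else
      c(min(tracks$x_um) - margin, min(tracks$y_um) - margin)
  }
  if (is.null(dim_px)) {
    dim_px <- c(ceiling((max(tracks$x_um) + margin - origin[1]) / pixel_size),
                ceiling((max(tracks$y_um) + margin - origin[2]) / pixel_size))
  }
  nx <- as.integer(dim_px[1]); ny <- as.integer(dim_px[2])
  n_frames <- if (empty) 1L else as.integer(max(tracks$frame) + 1L)
  stack <- array(background, dim = c(ny, nx, n_frames))

  if (!empty) {
    # render each emitter only within +/- 5 sigma of its position
    wpx <- ceiling(5 * psf_sigma / pixel_size)
    for (i in seq_len(nrow(tracks))) {
      cx <- (tracks$x_um[i] - origin[1]) / pixel_size
      cy <- (tracks$y_um[i] - origin[2]) / pixel_size
      ix <- max(1L, floor(cx) - wpx):min(nx, ceiling(cx) + wpx)
      iy <- max(1L, floor(cy) - wpx):min(ny, ceiling(cy) + wpx)
      if (!length(ix) || !length(iy)) next
      xe <- origin[1] + c(ix[1] - 1L, ix) * pixel_size
      ye <- origin[2] + c(iy[1] - 1L, iy) * pixel_size
      wx <- diff(stats::pnorm(xe, tracks$x_um[i], psf_sigma))
      wy <- diff(stats::pnorm(ye, tracks$y_um[i], psf_sigma))
      fr <- tracks$frame[i] + 1L
      stack[iy, ix, fr] <- stack[iy, ix, fr] + peak_photons * (wy %o% wx)
    }
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    stack[] <- stats::rpois(length(stack), stack)
  }
  structure(stack, pixel_size = pixel_size, origin = origin,
            class = "image_stack")
}
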