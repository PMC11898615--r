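#' Detect diffraction-limited spots in an image stack
#'
#' Per frame: the image is filtered with a (negated) Laplacian-of-Gaussian
#' kernel of scale `sigma = diameter / (2 * sqrt(2))` (converted to pixels),
#' local maxima of the response are refined to sub-pixel precision by a 2D
#' quadratic fit on their 3x3 neighborhood, and each candidate's
#' signal-to-noise ratio is estimated on the raw frame as
#' `(peak - local median) / (1.4826 * local MAD)`; spots with SNR below
#' `snr_min` are discarded.
#'
#' @param stack an `image_stack` array (`[ny, nx, n_frames]`) or a plain 3D
#'   array / list of matrices.
#' @param diameter estimated spot diameter (um); default 0.5.
#' @param snr_min minimum signal-to-noise ratio; default 5.
#' @param pixel_size pixel pitch (um); taken from the stack attribute when
#'   present.
#' @return data.frame of localizations: `frame` (0-based), `x_um`, `y_um`,
#'   `intensity` (raw peak value), `snr`.
#' @examples
#' trk <- data.frame(frame = 0L, x_um = 1.1, y_um = 0.9)
#' st <- simulate_image_stack(trk, background = 0, seed = NULL,
#'                            origin = c(0, 0), dim_px = c(22, 20))
#' detect_spots(st, snr_min = 3)
#' @export
detect_spots <- function(stack, diameter = 0.5, snr_min = 5,
                         pixel_size = NULL) {
  if (is.list(stack) && !is.array(stack))
    stack <- simplify2array(stack)
  if (length(stack) == 0 || is.null(dim(stack)))
    stop("stack must be a non-empty image stack")
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1L)
  if (diameter <= 0) stop("diameter must be positive")
  if (is.null(pixel_size)) pixel_size <- attr(stack, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size required")
  origin <- attr(stack, "origin")
  if (is.null(origin)) origin <- c(0, 0)

  sigma_px <- diameter / (2 * sqrt(2)) / pixel_size
  kern <- log_kernel_1d(sigma_px)
  h <- kern$h
  win <- max(h, 3L)  # half-width of the SNR estimation window

  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    resp <- cpp_log_response(img, kern$g, kern$d2)
    cand <- local_maxima(resp, exclude = max(h, win))
    if (nrow(cand) == 0) next
    # cheap frame-level pre-filter: a spot passing the local-SNR gate must
    # also stand out of the global frame noise; this prunes noise maxima
    # before the expensive local median/MAD estimate
    fmed <- stats::median(img)
    fmad <- stats::median(abs(img - fmed))
    if (fmad > 0) {
      pre <- img[cand] - fmed >= 0.5 * snr_min * 1.4826 * fmad
      cand <- cand[pre, , drop = FALSE]
      if (nrow(cand) == 0) next
    }
    keep <- logical(nrow(cand))
    xs <- ys <- inten <- snr <- numeric(nrow(cand))
    lstats <- cpp_local_stats(img, cand[, 1], cand[, 2], as.integer(win))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      med <- lstats[i, 1]; madv <- lstats[i, 2]
      peak <- img[r, c]
      s <- if (madv > 0) (peak - med) / (1.4826 * madv) else
        if (peak > med) Inf else 0
      if (s < snr_min) next
      off <- quad_refine(resp[(r - 1):(r + 1), (c - 1):(c + 1)])
      ref <- cpp_centroid_refine(img, r + off[1], c + off[2], sigma_px, med,
                                 5L)
      keep[i] <- TRUE
      xs[i] <- ref[2] - 0.5
      ys[i] <- ref[1] - 0.5
      inten[i] <- peak
      snr[i] <- s
    }
    if (any(keep)) {
      out[[f]] <- data.frame(frame = f - 1L,
                             x_um = origin[1] + xs[keep] * pixel_size,
                             y_um = origin[2] + ys[keep] * pixel_size,
                             intensity = inten[keep], snr = snr[keep])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  res
}

# Negated Laplacian-of-Gaussian filter components. The LoG kernel is the
# sum of two separable terms, -(Gxx(x) g(y) + g(x) Gyy(y)); each 1D
# second-derivative component is recentered to zero sum so the composite
# filter responds with exactly zero to constant images.
log_kernel_1d <- function(sigma) {
  h <- max(2L, as.integer(ceiling(3 * sigma)))
  t <- seq(-h, h)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  d2 <- -(t^2 - sigma^2) / sigma^4 * exp(-t^2 / (2 * sigma^2))
  d2 <- d2 - mean(d2)
  list(g = g, d2 = d2, h = h)
}

# full 2D kernel (used for documentation/tests of the filter itself)
log_kernel <- function(sigma) {
  k1 <- log_kernel_1d(sigma)
  outer(k1$d2, k1$g) + outer(k1$g, k1$d2)
}

# (the separable response itself is computed in compiled code; see
# src/detect_core.cpp)

# Strict local maxima of a matrix (8-neighborhood), excluding a border.
local_maxima <- function(m, exclude = 1L) {
  ny <- nrow(m); nx <- ncol(m)
  e <- max(1L, as.integer(exclude))
  if (ny <= 2 * e || nx <= 2 * e) return(cbind(row = integer(0), col = integer(0)))
  ri <- (e + 1L):(ny - e); ci <- (e + 1L):(nx - e)
  c0 <- m[ri, ci, drop = FALSE]
  ok <- c0 > m[ri - 1L, ci, drop = FALSE] & c0 > m[ri + 1L, ci, drop = FALSE] &
        c0 > m[ri, ci - 1L, drop = FALSE] & c0 > m[ri, ci + 1L, drop = FALSE] &
        c0 > m[ri - 1L, ci - 1L, drop = FALSE] & c0 > m[ri - 1L, ci + 1L, drop = FALSE] &
        c0 > m[ri + 1L, ci - 1L, drop = FALSE] & c0 > m[ri + 1L, ci + 1L, drop = FALSE]
  w <- which(ok, arr.ind = TRUE)
  cbind(row = w[, 1] + e, col = w[, 2] + e)
}

# Sub-pixel positions come from a quadratic fit on the filter response
# followed by iterative Gaussian-weighted centroid refinement on the raw
# image (compiled; src/detect_core.cpp). The weighted centroid shrinks the
# measured offset toward the window center, but re-centering the window on
# the running estimate is a contraction whose fixed point is the true
# center, so a few iterations converge without a shrinkage correction.

# Sub-pixel offset (dy, dx) from a least-squares 2D quadratic fit on a 3x3
# patch; offsets clamped to [-1, 1].
quad_refine <- function(p) {
  x <- matrix(c(-1, 0, 1), 3, 3, byrow = TRUE)  # column offset
  y <- t(x)                                      # row offset
  b <- sum(x * p) / 6
  c_ <- sum(y * p) / 6
  d <- sum((x^2 - 2 / 3) * p) / 2
  e <- sum((y^2 - 2 / 3) * p) / 2
  g <- sum(x * y * p) / 4
  H <- matrix(c(2 * d, g, g, 2 * e), 2, 2)
  det <- H[1, 1] * H[2, 2] - H[1, 2] * H[2, 1]
  if (!is.finite(det) || abs(det) < 1e-12) return(c(0, 0))
  off <- -solve(H, c(b, c_))  # (dx, dy)
  off <- pmin(pmax(off, -1), 1)
  c(off[2], off[1])  # return (dy, dx)
}
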