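#' First-order plane background subtraction
#'
#' Fits a least-squares plane `a*col + b*row + c` to the frame (or to its
#' background pixels if a feature mask is supplied) and subtracts it, so
#' that the background mean is ~0 and residual scanner tilt is removed.
#'
#' @param frame numeric matrix of heights (nm).
#' @param feature_mask optional logical matrix, `TRUE` where pixels belong
#'   to features and must be excluded from the background fit.
#' @return Levelled frame, same shape.
#' @export
plane_level <- function(frame, feature_mask = NULL) {
  if (!is.matrix(frame) || nrow(frame) < 2L || ncol(frame) < 2L) {
    stop("fit error: plane_level needs a matrix with >= 2 rows and columns",
         call. = FALSE)
  }
  rows <- matrix(seq_len(nrow(frame)) - 1, nrow(frame), ncol(frame))
  cols <- matrix(rep(seq_len(ncol(frame)) - 1, each = nrow(frame)),
                 nrow(frame), ncol(frame))
  bg <- if (is.null(feature_mask)) rep(TRUE, length(frame)) else !feature_mask
  X <- cbind(1, cols[bg], rows[bg])
  if (qr(X)$rank < 3L) {
    stop("fit error: degenerate frame, background pixels are collinear",
         call. = FALSE)
  }
  beta <- qr.coef(qr(X), frame[bg])
  frame - (beta[1] + beta[2] * cols + beta[3] * rows)
}

#' Default background mask: features above median + 3 MAD
#'
#' Automatic stand-in for the manual "bilayer as reference" selection: the
#' bilayer occupies most of the field at near-constant height, so pixels
#' above `median + 3 * mad` are flagged as features.
#'
#' @param frame numeric matrix of heights (nm).
#' @param k threshold in MAD units (default 3).
#' @return Logical matrix, `TRUE` where pixels are features.
#' @export
feature_mask_mad <- function(frame, k = 3) {
  med <- stats::median(frame)
  s <- stats::mad(frame)
  if (s == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  frame > med + k * s
}

#' Line-by-line flattening against the bilayer background
#'
#' Subtracts, from each scan line (matrix row), the median of its
#' background (unmasked) pixels, referencing every line to the lipid
#' bilayer. A line whose pixels are all masked carries the previous line's
#' offset (the frame background median for a fully-masked first line).
#'
#' @inheritParams plane_level
#' @return Flattened frame, same shape.
#' @export
line_flatten <- function(frame, feature_mask = NULL) {
  if (!is.matrix(frame)) stop("line_flatten needs a matrix", call. = FALSE)
  bg <- if (is.null(feature_mask)) {
    matrix(TRUE, nrow(frame), ncol(frame))
  } else {
    !feature_mask
  }
  prev <- stats::median(frame[bg])
  if (!is.finite(prev)) prev <- stats::median(frame)
  out <- frame
  for (i in seq_len(nrow(frame))) {
    line_bg <- frame[i, bg[i, ]]
    off <- if (length(line_bg)) stats::median(line_bg) else prev
    out[i, ] <- frame[i, ] - off
    prev <- off
  }
  out
}

# Separable Gaussian convolution of one row/column direction with reflect
# padding; kernel normalized to unit sum so constants pass unchanged.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_reflect_1d <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[pmin(n, pmax(1L, r:1 + 1L))],  # reflect about first sample
           x,
           x[pmin(n, pmax(1L, n - (1:r)))])
  stats::filter(pad, kernel, sides = 2)[(r + 1L):(r + n)]
}

#' Gaussian smoothing of a height map
#'
#' Convolution with an isotropic Gaussian kernel specified by its
#' full-width at half-maximum (default 2 px, i.e. 4 nm at 2 nm/px), using
#' reflect padding so edges are not dimmed. Constant inputs are preserved
#' exactly.
#'
#' @param frame numeric matrix of heights (nm).
#' @param fwhm_px kernel full-width at half-maximum, pixels;
#'   `sigma = fwhm / (2 sqrt(2 log 2))`.
#' @return Smoothed frame, same shape.
#' @export
gaussian_smooth <- function(frame, fwhm_px = 2) {
  if (fwhm_px <= 0) stop("fwhm_px must be > 0", call. = FALSE)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  k <- gaussian_kernel_1d(sigma)
  out <- apply(frame, 2L, convolve_reflect_1d, kernel = k)   # down columns
  t(apply(out, 1L, convolve_reflect_1d, kernel = k))         # along rows
}

#' Condition every frame of a movie
#'
#' Applies, in the standard order, first-order plane subtraction,
#' line-by-line flattening (with an automatic median + 3 MAD feature mask
#' per frame), and Gaussian smoothing. Metadata are preserved.
#'
#' @param movie a [movie_stack()].
#' @param fwhm_px Gaussian FWHM in pixels; `NULL` or 0 skips smoothing.
#' @param mask_k MAD threshold for the automatic feature mask.
#' @param flatten_lines apply the line-by-line flattening step?
#' @return A preprocessed [movie_stack()].
#' @export
preprocess_movie <- function(movie, fwhm_px = 2, mask_k = 3,
                             flatten_lines = TRUE) {
  stopifnot(inherits(movie, "movie_stack"))
  frames <- lapply(movie$frames, function(fr) {
    mask <- feature_mask_mad(fr, k = mask_k)
    fr <- plane_level(fr, feature_mask = mask)
    if (flatten_lines) {
      mask <- feature_mask_mad(fr, k = mask_k)
      fr <- line_flatten(fr, feature_mask = mask)
    }
    if (!is.null(fwhm_px) && fwhm_px > 0) fr <- gaussian_smooth(fr, fwhm_px)
    fr
  })
  movie_stack(frames, pixel_size = movie$pixel_size,
              frame_interval = movie$frame_interval,
              time_offset = movie$time_offset)
}
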