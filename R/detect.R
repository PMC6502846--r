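#' Zero-normalized cross-correlation map of a template over a frame
#'
#' Pearson-type normalized cross-correlation: at each valid centre position
#' the template (zero-mean, unit-energy) is correlated with the
#' equally-normalized image window, making the detection threshold
#' contrast-invariant. Computed with an FFT for the cross term and integral
#' images for the window sums. Positions within half a template width of
#' the frame border are `NA` (edge exclusion); windows with (near-)zero
#' variance score 0.
#'
#' @param frame numeric matrix (heights, nm).
#' @param template odd-sided numeric matrix, smaller than the frame.
#' @return Matrix of scores in \[-1, 1\], same shape as `frame`.
#' @export
zncc_map <- function(frame, template) {
  mr <- nrow(template); mc <- ncol(template)
  H <- nrow(frame); W <- ncol(frame)
  if (mr %% 2 == 0 || mc %% 2 == 0) {
    stop("template must have odd side lengths", call. = FALSE)
  }
  if (mr > H || mc > W) {
    stop("template larger than frame", call. = FALSE)
  }
  hr <- (mr - 1L) %/% 2L; hc <- (mc - 1L) %/% 2L
  t0 <- template - mean(template)
  den_t <- sqrt(sum(t0^2))
  if (den_t == 0) stop("template is constant", call. = FALSE)

  # circular cross-correlation via FFT; entry (i, j) aligns template origin
  # with frame pixel (i, j)
  tpad <- matrix(0, H, W)
  tpad[seq_len(mr), seq_len(mc)] <- t0
  cross <- Re(stats::fft(stats::fft(frame) * Conj(stats::fft(tpad)),
                         inverse = TRUE)) / (H * W)

  # window sums of frame and frame^2 via integral images
  ii1 <- rbind(0, cbind(0, t(apply(apply(frame, 2, cumsum), 1, cumsum))))
  ii2 <- rbind(0, cbind(0, t(apply(apply(frame^2, 2, cumsum), 1, cumsum))))
  rc <- (hr + 1L):(H - hr)   # valid centre rows
  cc <- (hc + 1L):(W - hc)   # valid centre cols
  win_sum <- function(ii) {
    ii[rc + hr + 1L, cc + hc + 1L, drop = FALSE] -
      ii[rc - hr, cc + hc + 1L, drop = FALSE] -
      ii[rc + hr + 1L, cc - hc, drop = FALSE] +
      ii[rc - hr, cc - hc, drop = FALSE]
  }
  s1 <- win_sum(ii1)
  s2 <- win_sum(ii2)
  npix <- mr * mc
  var_w <- pmax(s2 - s1^2 / npix, 0)

  num <- cross[rc - hr, cc - hc, drop = FALSE]
  den <- den_t * sqrt(var_w)
  score <- matrix(0, length(rc), length(cc))
  ok <- den > 1e-9 * den_t   # window sd above ~1e-9: defined correlation
  score[ok] <- num[ok] / den[ok]
  score <- pmin(pmax(score, -1), 1)

  out <- matrix(NA_real_, H, W)
  out[rc, cc] <- score
  out
}

#' Detect pores in one frame by template matching
#'
#' Reports local correlation maxima at or above `threshold` after greedy
#' non-maximum suppression with an exclusion radius of half the template
#' width; ties at equal score are broken by raster order. Coordinates use
#' the 0-based pixel-centre convention.
#'
#' @param frame numeric matrix (preprocessed heights, nm).
#' @param template matching template, e.g. from [make_template()].
#' @param threshold normalized correlation threshold in (0, 1\]; default
#'   0.6.
#' @param frame_index frame index recorded in the output (0-based).
#' @return data.frame with columns `frame_index`, `row`, `col`, `score`.
#' @export
detect_pores <- function(frame, template, threshold = 0.6,
                         frame_index = 0L) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  score <- zncc_map(frame, template)
  cand <- which(!is.na(score) & score >= threshold, arr.ind = TRUE)
  empty <- data.frame(frame_index = integer(), row = integer(),
                      col = integer(), score = numeric())
  if (nrow(cand) == 0L) return(empty)
  sc <- score[cand]
  # order: score desc, then raster order (row, then col; 0-based)
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  excl <- max(nrow(template), ncol(template)) / 2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L || all((cand[keep, 1] - cand[i, 1])^2 +
                       (cand[keep, 2] - cand[i, 2])^2 > excl^2)) {
      keep[i] <- TRUE
    }
  }
  out <- data.frame(frame_index = as.integer(frame_index),
                    row = cand[keep, 1] - 1L,
                    col = cand[keep, 2] - 1L,
                    score = sc[keep])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Detect pores in every frame of a movie
#'
#' @param movie a preprocessed [movie_stack()].
#' @inheritParams detect_pores
#' @return data.frame of detections over all frames (columns as in
#'   [detect_pores()]).
#' @export
detect_movie <- function(movie, template, threshold = 0.6) {
  stopifnot(inherits(movie, "movie_stack"))
  if (length(movie$frames) == 0L) {
    stop("detect: movie has no frames", call. = FALSE)
  }
  dets <- lapply(seq_along(movie$frames), function(k) {
    detect_pores(movie$frames[[k]], template, threshold,
                 frame_index = k - 1L)
  })
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out
}

#' Per-frame pore counts
#'
#' The number of template-matched features in each frame; with slow
#' initiation and fast completion, this appearance curve follows
#' \eqn{A (1 - exp(-t/\tau_{init}))}.
#'
#' @inheritParams detect_movie
#' @param detections optional precomputed result of [detect_movie()].
#' @return integer vector, one count per frame.
#' @export
count_pores <- function(movie, template, threshold = 0.6,
                        detections = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (is.null(detections)) {
    detections <- detect_movie(movie, template, threshold)
  }
  counts <- tabulate(detections$frame_index + 1L,
                     nbins = length(movie$frames))
  as.integer(counts)
}
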