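#' Link per-frame detections into pore tracks
#'
#' Greedy frame-order nearest-neighbour linking: a detection joins an
#' existing track iff it lies within `max_link_dist_px` of the track's last
#' position and within `max_gap_frames` frames of its last detection
#' (gap closing); otherwise it starts a new track. Candidate links are
#' resolved by smallest distance first, ties by raster order, and each
#' detection belongs to exactly one track. The assignment is deterministic.
#'
#' @param detections data.frame from [detect_movie()] (columns
#'   `frame_index`, `row`, `col`, `score`), sorted or not.
#' @param max_link_dist_px maximum linking distance, pixels (default 30).
#' @param max_gap_frames maximum gap closing, frames (default 3): a track
#'   missing for up to this many frames can still be continued.
#' @return Object of class `pore_tracks`: a list with `detections` (the
#'   input plus a `track_id` column) and `tracks` (per-track summary
#'   data.frame: `track_id`, `birth_frame`, `last_frame`, `n_detections`,
#'   `row`, `col` (median position, px), `pre_existing`).
#' @export
link_tracks <- function(detections, max_link_dist_px = 30,
                        max_gap_frames = 3) {
  det <- detections[order(detections$frame_index, detections$row,
                          detections$col), , drop = FALSE]
  det$track_id <- rep(NA_integer_, nrow(det))
  last_pos <- matrix(numeric(0), ncol = 2)   # per-track last (row, col)
  last_frame <- integer(0)
  n_tracks <- 0L

  for (f in sort(unique(det$frame_index))) {
    idx <- which(det$frame_index == f)
    open <- which(last_frame >= f - max_gap_frames - 1L & last_frame < f)
    if (length(open) && length(idx)) {
      d2 <- outer(det$row[idx], last_pos[open, 1], `-`)^2 +
        outer(det$col[idx], last_pos[open, 2], `-`)^2
      cand <- which(d2 <= max_link_dist_px^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d2[cand], cand[, 1])   # distance, then raster order
        used_det <- logical(length(idx))
        used_trk <- logical(length(open))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_det[i] && !used_trk[j]) {
            used_det[i] <- TRUE
            used_trk[j] <- TRUE
            tid <- open[j]
            det$track_id[idx[i]] <- tid
            last_pos[tid, ] <- c(det$row[idx[i]], det$col[idx[i]])
            last_frame[tid] <- f
          }
        }
      }
    }
    for (i in idx[is.na(det$track_id[idx])]) {   # births
      n_tracks <- n_tracks + 1L
      det$track_id[i] <- n_tracks
      last_pos <- rbind(last_pos, c(det$row[i], det$col[i]))
      last_frame <- c(last_frame, f)
    }
  }

  summaries <- if (n_tracks > 0L) {
    do.call(rbind, lapply(seq_len(n_tracks), function(tid) {
      d <- det[det$track_id == tid, , drop = FALSE]
      data.frame(track_id = tid,
                 birth_frame = min(d$frame_index),
                 last_frame = max(d$frame_index),
                 n_detections = nrow(d),
                 row = stats::median(d$row),
                 col = stats::median(d$col),
                 pre_existing = min(d$frame_index) == 0L)
    }))
  } else {
    data.frame(track_id = integer(), birth_frame = integer(),
               last_frame = integer(), n_detections = integer(),
               row = numeric(), col = numeric(), pre_existing = logical())
  }
  structure(list(detections = det, tracks = summaries),
            class = "pore_tracks")
}

#' Discard likely false-positive tracks
#'
#' Automatic stand-in for manual track curation: tracks with fewer than
#' `min_detections` detections are flagged as rejected (noise-induced
#' spurious matches rarely persist); nothing is silently dropped.
#'
#' @param tracks a `pore_tracks` object from [link_tracks()].
#' @param min_detections minimum detections for a track to be kept
#'   (default 3).
#' @return The `pore_tracks` object with a logical `curated` column added
#'   to `$tracks`.
#' @export
curate_tracks <- function(tracks, min_detections = 3L) {
  stopifnot(inherits(tracks, "pore_tracks"))
  tracks$tracks$curated <- tracks$tracks$n_detections >= min_detections
  tracks
}

#' Crop a per-pore sub-movie around a track
#'
#' Extracts a square region of half-width `radius_nm` centred on the
#' track's median position, from `pre_frames` frames before the birth frame
#' (clamped at 0) to the end of the movie; the extra pre-appearance frames
#' capture the baseline before the pore is first detected. Pixels falling
#' outside the frame are filled with the frame's background median and the
#' crop is flagged `clipped`.
#'
#' @param movie a [movie_stack()].
#' @param track one row of `tracks$tracks` (or a list with `birth_frame`,
#'   `row`, `col`, `track_id`).
#' @param radius_nm crop radius, nm (default 25).
#' @param pre_frames frames included before the birth frame (default 5).
#' @return Object of class `pore_crop`: list with `frames`, `times`,
#'   `track_id`, `birth_frame`, `start_frame`, `pixel_size`, `clipped`.
#' @export
crop_track <- function(movie, track, radius_nm = 25, pre_frames = 5L) {
  stopifnot(inherits(movie, "movie_stack"))
  side <- max(3L, round(2 * radius_nm / movie$pixel_size))
  half_lo <- (side - 1L) %/% 2L
  half_hi <- side - 1L - half_lo
  cr <- round(track$row); cc <- round(track$col)   # 0-based centre px
  start <- max(0L, track$birth_frame - as.integer(pre_frames))
  kk <- (start + 1L):length(movie$frames)
  shp <- dim(movie$frames[[1]])
  rr <- (cr - half_lo):(cr + half_hi) + 1L
  ccx <- (cc - half_lo):(cc + half_hi) + 1L
  clipped <- any(rr < 1L | rr > shp[1]) || any(ccx < 1L | ccx > shp[2])
  frames <- lapply(kk, function(k) {
    fr <- movie$frames[[k]]
    out <- matrix(stats::median(fr), side, side)
    okr <- rr >= 1L & rr <= shp[1]
    okc <- ccx >= 1L & ccx <= shp[2]
    out[okr, okc] <- fr[rr[okr], ccx[okc]]
    out
  })
  structure(list(frames = frames,
                 times = frame_times(movie)[kk],
                 track_id = track$track_id,
                 birth_frame = track$birth_frame,
                 start_frame = start,
                 pixel_size = movie$pixel_size,
                 clipped = clipped),
            class = "pore_crop")
}

#' Average-height trace of a cropped sub-movie
#'
#' The mean pixel height of each cropped frame, used as a proxy for pore
#' completeness: as subunits add, the annular arc grows and the average
#' height of the crop rises to a plateau. The normalized trace maps the
#' robust extremes (5th/95th percentiles) of the trace to \[0, 1\].
#'
#' @param crop a `pore_crop` from [crop_track()].
#' @return Object of class `height_trace`: list with `times` (s),
#'   `mean_heights` (nm), `normalized_heights`, `degenerate` (flat-trace
#'   flag).
#' @export
height_trace <- function(crop) {
  stopifnot(inherits(crop, "pore_crop"))
  if (length(crop$frames) < 3L) {
    stop("height_trace needs >= 3 frames", call. = FALSE)
  }
  h <- vapply(crop$frames, mean, numeric(1))
  lo <- stats::quantile(h, 0.05, names = FALSE)
  hi <- stats::quantile(h, 0.95, names = FALSE)
  degenerate <- (hi - lo) < .Machine$double.eps^0.5
  norm <- if (degenerate) rep(NA_real_, length(h)) else (h - lo) / (hi - lo)
  structure(list(times = crop$times, mean_heights = h,
                 normalized_heights = norm, degenerate = degenerate),
            class = "height_trace")
}
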