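#' Construct a movie stack of AFM height maps
#'
#' @param frames list of numeric matrices (heights in nm), all the same
#'   shape.
#' @param pixel_size nm per pixel.
#' @param frame_interval seconds between frames.
#' @param time_offset time of frame 0 relative to C9 addition (s).
#' @return Object of class `movie_stack` with fields `frames`,
#'   `pixel_size`, `frame_interval`, `time_offset`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval,
                        time_offset = 0) {
  if (!is.list(frames)) stop("frames must be a list of matrices",
                             call. = FALSE)
  if (length(frames) > 0L) {
    shp <- dim(frames[[1]])
    ok <- vapply(frames, function(f) {
      is.matrix(f) && identical(dim(f), shp) && all(is.finite(f))
    }, logical(1))
    if (!all(ok)) {
      stop("format error: all frames must be finite matrices of one shape",
           call. = FALSE)
    }
  }
  if (pixel_size <= 0 || frame_interval <= 0) {
    stop("pixel_size and frame_interval must be > 0", call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 time_offset = time_offset),
            class = "movie_stack")
}

#' Frame acquisition times of a movie stack
#' @param movie a [movie_stack()].
#' @return numeric vector, `time_offset + k * frame_interval` for frame
#'   index k = 0, 1, ...
#' @export
frame_times <- function(movie) {
  movie$time_offset +
    (seq_along(movie$frames) - 1L) * movie$frame_interval
}

#' @export
print.movie_stack <- function(x, ...) {
  shp <- if (length(x$frames)) dim(x$frames[[1]]) else c(0L, 0L)
  cat(sprintf(
    "movie_stack: %d frames of %d x %d px (%.3g nm/px, %.3g s/frame, t0 = %.3g s)\n",
    length(x$frames), shp[1], shp[2], x$pixel_size, x$frame_interval,
    x$time_offset))
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a movie stack as multi-frame TIFF plus JSON sidecar
#'
#' Heights (nm) are affine-encoded into the [0, 1] range of 32-bit float
#' TIFF samples; the offset and scale (nm) are stored in the sidecar and
#' inverted by [read_movie()]. Round-trip accuracy is limited by float32
#' resolution of the height range (about 1e-6 nm for a 20 nm range).
#'
#' @param stack a [movie_stack()].
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param overwrite overwrite existing files? Defaults to `FALSE`.
#' @param config optional [synthetic_config()] recorded in the sidecar for
#'   provenance.
#' @return Invisibly, the sidecar metadata list.
#' @export
write_movie <- function(stack, path, overwrite = FALSE, config = NULL) {
  stopifnot(inherits(stack, "movie_stack"))
  if (length(stack$frames) == 0L) {
    stop("cannot write an empty movie", call. = FALSE)
  }
  side <- sidecar_path(path)
  if (!overwrite && (file.exists(path) || file.exists(side))) {
    stop("output exists; pass overwrite = TRUE to replace it",
         call. = FALSE)
  }
  rng <- range(unlist(lapply(stack$frames, range)))
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  enc <- lapply(stack$frames, function(f) (f - offset) / scale)
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    pixel_size_nm = stack$pixel_size,
    frame_interval_s = stack$frame_interval,
    time_offset_s = stack$time_offset,
    height_offset_nm = offset,
    height_scale_nm = scale,
    n_frames = length(stack$frames),
    image_shape = dim(stack$frames[[1]])
  )
  if (!is.null(config)) meta$synthetic_config <- unclass(config)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Read a movie stack written by [write_movie()]
#'
#' @param path TIFF path; a JSON sidecar with keys `pixel_size_nm`,
#'   `frame_interval_s`, `time_offset_s`, `height_offset_nm`,
#'   `height_scale_nm` must sit next to it.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("no such movie: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing sidecar ", side, "; required keys: pixel_size_nm, ",
         "frame_interval_s, time_offset_s, height_offset_nm, ",
         "height_scale_nm", call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  required <- c("pixel_size_nm", "frame_interval_s", "time_offset_s",
                "height_offset_nm", "height_scale_nm")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("sidecar missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  shp <- dim(raw[[1]])
  if (!all(vapply(raw, function(f) identical(dim(f), shp), logical(1)))) {
    stop("format error: mixed frame shapes in ", path, call. = FALSE)
  }
  frames <- lapply(raw, function(f) {
    f * meta$height_scale_nm + meta$height_offset_nm
  })
  movie_stack(frames, pixel_size = meta$pixel_size_nm,
              frame_interval = meta$frame_interval_s,
              time_offset = meta$time_offset_s)
}
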