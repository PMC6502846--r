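#' Savitzky-Golay smoothing of a height trace
#'
#' Polynomial-preserving smoothing of the average-height array to reduce
#' imaging noise before the sigmoid fit: any trace that is exactly a
#' polynomial of degree <= `polyorder` passes through unchanged. Defaults
#' (window 7 frames, order 2) leave a tanh transition of width >= 2 frame
#' intervals essentially untouched.
#'
#' @param trace a `height_trace` from [height_trace()], or a numeric
#'   vector.
#' @param window_frames odd window length in frames (default 7).
#' @param polyorder polynomial order (default 2), must be < window.
#' @return Same type as the input, smoothed; for a `height_trace` the
#'   normalized trace is recomputed from the smoothed heights.
#' @export
savgol_smooth <- function(trace, window_frames = 7L, polyorder = 2L) {
  if (window_frames %% 2L == 0L || polyorder >= window_frames) {
    stop("window must be odd and larger than polyorder", call. = FALSE)
  }
  smooth1 <- function(x) {
    if (length(x) < window_frames) {
      stop("trace shorter than the smoothing window (", window_frames,
           "); use a smaller window", call. = FALSE)
    }
    as.numeric(signal::sgolayfilt(x, p = polyorder, n = window_frames))
  }
  if (is.numeric(trace)) return(smooth1(trace))
  stopifnot(inherits(trace, "height_trace"))
  h <- smooth1(trace$mean_heights)
  lo <- stats::quantile(h, 0.05, names = FALSE)
  hi <- stats::quantile(h, 0.95, names = FALSE)
  degenerate <- (hi - lo) < .Machine$double.eps^0.5
  structure(list(times = trace$times, mean_heights = h,
                 normalized_heights = if (degenerate) rep(NA_real_, length(h))
                                      else (h - lo) / (hi - lo),
                 degenerate = degenerate),
            class = "height_trace")
}

new_sigmoid_fit <- function(A = NA_real_, B = NA_real_, t0 = NA_real_,
                            tau = NA_real_, residual_rms = NA_real_,
                            converged = FALSE, qc_pass = NA,
                            reject_reason = "none") {
  structure(list(A = A, B = B, t0 = t0, tau = tau,
                 tau_olig = 3 * tau, residual_rms = residual_rms,
                 converged = converged, qc_pass = qc_pass,
                 reject_reason = reject_reason),
            class = "sigmoid_fit")
}

#' Fit the tanh sigmoid to a height trace
#'
#' Nonlinear least squares of
#' \deqn{f(t) = A \tanh((t - t_0)/\tau) + B}
#' to the (smoothed) trace, describing the smooth transition between pore
#' absence and pore completion. Initialization: `A = (max - min)/2`,
#' `B = mean`, `t0` at the largest discrete derivative, `tau` = a quarter
#' of the trace time span; bounds `A > 0`, `tau > 0`.
#'
#' @param trace a `height_trace` (ideally after [savgol_smooth()]) or a
#'   numeric vector of heights; in the latter case supply `times`.
#' @param times sample times (s), taken from the trace when omitted.
#' @param use `"normalized"` (default) or `"raw"` heights of a
#'   `height_trace`.
#' @return A `sigmoid_fit`: `A`, `B`, `t0` (s), `tau` (s),
#'   `tau_olig = 3 tau` (s), `residual_rms`, `converged`, and QC fields
#'   filled in by [qc_fit()]. Non-convergence yields
#'   `reject_reason = "fit_failed"`.
#' @export
fit_sigmoid <- function(trace, times = NULL, use = c("normalized", "raw")) {
  use <- match.arg(use)
  if (inherits(trace, "height_trace")) {
    y <- if (use == "normalized" && !trace$degenerate) {
      trace$normalized_heights
    } else {
      trace$mean_heights
    }
    times <- trace$times
  } else {
    y <- as.numeric(trace)
  }
  if (is.null(times) || length(times) != length(y)) {
    stop("times must accompany the trace", call. = FALSE)
  }
  if (length(y) < 6L) {
    stop("fit_sigmoid needs >= 6 points spanning the transition",
         call. = FALSE)
  }
  a0 <- (max(y) - min(y)) / 2
  if (a0 <= 0) {
    return(new_sigmoid_fit(converged = FALSE, qc_pass = FALSE,
                           reject_reason = "fit_failed"))
  }
  dy <- diff(y) / diff(times)
  start <- list(A = a0, B = mean(y),
                t0 = times[which.max(dy)],
                tau = diff(range(times)) / 4)
  # unbounded LM; (A, tau) -> (-A, -tau) leaves the model invariant, so the
  # A > 0, tau > 0 constraint is enforced by sign canonicalization (bounded
  # LM stalls when a large step clips tau to its bound and the gradient
  # underflows)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * tanh((tt - t0) / tau) + B,
      data = data.frame(tt = times, y = y),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_sigmoid_fit(converged = FALSE, qc_pass = FALSE,
                           reject_reason = "fit_failed"))
  }
  p <- stats::coef(fit)
  if (p[["tau"]] < 0) {
    p[["tau"]] <- -p[["tau"]]
    p[["A"]] <- -p[["A"]]
  }
  if (p[["A"]] <= 0) {
    return(new_sigmoid_fit(A = p[["A"]], B = p[["B"]], t0 = p[["t0"]],
                           tau = p[["tau"]], converged = FALSE,
                           qc_pass = FALSE, reject_reason = "fit_failed"))
  }
  new_sigmoid_fit(A = p[["A"]], B = p[["B"]], t0 = p[["t0"]],
                  tau = p[["tau"]],
                  residual_rms = sqrt(mean(stats::resid(fit)^2)),
                  converged = TRUE)
}

#' Quality control of a sigmoid fit
#'
#' A fit is rejected when the transition centre precedes the start of the
#' recording (`t0 < 0`) or when the transition width `3 tau` exceeds the
#' movie duration — both indicate the sigmoid was not constrained by an
#' observed transition.
#'
#' @param fit a `sigmoid_fit`.
#' @param movie_duration duration of the (cropped) movie sequence, s.
#' @return The fit with `qc_pass` and `reject_reason` set.
#' @export
qc_fit <- function(fit, movie_duration) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged)) {
    fit$qc_pass <- FALSE
    fit$reject_reason <- "fit_failed"
  } else if (fit$t0 < 0) {
    fit$qc_pass <- FALSE
    fit$reject_reason <- "t0_negative"
  } else if (3 * fit$tau > movie_duration) {
    fit$qc_pass <- FALSE
    fit$reject_reason <- "width_exceeds_movie"
  } else {
    fit$qc_pass <- TRUE
    fit$reject_reason <- "none"
  }
  fit
}

#' Oligomerization time of a QC-passing fit
#'
#' The transition width `3 tau`, over which the sigmoid traverses
#' `tanh(1.5)` (about 90%) of its full amplitude `2A`; this width is the
#' reaction time for the 17 C9 additions that complete the pore.
#'
#' @param fit a QC-passing `sigmoid_fit` (see [qc_fit()]).
#' @return `3 * tau`, s.
#' @export
transition_width <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$qc_pass)) {
    stop("transition_width requires a QC-passing fit (reject_reason: ",
         fit$reject_reason, ")", call. = FALSE)
  }
  3 * fit$tau
}

#' Summarize oligomerization times over many pores
#'
#' Aggregates `tau_olig = 3 tau` over the QC-passing fits only.
#'
#' @param fits list of `sigmoid_fit` objects (after [qc_fit()]).
#' @param bin_width histogram bin width, s (default 20).
#' @return List with `n`, `tau_olig` (vector, s), `mean`, `sd`, `sem`
#'   (`NA` when `n < 2`), and `histogram` (`breaks`, `counts`).
#' @export
aggregate_oligomerization <- function(fits, bin_width = 20) {
  pass <- Filter(function(f) isTRUE(f$qc_pass), fits)
  if (length(pass) == 0L) {
    stop("no QC-passing fits to aggregate", call. = FALSE)
  }
  w <- vapply(pass, function(f) 3 * f$tau, numeric(1))
  breaks <- seq(0, (floor(max(w) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(w, breaks = breaks, plot = FALSE)
  list(n = length(w), tau_olig = w, mean = mean(w),
       sd = if (length(w) > 1L) stats::sd(w) else NA_real_,
       sem = if (length(w) > 1L) stats::sd(w) / sqrt(length(w))
             else NA_real_,
       histogram = list(breaks = h$breaks, counts = h$counts))
}

#' Fit results as a table
#'
#' @param fits list of `sigmoid_fit` objects.
#' @param track_ids optional ids matched to `fits`.
#' @return data.frame with one row per fit: track_id, A, B, t0_s, tau_s,
#'   tau_olig_s, residual_rms, qc_pass, reject_reason.
#' @export
fits_to_df <- function(fits, track_ids = seq_along(fits)) {
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(track_id = track_ids[i], A = f$A, B = f$B, t0_s = f$t0,
               tau_s = f$tau, tau_olig_s = f$tau_olig,
               residual_rms = f$residual_rms,
               qc_pass = isTRUE(f$qc_pass),
               reject_reason = f$reject_reason)
  }))
}
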