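#' Configuration for synthetic AFM movie generation
#'
#' Bundles the kinetic and imaging parameters used to simulate MAC assembly
#' and render it as a height-map movie. Defaults reproduce the study
#' conditions: \eqn{[C9] \approx 1.4\,\mu M} (1.4e-3 mM), 6.5 s per frame,
#' 2 nm pixels, a 256 x 256 px field of view, and the measured rate
#' constants \eqn{k_{init} = 0.78} and \eqn{k_+ = 108} s^-1 mM^-1.
#'
#' @param n_complexes number of C5b-8 complexes (potential pores) on the
#'   membrane. The final pore count is set by this number because C9 is in
#'   excess.
#' @param k_init initiation rate constant (s^-1 mM^-1) for the first C9
#'   insertion.
#' @param k_plus oligomerization rate constant (s^-1 mM^-1) per C9 addition.
#' @param c9_conc C9 concentration (mM), assumed constant (excess).
#' @param t_max movie duration (s); events after `t_max` are truncated.
#'   May be `Inf` when only event times (no movie) are needed.
#' @param frame_interval time between frames (s).
#' @param pixel_size lateral pixel size (nm/px).
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param noise_sd standard deviation of additive Gaussian height noise (nm).
#' @param drift_per_frame lateral drift `c(row_nm, col_nm)` applied
#'   cumulatively per frame.
#' @param tilt global plane tilt `c(nm_per_px_row, nm_per_px_col)` added to
#'   every frame (models residual scanner tilt).
#' @param time_offset time of frame 0 relative to C9 addition (s).
#' @param seed integer seed; event times, positions and pixel noise use
#'   separate substreams derived from it, so changing the rendering does not
#'   perturb the sampled kinetics.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_complexes = 50,
                             k_init = 0.78,
                             k_plus = 108,
                             c9_conc = 1.4e-3,
                             t_max = 3250,
                             frame_interval = 6.5,
                             pixel_size = 2,
                             image_shape = c(256L, 256L),
                             noise_sd = 0.3,
                             drift_per_frame = c(0, 0),
                             tilt = c(0, 0),
                             time_offset = 0,
                             seed = 1L) {
  cfg <- list(
    n_complexes = as.integer(n_complexes), k_init = k_init, k_plus = k_plus,
    c9_conc = c9_conc, t_max = t_max, frame_interval = frame_interval,
    pixel_size = pixel_size, image_shape = as.integer(image_shape),
    noise_sd = noise_sd, drift_per_frame = drift_per_frame, tilt = tilt,
    time_offset = time_offset, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_complexes < 0) stop("n_complexes must be >= 0", call. = FALSE)
  if (cfg$k_init < 0 || cfg$k_plus < 0) {
    stop("invalid parameter: rate constants must be >= 0", call. = FALSE)
  }
  if (cfg$c9_conc <= 0) {
    stop("invalid parameter: c9_conc must be > 0", call. = FALSE)
  }
  if (cfg$t_max <= 0 || cfg$frame_interval <= 0 || cfg$pixel_size <= 0) {
    stop("invalid parameter: t_max, frame_interval, pixel_size must be > 0",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L)) {
    stop("image_shape must be c(rows, cols), each >= 8 px", call. = FALSE)
  }
  invisible(cfg)
}

#' Geometry of a rendered MAC pore
#'
#' The complete MAC is rendered as an annulus (ring) around an 11 nm lumen,
#' consistent with the transmembrane pore dimensions seen by AFM; a growing
#' pore with n of 18 subunits is rendered as an arc covering a fraction
#' n/18 of the ring. An optional central stalk bump models the C5b678 stalk
#' that protrudes above the ring.
#'
#' @param lumen_diameter inner (lumen) diameter, nm.
#' @param ring_outer_diameter outer ring diameter, nm.
#' @param ring_height ring protrusion height above the bilayer, nm.
#' @param stalk_height stalk bump height, nm (used when `stalk_enabled`).
#' @param stalk_enabled render the central stalk bump?
#' @return An object of class `pore_geometry`.
#' @export
pore_geometry <- function(lumen_diameter = 11,
                          ring_outer_diameter = 22,
                          ring_height = 10,
                          stalk_height = 16,
                          stalk_enabled = FALSE) {
  if (lumen_diameter >= ring_outer_diameter) {
    stop("lumen_diameter must be smaller than ring_outer_diameter",
         call. = FALSE)
  }
  if (any(c(lumen_diameter, ring_outer_diameter) <= 0) ||
      ring_height < 0 || stalk_height < 0) {
    stop("pore geometry lengths must be positive, heights >= 0",
         call. = FALSE)
  }
  structure(list(lumen_diameter = lumen_diameter,
                 ring_outer_diameter = ring_outer_diameter,
                 ring_height = ring_height,
                 stalk_height = stalk_height,
                 stalk_enabled = isTRUE(stalk_enabled)),
            class = "pore_geometry")
}

# Template side in pixels: next odd count >= outer diameter in px + 4,
# leaving a ~2 px background rim that anchors the normalized correlation.
template_side_px <- function(geometry, pixel_size) {
  side <- ceiling(geometry$ring_outer_diameter / pixel_size + 4)
  if (side %% 2 == 0) side <- side + 1
  as.integer(side)
}

# Substream seeds: distinct deterministic offsets keep event times invariant
# under changes to placement or rendering noise (all kept below 2^31).
.seed_events    <- function(seed) (seed %% 1000000L) * 3L + 11L
.seed_positions <- function(seed) (seed %% 1000000L) * 3L + 12L
.seed_noise     <- function(seed) (seed %% 1000000L) * 3L + 13L

#' Simulate MAC assembly event times and positions
#'
#' Draws, for each C5b-8 complex, the time of first C9 insertion from an
#' exponential law with rate \eqn{k_{init}[C9]}, followed by 17 independent
#' exponential waiting times with rate \eqn{k_+[C9]} for the remaining C9
#' additions (sequential birth chain with absorbing completed state, 18
#' subunits total). Positions are drawn uniformly with a minimum pairwise
#' separation of one template width so that ground-truth identity is
#' unambiguous for the tracker.
#'
#' @param config a [synthetic_config()].
#' @param geometry a [pore_geometry()]; sets the minimum separation.
#' @return List of `assembly_trajectory` objects with fields `complex_id`,
#'   `t_init` (s; may exceed `t_max`, meaning the pore never appears within
#'   the movie), `t_additions` (addition times <= `t_max`, strictly
#'   increasing), `position` (`c(row_nm, col_nm)`), `angle0` (fixed arc
#'   start angle; growth is unidirectional), and `completed`.
#' @export
simulate_assembly_events <- function(config, geometry = pore_geometry()) {
  validate_synthetic_config(config)
  lam_init <- config$k_init * config$c9_conc
  lam_plus <- config$k_plus * config$c9_conc
  n <- config$n_complexes

  set.seed(.seed_events(config$seed))
  t_init <- if (lam_init > 0) stats::rexp(n, rate = lam_init) else rep(Inf, n)
  waits <- if (lam_plus > 0) {
    matrix(stats::rexp(17L * n, rate = lam_plus), nrow = 17L)
  } else {
    matrix(Inf, nrow = 17L, ncol = n)
  }

  positions <- place_positions(config, geometry)

  lapply(seq_len(n), function(i) {
    adds <- t_init[i] + cumsum(waits[, i])
    completed <- length(adds) == 17L && adds[17L] <= config$t_max
    adds <- adds[adds <= config$t_max]
    structure(list(
      complex_id = i,
      t_init = t_init[i],
      t_additions = adds,
      position = positions[i, ],
      angle0 = (i * 2.39996322972865332) %% (2 * pi),  # golden-angle spread
      completed = completed
    ), class = "assembly_trajectory")
  })
}

# Dart-throwing placement with min separation = one template width and an
# edge inset of half a template width + 1 px, so no pore is edge-excluded.
place_positions <- function(config, geometry) {
  n <- config$n_complexes
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  side_nm <- template_side_px(geometry, config$pixel_size) * config$pixel_size
  extent <- (config$image_shape - 1) * config$pixel_size
  margin <- side_nm / 2 + config$pixel_size
  lo <- c(margin, margin)
  hi <- extent - margin
  if (any(hi <= lo)) {
    stop("placement error: image too small for the pore geometry",
         call. = FALSE)
  }
  set.seed(.seed_positions(config$seed))
  pos <- matrix(NA_real_, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(5000L)) {
      p <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (i == 1L ||
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1L), , drop = FALSE],
                                 2, p)^2))) >= side_nm) {
        pos[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("placement error: image too small for ", n,
           " complexes at separation ", signif(side_nm, 3), " nm",
           call. = FALSE)
    }
  }
  colnames(pos) <- c("row_nm", "col_nm")
  pos
}

# Number of C9 subunits held by a trajectory at absolute time t (0 before
# initiation, capped at 18). Sub-frame event times are effectively rounded
# down to the first frame at which the new state is displayed.
subunit_count <- function(traj, t) {
  if (t < traj$t_init) return(0L)
  min(18L, 1L + sum(traj$t_additions <= t))
}

# Render one pore (n subunits out of 18) into a patch. `centre` is the pore
# centre in nm relative to the patch origin pixel (0-based pixel centres at
# multiples of pixel_size). Returns a side x side matrix of heights (nm).
render_pore_patch <- function(geometry, pixel_size, n_sub, angle0,
                              side, centre) {
  patch <- matrix(0, nrow = side, ncol = side)
  if (n_sub <= 0L) return(patch)
  idx <- seq_len(side) - 1L
  dr <- outer(idx * pixel_size - centre[1], rep(1, side))
  dc <- outer(rep(1, side), idx * pixel_size - centre[2])
  rad <- sqrt(dr^2 + dc^2)
  in_ring <- rad >= geometry$lumen_diameter / 2 &
    rad <= geometry$ring_outer_diameter / 2
  frac <- min(1, n_sub / 18)
  if (frac < 1) {
    theta <- (atan2(dc, dr) - angle0) %% (2 * pi)
    in_ring <- in_ring & (theta <= 2 * pi * frac)
  }
  patch[in_ring] <- geometry$ring_height
  if (geometry$stalk_enabled) {
    in_stalk <- rad <= geometry$lumen_diameter / 4
    patch[in_stalk] <- geometry$stalk_height
  }
  patch
}

#' Render assembly trajectories into a synthetic AFM movie
#'
#' Each frame is a flat (0 nm) bilayer background plus additive Gaussian
#' noise, an optional global plane tilt, and one annular feature per pore.
#' A pore holding n subunits is drawn as an arc covering n/18 of the full
#' ring at full ring height; growth is unidirectional from a fixed start
#' angle. Frame k represents time `time_offset + k * frame_interval`.
#'
#' @param trajectories list of trajectories from [simulate_assembly_events()].
#' @param geometry a [pore_geometry()].
#' @param config a [synthetic_config()].
#' @return A [movie_stack()].
#' @export
render_movie <- function(trajectories, geometry = pore_geometry(),
                         config = synthetic_config()) {
  validate_synthetic_config(config)
  shp <- config$image_shape
  side_nm <- template_side_px(geometry, config$pixel_size) * config$pixel_size
  if (geometry$ring_outer_diameter >=
      min(shp) * config$pixel_size) {
    stop("render error: pore geometry larger than the image", call. = FALSE)
  }
  n_frames <- floor((config$t_max - config$time_offset) /
                      config$frame_interval) + 1L
  times <- config$time_offset + (seq_len(n_frames) - 1L) * config$frame_interval

  set.seed(.seed_noise(config$seed))
  frames <- vector("list", n_frames)
  side <- template_side_px(geometry, config$pixel_size)
  half <- (side - 1L) %/% 2L
  tilt_plane <- if (any(config$tilt != 0)) {
    outer((seq_len(shp[1]) - 1L) * config$tilt[1], rep(1, shp[2])) +
      outer(rep(1, shp[1]), (seq_len(shp[2]) - 1L) * config$tilt[2])
  } else NULL

  for (k in seq_len(n_frames)) {
    fr <- if (config$noise_sd > 0) {
      matrix(stats::rnorm(shp[1] * shp[2], sd = config$noise_sd),
             nrow = shp[1], ncol = shp[2])
    } else {
      matrix(0, nrow = shp[1], ncol = shp[2])
    }
    if (!is.null(tilt_plane)) fr <- fr + tilt_plane
    drift <- (k - 1L) * config$drift_per_frame
    for (traj in trajectories) {
      n_sub <- subunit_count(traj, times[k])
      if (n_sub == 0L) next
      pos <- traj$position + drift
      cpx <- round(pos / config$pixel_size)          # nearest pixel, 0-based
      r0 <- cpx[1] - half; c0 <- cpx[2] - half       # patch origin, 0-based
      patch <- render_pore_patch(
        geometry, config$pixel_size, n_sub, traj$angle0, side,
        centre = pos - c(r0, c0) * config$pixel_size
      )
      rr <- (r0 + 1L):(r0 + side); cc <- (c0 + 1L):(c0 + side)
      keep_r <- rr >= 1L & rr <= shp[1]
      keep_c <- cc >= 1L & cc <= shp[2]
      fr[rr[keep_r], cc[keep_c]] <- fr[rr[keep_r], cc[keep_c]] +
        patch[keep_r, keep_c]
    }
    frames[[k]] <- fr
  }
  movie_stack(frames, pixel_size = config$pixel_size,
              frame_interval = config$frame_interval,
              time_offset = config$time_offset)
}

#' Build a noiseless template image of one complete pore
#'
#' Synthetic analogue of user-selecting a template pore from the final frame
#' of a recording: a centred, complete (18-subunit) ring on a zero
#' background. The side length is the next odd pixel count at least
#' `ring_outer_diameter / pixel_size + 4`.
#'
#' @param geometry a [pore_geometry()].
#' @param pixel_size nm per pixel.
#' @return A square numeric matrix of heights (nm).
#' @export
make_template <- function(geometry = pore_geometry(), pixel_size = 2) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  side <- template_side_px(geometry, pixel_size)
  half <- (side - 1L) / 2
  render_pore_patch(geometry, pixel_size, n_sub = 18L, angle0 = 0,
                    side = side, centre = c(half, half) * pixel_size)
}

#' Ground-truth event table for simulated trajectories
#'
#' Long-format table of all simulated events (event_index 0 is the first C9
#' insertion; 1..17 the subsequent additions), suitable for CSV export.
#'
#' @param trajectories list from [simulate_assembly_events()].
#' @return data.frame with columns complex_id, event_index, time_s, row_nm,
#'   col_nm.
#' @export
trajectories_to_df <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    times <- c(tr$t_init, tr$t_additions)
    times <- times[is.finite(times)]
    if (length(times) == 0L) return(NULL)
    data.frame(complex_id = tr$complex_id,
               event_index = seq_along(times) - 1L,
               time_s = times,
               row_nm = unname(tr$position[1]),
               col_nm = unname(tr$position[2]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(complex_id = integer(), event_index = integer(),
                      time_s = numeric(), row_nm = numeric(),
                      col_nm = numeric())
  }
  rownames(out) <- NULL
  out
}
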