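#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its default, plus a
#' provenance block (config hash, package version, timestamp) embedded in
#' all outputs. Serializes round-trip through JSON.
#'
#' @param threshold normalized correlation detection threshold.
#' @param max_link_dist_px tracker maximum linking distance, px.
#' @param max_gap_frames tracker maximum gap closing, frames.
#' @param radius_nm crop radius around each track, nm.
#' @param pre_frames pre-appearance frames included in each crop.
#' @param savgol_window,savgol_order Savitzky-Golay smoothing parameters.
#' @param min_detections curation threshold on detections per track.
#' @param count_mode appearance counts from curated `"tracks"` (default)
#'   or raw `"detections"`.
#' @param c9_conc C9 concentration, mM.
#' @param n_additions C9 additions after the first insertion (17).
#' @param fwhm_px preprocessing Gaussian FWHM, px.
#' @param synthetic a [synthetic_config()] used when simulating input.
#' @param geometry a [pore_geometry()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 0.6,
                            max_link_dist_px = 30,
                            max_gap_frames = 3L,
                            radius_nm = 25,
                            pre_frames = 5L,
                            savgol_window = 7L,
                            savgol_order = 2L,
                            min_detections = 3L,
                            count_mode = c("tracks", "detections"),
                            c9_conc = 1.4e-3,
                            n_additions = 17L,
                            fwhm_px = 2,
                            synthetic = synthetic_config(),
                            geometry = pore_geometry()) {
  cfg <- list(threshold = threshold, max_link_dist_px = max_link_dist_px,
              max_gap_frames = max_gap_frames, radius_nm = radius_nm,
              pre_frames = pre_frames, savgol_window = savgol_window,
              savgol_order = savgol_order, min_detections = min_detections,
              count_mode = match.arg(count_mode), c9_conc = c9_conc,
              n_additions = n_additions, fwhm_px = fwhm_px,
              synthetic = unclass(synthetic), geometry = unclass(geometry))
  cfg$provenance <- list(
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("mackin"))
  )
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis chain on one movie
#'
#' preprocess -> detect -> track -> fit traces -> kinetics. With
#' `movie = NULL`, a synthetic movie is first simulated from
#' `config$synthetic` (ground truth is then included in the report).
#'
#' @param movie a [movie_stack()], or `NULL` to simulate one.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-stage CSV tables and
#'   a `summary.json` are written there.
#' @return Report list: `config`, `counts` (per-frame), `appearance`
#'   ([fit_appearance()] result), `tracks`, `fits` (table), `olig`
#'   (aggregate), `kinetics` ([estimate_kinetics()] result), and
#'   `truth` for simulated input.
#' @export
run_pipeline <- function(movie = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  geometry <- do.call(pore_geometry, config$geometry)
  truth <- NULL
  if (is.null(movie)) {
    sim_cfg <- do.call(synthetic_config, config$synthetic)
    truth <- stage("simulate", simulate_assembly_events(sim_cfg, geometry))
    movie <- stage("render", render_movie(truth, geometry, sim_cfg))
  }
  if (length(movie$frames) == 0L) {
    stop("pipeline stage 'detect' failed: movie has no frames",
         call. = FALSE)
  }

  pre <- stage("preprocess",
               preprocess_movie(movie, fwhm_px = config$fwhm_px))
  template <- make_template(geometry, movie$pixel_size)
  detections <- stage("detect",
                      detect_movie(pre, template, config$threshold))
  tracks <- stage("track", {
    tr <- link_tracks(detections, config$max_link_dist_px,
                      config$max_gap_frames)
    curate_tracks(tr, config$min_detections)
  })

  times <- frame_times(movie)
  counts <- if (config$count_mode == "detections") {
    count_pores(pre, template, config$threshold, detections = detections)
  } else {
    kept <- tracks$tracks[tracks$tracks$curated, , drop = FALSE]
    vapply(seq_along(times) - 1L,
           function(k) sum(kept$birth_frame <= k), numeric(1))
  }
  appearance <- stage("kinetics", fit_appearance(times, counts))

  kept <- tracks$tracks[tracks$tracks$curated, , drop = FALSE]
  fits <- stage("fit-traces", lapply(seq_len(nrow(kept)), function(i) {
    crop <- crop_track(pre, kept[i, ], config$radius_nm,
                       config$pre_frames)
    tr <- height_trace(crop)
    if (tr$degenerate || length(tr$times) < config$savgol_window) {
      return(new_sigmoid_fit(converged = FALSE, qc_pass = FALSE,
                             reject_reason = "fit_failed"))
    }
    sm <- savgol_smooth(tr, config$savgol_window, config$savgol_order)
    qc_fit(fit_sigmoid(sm), movie_duration = diff(range(tr$times)))
  }))
  olig <- stage("fit-traces", aggregate_oligomerization(fits))
  kin <- stage("kinetics",
               estimate_kinetics(appearance, olig, config$c9_conc,
                                 config$n_additions))

  report <- list(
    config = config,
    counts = data.frame(time_s = times, count = counts),
    appearance = appearance,
    tracks = tracks$tracks,
    fits = fits_to_df(fits, kept$track_id),
    olig = olig,
    kinetics = kin,
    truth = truth
  )
  if (!is.null(out_dir)) write_report(report, tracks, out_dir)
  report
}

write_report <- function(report, tracks, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(tracks$detections, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  if (!is.null(report$truth)) {
    utils::write.csv(trajectories_to_df(report$truth),
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    config_hash = report$config$provenance$config_hash,
    tau_init_s = report$kinetics$tau_init,
    tau_olig_s = report$kinetics$tau_olig,
    tau_plus_s = report$kinetics$tau_plus,
    k_init_per_s_mM = report$kinetics$k_init,
    k_plus_per_s_mM = report$kinetics$k_plus,
    timescale_ratio = report$kinetics$timescale_ratio,
    n_tracks = nrow(report$tracks),
    n_fits_passing = report$olig$n,
    A_sat = report$appearance$A_sat
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
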