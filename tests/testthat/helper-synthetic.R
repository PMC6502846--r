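# Hand-built assembly trajectory with full control over event times.
make_trajectory <- function(complex_id, t_init, t_additions,
                            position, angle0 = 0) {
  structure(list(complex_id = complex_id, t_init = t_init,
                 t_additions = t_additions, position = position,
                 angle0 = angle0,
                 completed = length(t_additions) == 17L),
            class = "assembly_trajectory")
}

# A trajectory that is a complete pore from t = 0 at `position` (nm).
complete_pore <- function(position, complex_id = 1L) {
  make_trajectory(complex_id, t_init = 0,
                  t_additions = seq_len(17L) * 1e-9,
                  position = position)
}

# Noiseless movie containing the given trajectories. Frame 0 sits at t = 1 s
# so that a `complete_pore` (additions at ~0 s) is complete from the start.
quiet_movie <- function(trajectories, t_max = 65, shape = c(96L, 96L),
                        geometry = pore_geometry(), time_offset = 1) {
  cfg <- synthetic_config(n_complexes = length(trajectories),
                          t_max = t_max, image_shape = shape,
                          noise_sd = 0, time_offset = time_offset,
                          seed = 1L)
  render_movie(trajectories, geometry, cfg)
}

# Intensity-weighted centroid (0-based px) of a frame region.
frame_centroid <- function(frame) {
  w <- frame / sum(frame)
  rows <- matrix(seq_len(nrow(frame)) - 1, nrow(frame), ncol(frame))
  cols <- matrix(rep(seq_len(ncol(frame)) - 1, each = nrow(frame)),
                 nrow(frame), ncol(frame))
  c(sum(rows * w), sum(cols * w))
}

# A pore_crop built directly from a list of frames (bypasses tracking).
manual_crop <- function(frames, frame_interval = 6.5, pixel_size = 2) {
  structure(list(frames = frames,
                 times = (seq_along(frames) - 1) * frame_interval,
                 track_id = 1L, birth_frame = 0L, start_frame = 0L,
                 pixel_size = pixel_size, clipped = FALSE),
            class = "pore_crop")
}
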