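tpl <- make_template(pore_geometry(), pixel_size = 2)

test_that("a planted template is found exactly once with score 1", {
  fr <- matrix(0, 64, 64)
  fr[21:35, 41:55] <- tpl            # centre (28, 48) 1-based
  det <- detect_pores(fr, tpl, threshold = 0.6)
  expect_equal(nrow(det), 1L)
  expect_equal(det$row, 27)          # 0-based
  expect_equal(det$col, 47)
  expect_equal(det$score, 1, tolerance = 1e-6)
  expect_error(detect_pores(matrix(0, 8, 8), tpl), "larger than")
})

test_that("membrane noise alone produces no detections at threshold 0.6", {
  set.seed(99)
  hits <- sum(vapply(1:100, function(i) {
    fr <- matrix(rnorm(128 * 128, sd = 0.3), 128, 128)
    nrow(detect_pores(fr, tpl, threshold = 0.6))
  }, numeric(1)))
  expect_equal(hits, 0L)
})

test_that("well-separated pores are each detected at their centre", {
  trs <- list(complete_pore(c(60, 60), 1L), complete_pore(c(130, 120), 2L))
  mv <- quiet_movie(trs, t_max = 6.5, shape = c(96L, 96L))
  det <- detect_pores(mv$frames[[1]], tpl)
  expect_equal(nrow(det), 2L)
  got <- det[order(det$row), ]
  expect_lt(max(abs(got$row - c(30, 65))), 1.01)
  expect_lt(max(abs(got$col - c(30, 60))), 1.01)
  # edge exclusion: no detection closer than half a template to the border
  expect_true(all(got$row >= 7 & got$row <= 96 - 8))
})

test_that("per-frame counts follow the planted ground truth", {
  m0 <- quiet_movie(list(), t_max = 20, shape = c(64L, 64L))
  expect_equal(count_pores(m0, tpl), rep(0L, length(m0$frames)))

  trs <- list(complete_pore(c(40, 40), 1L), complete_pore(c(90, 80), 2L),
              complete_pore(c(40, 100), 3L))
  mv <- quiet_movie(trs, t_max = 32.5, shape = c(80L, 80L))
  expect_equal(count_pores(mv, tpl), rep(3L, length(mv$frames)))

  # staggered appearance with zero noise: counts are non-decreasing
  stag <- lapply(1:3, function(i) {
    make_trajectory(i, t_init = i * 40, t_additions = i * 40 + (1:17) * 2,
                    position = c(40, 30 * i + 10))
  })
  mvs <- quiet_movie(stag, t_max = 200, shape = c(80L, 80L))
  expect_true(all(diff(count_pores(mvs, tpl)) >= 0))
})

test_that("linking honours the gap-closing boundary exactly", {
  mk <- function(frames) {
    data.frame(frame_index = frames, row = 50, col = 50, score = 0.9)
  }
  # absent for exactly max_gap frames: one track
  one <- link_tracks(mk(c(0, 1, 2, 6, 7)), max_gap_frames = 3)
  expect_equal(nrow(one$tracks), 1L)
  # absent for max_gap + 1 frames: two tracks
  two <- link_tracks(mk(c(0, 1, 2, 7, 8)), max_gap_frames = 3)
  expect_equal(nrow(two$tracks), 2L)
  # a detection in every frame: a single track spanning the movie
  all_frames <- link_tracks(mk(0:19))
  expect_equal(nrow(all_frames$tracks), 1L)
  expect_equal(all_frames$tracks$birth_frame, 0L)
  expect_equal(all_frames$tracks$last_frame, 19L)
  expect_true(all_frames$tracks$pre_existing)
})

test_that("unlinkable detections and empty input behave", {
  det <- data.frame(frame_index = c(0L, 0L, 1L, 1L),
                    row = c(10, 110, 10, 110), col = c(10, 110, 10, 110),
                    score = 0.9)
  trk <- link_tracks(det, max_link_dist_px = 30)
  expect_equal(nrow(trk$tracks), 2L)
  expect_true(all(trk$tracks$n_detections == 2L))

  empty <- link_tracks(data.frame(frame_index = integer(), row = integer(),
                                  col = integer(), score = numeric()))
  expect_equal(nrow(empty$tracks), 0L)

  # determinism
  a <- link_tracks(det)
  b <- link_tracks(det)
  expect_identical(a, b)
})

test_that("cropping geometry and pre-frames follow the conventions", {
  mv <- quiet_movie(list(complete_pore(c(96, 96))), t_max = 65,
                    shape = c(96L, 96L))
  track <- list(track_id = 1L, birth_frame = 3L, row = 48, col = 48)
  crop <- crop_track(mv, track, radius_nm = 25, pre_frames = 5)
  expect_identical(dim(crop$frames[[1]]), c(25L, 25L))  # 2*25 nm / 2 nm/px
  expect_equal(crop$start_frame, 0L)                    # clamped at 0
  expect_false(crop$clipped)
  # the noiseless complete pore's global maximum lies inside the crop
  expect_equal(max(crop$frames[[1]]), max(mv$frames[[1]]))
})

test_that("height traces reduce crops to the expected step", {
  flat <- manual_crop(replicate(6, matrix(0, 10, 10), simplify = FALSE))
  tr <- height_trace(flat)
  expect_true(tr$degenerate)
  expect_equal(tr$mean_heights, rep(0, 6))

  # pore covering fraction f of pixels at height H appears at frame 4
  H <- 12
  on <- matrix(0, 10, 10)
  on[1:5, 1:4] <- H                   # f = 0.2
  frames <- c(replicate(3, matrix(0, 10, 10), simplify = FALSE),
              replicate(5, on, simplify = FALSE))
  tr <- height_trace(manual_crop(frames))
  expect_equal(tr$mean_heights, c(rep(0, 3), rep(0.2 * H, 5)))
  ok <- is.finite(tr$normalized_heights)
  expect_true(all(tr$normalized_heights[ok] >= -0.11 &
                    tr$normalized_heights[ok] <= 1.11))
  expect_error(height_trace(manual_crop(frames[1:2])), ">= 3 frames")
})
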