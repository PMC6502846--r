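test_that("initiation and completion times follow the exponential laws", {
  # rate k_init * [C9] = 1/912 s^-1; analytic mean and variance of the
  # exponential law are the oracle
  cfg <- synthetic_config(n_complexes = 10000, k_init = 1 / 912,
                          c9_conc = 1, k_plus = 17 / 50, t_max = Inf,
                          image_shape = c(4096L, 4096L), seed = 11)
  trs <- simulate_assembly_events(cfg)
  t_init <- vapply(trs, `[[`, numeric(1), "t_init")
  se_mean <- 912 / sqrt(length(t_init))
  expect_lt(abs(mean(t_init) - 912), 3 * se_mean)
  se_var <- 912^2 * sqrt(8 / length(t_init))
  expect_lt(abs(var(t_init) - 912^2), 3 * se_var)

  # completion time = Gamma(17, k_plus * c9): mean 17 / (k_plus * c9) = 50 s
  compl <- vapply(trs, function(tr) tr$t_additions[17] - tr$t_init,
                  numeric(1))
  se_c <- (50 / sqrt(17)) / sqrt(length(compl))
  expect_lt(abs(mean(compl) - 50), 3 * se_c)
})

test_that("zero initiation rate and instantaneous propagation limits hold", {
  cfg0 <- synthetic_config(n_complexes = 50, k_init = 0, t_max = 1e6,
                           seed = 2)
  trs <- simulate_assembly_events(cfg0)
  expect_true(all(!is.finite(vapply(trs, `[[`, numeric(1), "t_init"))))

  cfgf <- synthetic_config(n_complexes = 20, k_plus = 1e6, t_max = 5000,
                           seed = 3)
  trs <- simulate_assembly_events(cfgf)
  done <- Filter(function(tr) tr$completed, trs)
  compl <- vapply(done, function(tr) tr$t_additions[17] - tr$t_init,
                  numeric(1))
  expect_true(all(compl < 0.5))
})

test_that("event times are reproducible and invariant to render settings", {
  cfg <- synthetic_config(n_complexes = 10, t_max = 300,
                          image_shape = c(128L, 128L), seed = 5)
  a <- simulate_assembly_events(cfg)
  b <- simulate_assembly_events(cfg)
  expect_identical(a, b)
  ma <- render_movie(a, config = cfg)
  mb <- render_movie(b, config = cfg)
  expect_identical(ma, mb)

  # noise_sd belongs to the rendering substream, not the event substream
  cfg2 <- synthetic_config(n_complexes = 10, t_max = 300,
                           image_shape = c(128L, 128L), noise_sd = 1,
                           seed = 5)
  c2 <- simulate_assembly_events(cfg2)
  expect_identical(vapply(a, `[[`, numeric(1), "t_init"),
                   vapply(c2, `[[`, numeric(1), "t_init"))
})

test_that("invalid parameters and impossible placement are rejected", {
  expect_error(synthetic_config(c9_conc = 0), "invalid parameter")
  expect_error(synthetic_config(t_max = -1), "invalid parameter")
  expect_error(
    simulate_assembly_events(
      synthetic_config(n_complexes = 500, image_shape = c(32L, 32L))),
    "placement"
  )
})

test_that("rendering places features accurately on an empty background", {
  # background only
  m0 <- quiet_movie(list(), t_max = 13, shape = c(48L, 48L))
  expect_true(all(vapply(m0$frames, function(f) all(f == 0), logical(1))))

  # single completed pore: max equals ring height (stalk taller if enabled)
  geo <- pore_geometry()
  m1 <- quiet_movie(list(complete_pore(c(48, 48))), t_max = 13,
                    shape = c(48L, 48L))
  expect_equal(max(m1$frames[[1]]), geo$ring_height)
  geo_s <- pore_geometry(stalk_enabled = TRUE)
  m1s <- quiet_movie(list(complete_pore(c(48, 48))), t_max = 13,
                     shape = c(48L, 48L), geometry = geo_s)
  expect_equal(max(m1s$frames[[1]]), geo_s$stalk_height)

  # 10 well-separated pores at known sub-pixel positions: rendered
  # centroids within 0.5 px
  set.seed(42)
  grid <- as.matrix(expand.grid(c(50, 110, 170), c(50, 110, 170)))
  pos <- rbind(grid, c(215, 215)) + matrix(runif(20, -1, 1), 10, 2)
  trs <- lapply(seq_len(10), function(i) complete_pore(pos[i, ], i))
  mv <- quiet_movie(trs, t_max = 6.5, shape = c(128L, 128L))
  fr <- mv$frames[[1]]
  for (i in seq_len(10)) {
    px <- pos[i, ] / mv$pixel_size
    win <- fr[round(px[1]) + (-8:8) + 1L, round(px[2]) + (-8:8) + 1L]
    cent <- frame_centroid(win) + round(px) - 8
    expect_lt(max(abs(cent - px)), 0.5)
  }
})

test_that("rendered subunit readout is non-decreasing in time", {
  tr <- make_trajectory(1L, t_init = 10, t_additions = 10 + (1:17) * 12,
                        position = c(48, 48))
  mv <- quiet_movie(list(tr), t_max = 260, shape = c(48L, 48L))
  ring_px <- vapply(mv$frames,
                    function(f) sum(f >= pore_geometry()$ring_height / 2),
                    numeric(1))
  expect_true(all(diff(ring_px) >= 0))
})

test_that("the template is a centred, symmetric, complete pore", {
  geo <- pore_geometry()
  tpl <- make_template(geo, pixel_size = 2)
  expect_identical(dim(tpl), c(15L, 15L))      # next odd >= 22/2 + 4
  expect_equal(max(tpl), geo$ring_height)
  expect_equal(tpl, tpl[rev(seq_len(nrow(tpl))), rev(seq_len(ncol(tpl)))])
  centre <- (nrow(tpl) + 1L) %/% 2L
  sc <- zncc_map(`[<-`(matrix(0, 45, 45), 16:30, 16:30, tpl), tpl)
  expect_equal(sc[23, 23], 1, tolerance = 1e-9)
})
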