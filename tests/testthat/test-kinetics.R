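test_that("fit_appearance recovers exact saturating-exponential counts", {
  t <- seq(0, 4000, by = 6.5)
  counts <- 50 * (1 - exp(-t / 912))
  fit <- fit_appearance(t, counts)
  expect_equal(fit$A_sat, 50, tolerance = 1e-6)
  expect_equal(fit$tau_init, 912, tolerance = 1e-6)
  expect_false(fit$boundary)
})

test_that("fit_appearance is scale-equivariant and guards its domain", {
  t <- seq(0, 4000, by = 13)
  set.seed(6)
  counts <- pmax(0, 40 * (1 - exp(-t / 800)) + rnorm(length(t)))
  f1 <- fit_appearance(t, counts)
  f3 <- fit_appearance(t, 3 * counts)
  expect_equal(f3$A_sat, 3 * f1$A_sat, tolerance = 1e-6)
  expect_equal(f3$tau_init, f1$tau_init, tolerance = 1e-6)

  expect_error(fit_appearance(t, rep(0, length(t))), "degenerate")
  expect_error(fit_appearance(1:3, 1:3), ">= 5")
  expect_true(fit_appearance(t, rep(25, length(t)))$boundary)
})

test_that("appearance fit recovers the rate of a stochastic process", {
  # binomial appearance: 1000 complexes, rate 1/912 s^-1, 6.5 s bins;
  # per-seed sampling error is a few percent, so assess over 5 seeds
  t <- seq(0, 4000, by = 6.5)
  taus <- vapply(21:25, function(s) {
    cfg <- synthetic_config(n_complexes = 1000, k_init = 1 / 912,
                            c9_conc = 1, t_max = 4000,
                            image_shape = c(2048L, 2048L), seed = s)
    t_init <- vapply(simulate_assembly_events(cfg), `[[`, numeric(1),
                     "t_init")
    counts <- vapply(t, function(tt) sum(t_init <= tt), numeric(1))
    fit_appearance(t, counts)$tau_init
  }, numeric(1))
  expect_lt(abs(mean(taus) - 912) / 912, 0.05)
})

test_that("the initiation probability law behaves analytically", {
  expect_equal(p_init(0, 0.78, 1.4e-3), 0)
  expect_equal(p_init(1e9, 0.78, 1.4e-3), 1)
  expect_equal(p_init(912, 0.78, 1.4e-3), 0.6306, tolerance = 1e-4)
  expect_true(all(diff(p_init(seq(0, 5000, 50), 0.78, 1.4e-3)) >= 0))
  expect_error(p_init(-1, 0.78, 1.4e-3), ">= 0")
})

test_that("characteristic times convert to the printed rate constants", {
  expect_equal(signif(rate_constant(912, 1.4e-3), 2), 0.78)
  expect_equal(signif(rate_constant(6.6, 1.4e-3), 3), 108)
  expect_equal(rate_constant(1, 1), 1)
  expect_error(rate_constant(0, 1), "> 0")
  expect_error(rate_constant(1, -1), "> 0")

  expect_equal(signif(tau_plus_from_olig(112), 2), 6.6)
  expect_equal(tau_plus_from_olig(17, 17), 1)
  expect_error(tau_plus_from_olig(0), "> 0")
})

test_that("the occupancy solver matches the Poisson closed form", {
  lambda <- 1 / 6.6
  times <- seq(0, 198, by = 2)          # up to lambda * t = 30
  occ <- solve_occupancy(k_plus = lambda, c9 = 1, times = times)
  expect_equal(occ$p[1, ], c(1, rep(0, 17)))
  expect_lt(max(abs(rowSums(occ$p) - 1)), 1e-9)
  expect_true(all(occ$p >= -1e-12 & occ$p <= 1 + 1e-12))
  expect_true(all(diff(occ$p[, 1]) <= 1e-12))     # p_1 non-increasing
  expect_true(all(diff(occ$p[, 18]) >= -1e-12))   # p_18 non-decreasing

  # independent closed form: Poisson counts with absorbing final state
  closed <- sapply(0:16, function(m) dpois(m, lambda * times))
  closed <- cbind(closed, 1 - rowSums(closed))
  expect_lt(max(abs(occ$p - closed)), 1e-8)
  expect_error(solve_occupancy(1, 1, c(0, 2, 1)), "increasing")
})

test_that("occupancy frequencies match stochastic trajectories", {
  lambda <- 1 / 6.6
  cfg <- synthetic_config(n_complexes = 1000, k_init = 1e9,
                          k_plus = lambda, c9_conc = 1, t_max = Inf,
                          image_shape = c(2048L, 2048L), seed = 31)
  trs <- simulate_assembly_events(cfg)
  t_eval <- 30
  # state relative to initiation: 1 + additions completed within t_eval
  states <- vapply(trs, function(tr) {
    min(18L, 1L + sum(tr$t_additions - tr$t_init <= t_eval))
  }, integer(1))
  freq <- tabulate(states, nbins = 18) / length(states)
  occ <- solve_occupancy(lambda, 1, c(0, t_eval))
  p <- occ$p[2, ]
  se <- sqrt(pmax(p * (1 - p), 1e-12) / length(states))
  expect_true(all(abs(freq - p) <= 3 * se + 1e-12))
})

test_that("mean oligomer size grows linearly at rate k_plus * [C9]", {
  lambda <- 108 * 1.4e-3
  times <- seq(0, 200, by = 1)
  occ <- solve_occupancy(108, 1.4e-3, times)
  n_mean <- mean_oligomer_size(occ)
  expect_equal(n_mean[1], 1)
  expect_lt(abs(mean_growth_slope(occ) - lambda) / lambda, 0.01)

  late <- solve_occupancy(108, 1.4e-3, c(0, 1e4))
  expect_equal(mean_oligomer_size(late)[2], 18, tolerance = 1e-6)
})

test_that("estimate_kinetics reproduces the worked example", {
  t <- seq(0, 4000, by = 6.5)
  app <- fit_appearance(t, 50 * (1 - exp(-t / 912)))
  kin <- estimate_kinetics(app, list(mean = 112), c9 = 1.4e-3)
  expect_equal(signif(kin$k_init, 2), 0.78)
  expect_equal(signif(kin$k_plus, 3), 108)
  expect_equal(signif(kin$tau_plus, 2), 6.6)
  expect_equal(kin$n_max, 18L)
  expect_gt(kin$timescale_ratio, 100)
  expect_equal(kin$timescale_ratio, 912 / (112 / 17), tolerance = 1e-6)

  sym <- estimate_kinetics(app, list(mean = 912), c9 = 1.4e-3,
                           n_additions = 1L)
  expect_equal(sym$k_init, sym$k_plus, tolerance = 1e-6)
})
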