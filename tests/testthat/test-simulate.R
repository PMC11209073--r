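test_that("fatigue recurrence matches its closed form and limits", {
  # zero fixed point and no-decay limit
  expect_equal(fatigue_update(0, 0, tau_f = 7, k_f = 0.5), 0)
  expect_equal(fatigue_update(1, 0, tau_f = 1e12, k_f = 0.5), 1,
               tolerance = 1e-9)
  # hand-computed: 2 * 0.8668779 + 0.5 * 1 = 2.2337559
  expect_equal(fatigue_update(2, 1, tau_f = 7, k_f = 0.5), 2.2337559,
               tolerance = 1e-6)
  # vectorized over days via the series helper
  f <- fatigue_series(c(1, 0, 0), tau_f = 7, k_f = 0.5)
  expect_equal(f, c(0.5, 0.5 * exp(-1 / 7), 0.5 * exp(-2 / 7)))
  expect_error(fatigue_update(1, 1, tau_f = 0, k_f = 1), "tau_f")
  expect_error(fatigue_update(-1, 1, tau_f = 7, k_f = 1), "non-negative")
})

test_that("session features obey their ordering invariants in bulk", {
  expect_error(session_features(numeric(0)), "no sessions")
  expect_error(session_features(c(5000, 0)), "positive")
  set.seed(42)
  f <- session_features(runif(10000, 2000, 9000))
  expect_true(all(f$dist_gt_25_2 <= f$dist_gt_7_2))
  expect_true(all(f$dist_gt_7_2 <= f$total_distance))
  expect_true(all(f$n_acc_gt_3_5 <= f$n_acc_gt_2_5))
  expect_true(all(f$n_dec_lt_m3_5 <= f$n_dec_lt_m2_5))
  expect_true(all(f$max_dec < 0 & f$max_acc > 0))
  # deterministic under a fixed RNG state
  set.seed(7); a <- session_features(5000)
  set.seed(7); b <- session_features(5000)
  expect_identical(a, b)
})

test_that("measured PlayerLoad follows the inflation model exactly", {
  set.seed(3)
  f <- session_features(rep(5000, 50))
  cf <- base_pl_coeffs()
  base <- as.matrix(f[lei_predictors()]) %*% cf[lei_predictors()]
  expect_equal(true_playerload(f, cf), drop(base))
  expect_equal(true_playerload(f, cf, fatigue = 2, gamma = 0.1),
               drop(base) * 1.2)
  # Monte Carlo: mean of noisy draws within 3 SE of the closed form
  set.seed(4)
  n_rep <- 10000
  one <- f[1, , drop = FALSE]
  draws <- true_playerload(one[rep(1, n_rep), ], cf, noise_sd = 12)
  expect_lt(abs(mean(draws) - drop(base)[1]), 3 * 12 / sqrt(n_rep))
  expect_error(true_playerload(f, cf, fatigue = -1), "non-negative")
})

test_that("squad simulation has the promised shape and determinism", {
  cfg <- squad_config(n_players = 2, n_weeks = 4, sessions_per_week = 6,
                      second_session_prob = 0, unload_prob = 0,
                      overload_prob = 0, seed = 11)
  sim <- simulate_squad(cfg)
  expect_equal(nrow(sim$sessions), 2 * 4 * 6)  # single-session days
  expect_equal(nrow(sim$truth), 2 * 4 * 7)
  # byte-identical under an identical config
  sim2 <- simulate_squad(cfg)
  expect_identical(sim, sim2)
  # ordering invariants on every emitted row
  s <- small_sim(seed = 5)$sessions
  expect_true(all(s$dist_gt_25_2 <= s$dist_gt_7_2 &
                    s$dist_gt_7_2 <= s$total_distance))
  expect_true(all(s$n_acc_gt_3_5 <= s$n_acc_gt_2_5 &
                    s$n_dec_lt_m3_5 <= s$n_dec_lt_m2_5))
  expect_true(all(s$player_load > 0))
})

test_that("latent fatigue decays geometrically and is inert when disabled", {
  sim <- small_sim(seed = 9)
  tr <- sim$truth
  tau <- sim$config$tau_f
  # rest days (no impulse): exact one-day decay ratio exp(-1/tau)
  rest <- which(tr$impulse == 0)
  rest <- rest[rest > 1 & tr$player_id[rest] == tr$player_id[rest - 1] &
                 tr$fatigue[rest - 1] > 0]
  expect_gt(length(rest), 0)
  expect_equal(tr$fatigue[rest] / tr$fatigue[rest - 1],
               rep(exp(-1 / tau), length(rest)), tolerance = 1e-12)
  expect_true(all(tr$fatigue >= 0))
  # k_f = 0: fatigue identically zero, and PlayerLoad matches a gamma = 0
  # run with the same seed (fatigue never enters the measurement)
  off <- simulate_squad(squad_config(n_players = 3, n_weeks = 4, seed = 2,
                                     k_f = 0))
  expect_true(all(off$truth$fatigue == 0))
  g0 <- simulate_squad(squad_config(n_players = 3, n_weeks = 4, seed = 2,
                                    gamma = 0))
  expect_equal(off$sessions$player_load, g0$sessions$player_load)
})

test_that("heavier weeks raise next week's latent fatigue", {
  for (seed in 1:5) {
    sim <- simulate_squad(squad_config(n_players = 5, n_weeks = 10,
                                       seed = seed))
    tr <- sim$truth
    wk <- week_of(tr$date, origin = sim$config$start_date)
    imp <- aggregate(list(imp = tr$impulse),
                     by = list(player = tr$player_id, week = wk), FUN = sum)
    fat <- aggregate(list(fat = tr$fatigue),
                     by = list(player = tr$player_id, week = wk), FUN = mean)
    m <- merge(imp, fat)
    m <- m[order(m$player, m$week), ]
    lag_ok <- with(m, player[-nrow(m)] == player[-1] &
                     week[-1] == week[-nrow(m)] + 1)
    x <- m$imp[-nrow(m)][lag_ok]   # weekly summed impulse
    y <- m$fat[-1][lag_ok]         # next week's mean fatigue
    expect_gt(cor(x, y), 0)
  }
})

test_that("simulator CSV round-trips through the documented schema", {
  sim <- simulate_squad(squad_config(n_players = 2, n_weeks = 2, seed = 8))
  dir <- tempfile()
  paths <- write_squad_csv(sim, dir)
  back <- read.csv(file.path(dir, "sessions.csv"))
  expect_equal(nrow(back), nrow(sim$sessions))
  expect_equal(as.Date(back$date), sim$sessions$date)
  expect_equal(back$player_load, sim$sessions$player_load)
  unlink(dir, recursive = TRUE)
})
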