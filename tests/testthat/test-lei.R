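test_that("residual sign convention: positive means efficient", {
  expect_equal(delta_playerload(300, 300), 0)
  expect_equal(delta_playerload(320, 300), 20)
  expect_equal(delta_playerload(300, 320), -20)
  expect_error(delta_playerload(NA, 300), "finite")
})

test_that("per-player standardization is an exact z-score", {
  z <- standardize_player(c(1, 2, 3), rep("A", 3), min_sessions = 3)
  expect_equal(as.numeric(z), c(-1, 0, 1))
  # affine invariance: a * delta + b (a > 0) leaves the index unchanged
  set.seed(1)
  d <- rnorm(40)
  id <- rep(c("A", "B"), each = 20)
  z1 <- standardize_player(d, id)
  z2 <- standardize_player(3.7 * d + 11, id)
  expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 1e-12)
  # constant series: excluded, never divided by zero
  expect_warning(
    zc <- standardize_player(c(rep(5, 20), rnorm(20)), id),
    "zero_spread")
  expect_true(all(is.na(zc[1:20])))
  expect_true(all(!is.na(zc[21:40])))
  # short series: excluded for sample size
  expect_warning(
    zs <- standardize_player(c(1, 2, rnorm(20)), rep(c("A", "B"), c(2, 20))),
    "below_min_sessions")
  expect_true(all(is.na(zs[1:2])))
})

test_that("two-a-day sessions average into one daily value", {
  d <- data.frame(player_id = c("A", "A", "A", "B"),
                  date = as.Date("2021-08-02") + c(0, 0, 1, 0),
                  lei = c(0.2, 0.6, 0.4, -1))
  out <- aggregate_daily(d)
  expect_equal(nrow(out), 3)
  expect_equal(out$lei[out$player_id == "A" &
                         out$date == as.Date("2021-08-02")], 0.4)
  out3 <- aggregate_daily(data.frame(player_id = "A",
                                     date = as.Date("2021-08-02"),
                                     lei = c(-1, 0, 1)))
  expect_equal(out3$lei, 0)
})

test_that("load model validates its inputs and is seed-deterministic", {
  s <- small_sim(seed = 2)$sessions
  expect_error(fit_load_model(s[setdiff(names(s), "max_speed")]),
               "missing columns")
  expect_error(fit_load_model(s[1:10, ]), "at least 50")
  expect_error(fit_load_model(s, folds = nrow(s) + 1), "folds")
  m1 <- fit_load_model(s, regressor = "rf", ntree = 30, seed = 4)
  m2 <- fit_load_model(s, regressor = "rf", ntree = 30, seed = 4)
  expect_identical(m1$pl_pred, m2$pl_pred)
  # constant target: every prediction equals that constant
  s0 <- s
  s0$player_load <- 250
  for (reg in c("rf", "lm")) {
    m <- fit_load_model(s0, regressor = reg, ntree = 20, seed = 1)
    expect_equal(unname(m$pl_pred), rep(250, nrow(s0)), tolerance = 1e-8)
  }
})

test_that("out-of-fold predictions never come from a fold containing the
          session", {
  s <- small_sim(seed = 3)$sessions
  m <- fit_load_model(s, regressor = "lm", folds = 5, seed = 1)
  expect_equal(sort(unique(m$fold_id)), 1:5)
  # refit fold 1's model by hand and confirm the held-out predictions
  preds <- lei_predictors()
  train <- data.frame(y = s$player_load[m$fold_id != 1],
                      s[m$fold_id != 1, preds])
  fit <- lm(y ~ ., data = train)
  expect_equal(unname(m$pl_pred[m$fold_id == 1]),
               unname(predict(fit, s[m$fold_id == 1, preds])),
               tolerance = 1e-9)
})

test_that("noiseless linear world: out-of-fold model recovers the truth", {
  sim <- simulate_squad(squad_config(n_players = 5, n_weeks = 8,
                                     noise_sd = 0, gamma = 0, coeff_sd = 0,
                                     seed = 6))
  m <- fit_load_model(sim$sessions, regressor = "lm", seed = 1)
  resid <- m$pl_pred - sim$sessions$player_load
  r2 <- 1 - sum(resid^2) /
    sum((sim$sessions$player_load - mean(sim$sessions$player_load))^2)
  expect_gte(r2, 0.95)
  expect_lt(max(abs(resid)), 1e-6)
  # the random-forest ensemble approximates the same truth out of fold
  mrf <- fit_load_model(sim$sessions, regressor = "rf", ntree = 100,
                        seed = 1)
  rrf <- mrf$pl_pred - sim$sessions$player_load
  r2rf <- 1 - sum(rrf^2) /
    sum((sim$sessions$player_load - mean(sim$sessions$player_load))^2)
  expect_gt(r2rf, 0.8)
})

test_that("lei() standardizes every retained player to mean 0, sd 1", {
  sim <- small_sim(seed = 4)
  fit <- lei(sim$sessions, regressor = "lm", min_sessions = 10)
  r <- fit$records[!is.na(fit$records$lei), ]
  mu <- tapply(r$lei, r$player_id, mean)
  s <- tapply(r$lei, r$player_id, sd)
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(s - 1) < 1e-9))
  expect_identical(residuals(fit), fit$records$delta_pl)
  expect_identical(fitted(fit), fit$records$pl_pred)
  expect_equal(nrow(daily_lei(fit)),
               nrow(unique(r[c("player_id", "date")])))
})

test_that("session LEI falls when latent fatigue is high", {
  for (seed in 1:5) {
    sim <- simulate_squad(squad_config(n_players = 8, n_weeks = 10,
                                       seed = seed))
    fit <- lei(sim$sessions, regressor = "lm", min_sessions = 10)
    r <- fit$records
    key <- paste(r$player_id, r$date)
    tkey <- paste(sim$truth$player_id, sim$truth$date)
    f <- sim$truth$fatigue[match(key, tkey)]
    expect_lt(cor(f, r$lei, method = "spearman", use = "complete.obs"), 0)
  }
})
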