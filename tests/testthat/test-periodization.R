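test_that("participation filter keeps exactly the 60% boundary", {
  dates <- as.Date("2021-07-05") + 0:99
  sessions <- rbind(
    data.frame(player_id = "A", date = dates[1:59]),    # 59% -> out
    data.frame(player_id = "B", date = dates[1:60]),    # 60% -> kept
    data.frame(player_id = "C", date = dates))          # 100% -> kept
  out <- filter_participation(sessions, schedule = dates, threshold = 0.60)
  expect_setequal(unique(out$player_id), c("B", "C"))
  expect_equal(attr(out, "excluded_players")$player_id, "A")
  expect_error(filter_participation(sessions, schedule = as.Date(character())),
               "empty")
})

test_that("weekly readiness follows the mean weekly LEI and its cutoffs", {
  mk <- function(leis) {
    n <- length(leis)
    days <- as.Date("2021-07-05") + seq_len(n) - 1
    sessions <- data.frame(player_id = "A", date = days,
                           total_distance = 5000, dist_gt_25_2 = 40,
                           n_acc_gt_3_5 = 10, n_dec_lt_m3_5 = 12)
    daily <- data.frame(player_id = "A", date = days, lei = leis)
    weekly_summaries(daily, sessions)
  }
  expect_equal(as.character(mk(c(0.8, 0.7, 0.9))$readiness), "good")
  expect_equal(mk(c(0.8, 0.7, 0.9))$weekly_lei, 0.8)
  expect_equal(as.character(mk(c(-0.6, -0.6))$readiness), "bad")
  # boundary: exactly -0.5 and +0.5 are normal (closed interval)
  expect_equal(as.character(mk(c(-0.5, -0.5))$readiness), "normal")
  expect_equal(as.character(mk(c(0.5, 0.5))$readiness), "normal")
  # loads are weekly sums, LEI a weekly mean
  w <- mk(c(0, 0, 0))
  expect_equal(w$total_distance, 15000)
  expect_equal(w$mechanical_load, 3 * 22)
  expect_equal(w$n_sessions, 3L)
})

test_that("percentage change matches the worked example and identities", {
  expect_equal(pct_change(200, 100), -50)   # 50% reduction
  expect_equal(200 - 100, 100)              # absolute fall of 100 m
  expect_equal(pct_change(150, 150), 0)
  expect_equal(pct_change(1000, 1300), 30)
  expect_warning(out <- pct_change(c(0, 100), c(50, 110)), "undefined")
  expect_true(is.na(out[1]) && out[2] == 10)
  expect_error(pct_change(-5, 10), ">= 0")
  # exact inverse identity over a grid
  a <- rep(c(10, 250, 5000), each = 41)
  x <- rep(seq(-100, 100, by = 5), times = 3)
  expect_equal(pct_change(a, a * (1 + x / 100)), x, tolerance = 1e-9)
})

test_that("fluctuation classes partition the percentage axis monotonically", {
  expect_equal(as.character(classify_fluctuation(-50)), "large_decrease")
  expect_equal(as.character(classify_fluctuation(0)), "no_variation")
  # boundary conventions
  expect_equal(as.character(classify_fluctuation(c(-30, -10, 10, 30))),
               c("moderate_decrease", "no_variation", "no_variation",
                 "moderate_increase"))
  # exhaustive sweep: total, single-valued, monotone
  pct <- seq(-100, 100, by = 1)
  cl <- classify_fluctuation(pct)
  expect_true(!anyNA(cl))
  expect_true(all(diff(as.integer(cl)) >= 0))
  expect_error(classify_fluctuation(Inf), "finite")
})

test_that("LEI variation is the signed difference, most recent week first", {
  expect_equal(lei_variation(0.2, 0.2), 0)
  expect_equal(lei_variation(-0.8, 0.1), 0.9)
  expect_equal(lei_variation(0.5, -0.5), -1)
  expect_error(lei_variation(NA, 0), "finite")
})

test_that("transitions pair consecutive qualifying weeks only", {
  w <- toy_weeks("A", 1:4, total_distance = c(10000, 9000, 11000, 10000),
                 weekly_lei = c(0, 0.2, -0.1, 0.3))
  t1 <- build_transitions(w)
  expect_equal(nrow(t1), 3)
  expect_equal(t1$week_from, 1:3)
  # a gap breaks the chain
  t2 <- build_transitions(w[w$week_index != 3, ])
  expect_equal(nrow(t2), 1)
  expect_equal(t2$week_from, 1)
  # a short week (few sessions) is not a transition endpoint
  w$n_sessions[2] <- 2
  t3 <- build_transitions(w, min_week_sessions = 3)
  expect_equal(t3$week_from, 3)
  # readiness_ref comes from the earlier week by default
  expect_equal(as.character(t1$readiness_ref),
               as.character(w$readiness[1:3]))
})

test_that("hand-set fixture classifies as worked out on paper", {
  # 3 players x 5 weeks of total distance; categories checked by hand
  w <- rbind(
    toy_weeks("A", 1:5, c(10000, 10500, 6500, 9500, 13000)),
    toy_weeks("B", 1:5, c(8000, 5000, 5400, 6200, 6100)),
    toy_weeks("C", 1:5, c(12000, 12100, 14000, 17000, 9000)))
  tr <- build_transitions(w)
  expect_equal(nrow(tr), 12)
  hand <- c(
    # A: +5%, -38.1%, +46.2%, +36.8%
    "no_variation", "large_decrease", "large_increase", "large_increase",
    # B: -37.5%, +8%, +14.8%, -1.6%
    "large_decrease", "no_variation", "moderate_increase", "no_variation",
    # C: +0.8%, +15.7%, +21.4%, -47.1%
    "no_variation", "moderate_increase", "moderate_increase",
    "large_decrease")
  expect_equal(as.character(tr$cat_total_distance), hand)
  # per-category counts sum to the number of transitions emitted
  expect_equal(sum(table(tr$cat_total_distance)), nrow(tr))
  # zero previous-week load: transition dropped for that metric, counted
  w0 <- toy_weeks("D", 1:2, c(5000, 6000), dist_gt_25_2 = c(0, 50))
  tr0 <- suppressWarnings(build_transitions(w0))
  expect_true(is.na(tr0$pct_dist_gt_25_2))
  expect_equal(attr(tr0, "dropped_zero_load")[["dist_gt_25_2"]], 1L)
})
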