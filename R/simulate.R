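#' Configuration for the squad simulator
#'
#' Describes a simulated football squad monitored over one or two seasons:
#' squad size, weekly schedule, the latent fatigue dynamics (an
#' impulse-response recurrence driven by daily training dose), how fatigue
#' inflates measured PlayerLoad relative to locomotor output, and how
#' unload/overload weeks are programmed.
#'
#' The latent state of player *i* evolves daily as
#' \deqn{F_t = F_{t-1} e^{-1/\tau_f} + k_f u_t}
#' where \eqn{u_t} is the day's training dose (session distance divided by the
#' player's habitual session volume, so a typical training day has dose ~1).
#' Measured PlayerLoad is a linear combination of the seven locomotor
#' predictors multiplied by \eqn{1 + \gamma F} plus Gaussian noise: fatigued
#' players accumulate more body load for the same locomotor output.
#'
#' @param n_players Squad size.
#' @param n_weeks Number of simulated weeks (weeks beyond `season_length` are
#'   tagged season 2).
#' @param sessions_per_week Session days per week: `sessions_per_week - 1`
#'   training days plus one Saturday match.
#' @param tau_f Fatigue decay time constant, days.
#' @param k_f Fatigue gain per unit daily dose (dimensionless).
#' @param gamma PlayerLoad inflation per unit fatigue (dimensionless).
#' @param noise_sd Measurement noise on session PlayerLoad, arbitrary units.
#' @param unload_prob,overload_prob Probability that a player-week is
#'   programmed as an unload (volume x `unload_scale` and `unload_drop_days`
#'   training day(s) removed) or an overload (volume x `overload_scale` and
#'   second sessions at `overload_second_prob`).
#' @param unload_scale,overload_scale Planned-volume multipliers for
#'   programmed unload/overload weeks. Combined with the dropped day /
#'   added second sessions these swing the weekly dose by roughly +/- 35%.
#' @param unload_drop_days Training days removed in an unload week (the
#'   heaviest days of the microcycle go first).
#' @param overload_second_prob Second-session probability on training days of
#'   an overload week.
#' @param week_jitter_sd SD of the log-normal week-to-week jitter on planned
#'   volume (populates the moderate fluctuation categories).
#' @param second_session_prob Probability a training day carries a second,
#'   half-volume session.
#' @param match_multiplier Planned-volume multiplier for match days.
#' @param base_volume_mean,base_volume_sd Across-player distribution of
#'   habitual training-session distance, metres.
#' @param coeff_sd SD of per-player multiplicative variation around the squad
#'   PlayerLoad coefficients (player-to-player efficiency heterogeneity).
#'   Set to 0 for a truth exactly representable by one pooled linear model.
#' @param season_length Weeks per season, used only for the season tag.
#' @param start_date First simulated day; must be a Monday (weeks are
#'   Monday-anchored).
#' @param seed Integer seed; the simulator is a pure function of the config.
#' @return A validated list of class `squad_config`.
#' @seealso [simulate_squad()]
#' @export
squad_config <- function(n_players = 100, n_weeks = 80, sessions_per_week = 6,
                         tau_f = 3.5, k_f = 0.25, gamma = 0.10, noise_sd = 10,
                         unload_prob = 0.2, overload_prob = unload_prob,
                         unload_scale = 0.75, overload_scale = 1.15,
                         unload_drop_days = 1, overload_second_prob = 0.6,
                         week_jitter_sd = 0.08, second_session_prob = 0.1,
                         match_multiplier = 1.3,
                         base_volume_mean = 5000, base_volume_sd = 500,
                         coeff_sd = 0.05, season_length = 40,
                         start_date = as.Date("2021-07-05"), seed = 1) {
  cfg <- list(n_players = as.integer(n_players), n_weeks = as.integer(n_weeks),
              sessions_per_week = as.integer(sessions_per_week),
              tau_f = tau_f, k_f = k_f, gamma = gamma, noise_sd = noise_sd,
              unload_prob = unload_prob, overload_prob = overload_prob,
              unload_scale = unload_scale, overload_scale = overload_scale,
              unload_drop_days = as.integer(unload_drop_days),
              overload_second_prob = overload_second_prob,
              week_jitter_sd = week_jitter_sd,
              second_session_prob = second_session_prob,
              match_multiplier = match_multiplier,
              base_volume_mean = base_volume_mean,
              base_volume_sd = base_volume_sd, coeff_sd = coeff_sd,
              season_length = as.integer(season_length),
              start_date = as.Date(start_date), seed = as.integer(seed))
  stopifnot(cfg$n_players >= 1, cfg$n_weeks >= 1,
            cfg$sessions_per_week >= 1, cfg$sessions_per_week <= 7)
  if (!is.finite(cfg$tau_f) || cfg$tau_f <= 0)
    stop("tau_f must be a positive number of days")
  if (cfg$k_f < 0 || cfg$gamma < 0 || cfg$noise_sd < 0 || cfg$coeff_sd < 0)
    stop("k_f, gamma, noise_sd and coeff_sd must be non-negative")
  for (p in c("unload_prob", "overload_prob", "second_session_prob",
              "overload_second_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (cfg$unload_drop_days < 0 ||
      cfg$unload_drop_days > max(0L, cfg$sessions_per_week - 2L))
    stop("unload_drop_days must leave at least one training day")
  if (cfg$unload_prob + cfg$overload_prob > 1)
    stop("unload_prob + overload_prob must not exceed 1")
  stopifnot(cfg$unload_scale > 0, cfg$overload_scale > 0,
            cfg$match_multiplier > 0, cfg$base_volume_mean > 0)
  if (format(cfg$start_date, "%u") != "1")
    stop("start_date must be a Monday (weeks are Monday-anchored)")
  structure(cfg, class = "squad_config")
}

#' @export
#' @method print squad_config
print.squad_config <- function(x, ...) {
  cat("Squad simulator configuration\n")
  cat(sprintf("  %d players, %d weeks, %d session days/week (match Saturday)\n",
              x$n_players, x$n_weeks, x$sessions_per_week))
  cat(sprintf("  fatigue: tau_f = %g d, k_f = %g; PL inflation gamma = %g\n",
              x$tau_f, x$k_f, x$gamma))
  cat(sprintf("  noise sd = %g AU; unload/overload prob = %g/%g; seed = %d\n",
              x$noise_sd, x$unload_prob, x$overload_prob, x$seed))
  invisible(x)
}

#' One step of the latent fatigue recurrence
#'
#' `F_new = F_prev * exp(-1/tau_f) + k_f * impulse`: yesterday's fatigue
#' decays geometrically and today's training dose adds to it. Vectorized.
#'
#' @param f_prev Fatigue before the day (non-negative).
#' @param impulse Daily training dose in player-normalized units
#'   (session distance / habitual session volume).
#' @param tau_f Decay time constant, days (> 0).
#' @param k_f Gain per unit dose (>= 0).
#' @return Updated fatigue, same length as the inputs.
#' @examples
#' fatigue_update(2, 1, tau_f = 7, k_f = 0.5)
#' @export
fatigue_update <- function(f_prev, impulse, tau_f, k_f) {
  if (!is.numeric(tau_f) || length(tau_f) != 1L || !is.finite(tau_f) ||
      tau_f <= 0)
    stop("tau_f must be a single positive number of days")
  if (any(f_prev < 0)) stop("f_prev must be non-negative")
  if (any(impulse < 0)) stop("impulse must be non-negative")
  if (k_f < 0) stop("k_f must be non-negative")
  f_prev * exp(-1 / tau_f) + k_f * impulse
}

# Full fatigue trajectory for one player from a daily impulse series,
# starting at F = 0 before day 1.
fatigue_series <- function(impulse, tau_f, k_f) {
  as.numeric(stats::filter(k_f * impulse, exp(-1 / tau_f),
                           method = "recursive"))
}

# Squad-level PlayerLoad coefficients over the seven predictors. Scaled so a
# typical 5 km training session lands near 370 AU.
base_pl_coeffs <- function() {
  c(total_distance = 0.045, dist_gt_7_2 = 0.02, n_acc_gt_2_5 = 0.5,
    n_dec_lt_m2_5 = 0.5, max_speed = 1.0, max_acc = 4.0, max_dec = -4.0)
}

#' Draw session-level locomotor features
#'
#' Generates the GPS summary metrics of one or more sessions from documented
#' distributions scaled by the planned session volume. Construction is nested
#' (high-speed distance is a fraction of running distance, which is a fraction
#' of total distance; hard accelerations are a binomial thinning of moderate
#' ones) so the ordering invariants hold in every draw. Uses the current R
#' RNG stream.
#'
#' @param planned_volume Planned session distance(s), metres (> 0).
#' @param session_type `"training"` or `"match"` (recycled); carried through
#'   to the output.
#' @return A data frame with one row per session: `total_distance`,
#'   `dist_gt_7_2`, `dist_gt_25_2`, `n_acc_gt_2_5`, `n_dec_lt_m2_5`,
#'   `n_acc_gt_3_5`, `n_dec_lt_m3_5`, `max_speed`, `max_acc`, `max_dec`.
#' @examples
#' set.seed(1)
#' session_features(c(5000, 6500))
#' @export
session_features <- function(planned_volume, session_type = "training") {
  if (length(planned_volume) == 0L) stop("no sessions requested")
  if (any(!is.finite(planned_volume)) || any(planned_volume <= 0))
    stop("planned_volume must be positive and finite")
  n <- length(planned_volume)
  total <- planned_volume * rlnorm(n, 0, 0.05)
  frac_run <- stats::plogis(rnorm(n, stats::qlogis(0.35), 0.20))
  dist7 <- total * frac_run
  frac_hs <- stats::plogis(rnorm(n, stats::qlogis(0.018), 0.35))
  dist25 <- dist7 * frac_hs
  acc2 <- rpois(n, total / 100)
  dec2 <- rpois(n, total / 95)
  acc3 <- rbinom(n, acc2, 0.30)
  dec3 <- rbinom(n, dec2, 0.30)
  data.frame(
    session_type = rep_len(as.character(session_type), n),
    total_distance = total, dist_gt_7_2 = dist7, dist_gt_25_2 = dist25,
    n_acc_gt_2_5 = acc2, n_dec_lt_m2_5 = dec2,
    n_acc_gt_3_5 = acc3, n_dec_lt_m3_5 = dec3,
    max_speed = pmax(18, rnorm(n, 28, 1.5)),
    max_acc = pmax(2.5, rnorm(n, 3.8, 0.25)),
    max_dec = -pmax(2.5, rnorm(n, 4.1, 0.25)))
}

#' Measured PlayerLoad under the latent fatigue state
#'
#' The fatigue-free PlayerLoad of a session is the linear combination of the
#' seven locomotor predictors with the player's efficiency coefficients;
#' fatigue inflates it multiplicatively by `1 + gamma * fatigue`, Gaussian
#' measurement noise is added, and the result is floored at a small positive
#' value.
#'
#' @param features Data frame or matrix holding the seven predictor columns.
#' @param coeffs Named coefficient vector over the predictors, or a matrix
#'   with one row per session (per-player coefficients).
#' @param fatigue Latent fatigue at the session (>= 0), recycled.
#' @param gamma Inflation per unit fatigue (>= 0).
#' @param noise_sd Measurement noise SD, PlayerLoad units (>= 0); draws use
#'   the current R RNG stream.
#' @return Session PlayerLoad, arbitrary units, strictly positive.
#' @examples
#' set.seed(1)
#' f <- session_features(5000)
#' cf <- c(total_distance = 0.045, dist_gt_7_2 = 0.02, n_acc_gt_2_5 = 0.5,
#'         n_dec_lt_m2_5 = 0.5, max_speed = 1, max_acc = 4, max_dec = -4)
#' true_playerload(f, cf, fatigue = 1, gamma = 0.1)
#' @export
true_playerload <- function(features, coeffs, fatigue = 0, gamma = 0,
                            noise_sd = 0) {
  preds <- lei_predictors()
  x <- as.matrix(as.data.frame(features)[preds])
  if (any(fatigue < 0)) stop("fatigue must be non-negative")
  if (gamma < 0 || noise_sd < 0) stop("gamma and noise_sd must be >= 0")
  if (is.matrix(coeffs)) {
    stopifnot(nrow(coeffs) == nrow(x))
    base <- rowSums(x * coeffs[, preds, drop = FALSE])
  } else {
    base <- drop(x %*% coeffs[preds])
  }
  pl <- base * (1 + gamma * fatigue)
  if (noise_sd > 0) pl <- pl + rnorm(nrow(x), 0, noise_sd)
  pmax(pl, 1)
}

#' Simulate a longitudinally monitored squad
#'
#' Generates per-session GPS/accelerometer summaries for a squad over one or
#' two seasons, together with the latent ground-truth fatigue state of every
#' player-day, under the impulse-response dynamics described in
#' [squad_config()]. Each week is programmed as normal, unload or overload
#' volume; matches are Saturday volume peaks; a fraction of training days
#' carry a second, lighter session. The output is a pure function of the
#' configuration (including its seed).
#'
#' @param config A [squad_config()].
#' @return A list of class `squad_sim`:
#' \describe{
#'   \item{sessions}{one row per session: `player_id`, `date`, `season`,
#'     `week_index`, `session_index_in_day`, `session_type`, the ten
#'     locomotor metrics, `player_load`.}
#'   \item{truth}{one row per player-day (rest days included): `player_id`,
#'     `date`, `impulse`, `fatigue` (end-of-day latent state).}
#'   \item{players}{per-player habitual volume and PlayerLoad coefficients.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_squad(squad_config(n_players = 4, n_weeks = 6, seed = 2))
#' head(sim$sessions)
#' @export
simulate_squad <- function(config = squad_config()) {
  stopifnot(inherits(config, "squad_config"))
  cfg <- config
  with_seed(cfg$seed, {
    np <- cfg$n_players; nw <- cfg$n_weeks
    ids <- sprintf("P%03d", seq_len(np))
    base_volume <- pmax(3000, rnorm(np, cfg$base_volume_mean,
                                    cfg$base_volume_sd))
    bc <- base_pl_coeffs()
    coef_mat <- matrix(rep(bc, each = np), nrow = np,
                       dimnames = list(ids, names(bc)))
    coef_mat <- coef_mat * (1 + matrix(rnorm(np * length(bc), 0, cfg$coeff_sd),
                                       nrow = np))

    # programmed week types and week-level volume multipliers (player x week)
    u <- matrix(runif(np * nw), np, nw)
    wtype <- matrix("normal", np, nw)
    wtype[u < cfg$unload_prob] <- "unload"
    wtype[u >= cfg$unload_prob &
          u < cfg$unload_prob + cfg$overload_prob] <- "overload"
    wscale <- matrix(1, np, nw)
    wscale[wtype == "unload"] <- cfg$unload_scale
    wscale[wtype == "overload"] <- cfg$overload_scale
    wmult <- wscale * matrix(exp(rnorm(np * nw, 0, cfg$week_jitter_sd)), np, nw)

    # session-day layout within a week (0 = Monday): training days first
    # Mon-Fri, Sunday if a sixth is needed; the match is always Saturday
    n_train <- cfg$sessions_per_week - 1L
    train_days <- head(c(0L, 1L, 2L, 3L, 4L, 6L), n_train)
    match_day <- 5L
    # within-week volume profile: heavier mid-week, taper on the last
    # training day before the match (standard microcycle shape)
    day_profile <- setNames(c(0.95, 1.10, 1.05, 0.95, 0.70, 0.80),
                            c(0, 1, 2, 3, 4, 6))

    # session skeleton in deterministic order (player, week, day, index)
    grid <- expand.grid(day = sort(c(train_days, match_day)),
                        week = seq_len(nw), player = seq_len(np),
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$player, grid$week, grid$day), , drop = FALSE]
    grid$type <- ifelse(grid$day == match_day, "match", "training")
    wt_row <- wtype[cbind(grid$player, grid$week)]
    # overload weeks add second sessions; unload weeks drop the heaviest
    # training day(s) — weekly dose varies partly through session count
    second_p <- ifelse(grid$type == "training",
                       ifelse(wt_row == "overload", cfg$overload_second_prob,
                              cfg$second_session_prob), 0)
    second <- runif(nrow(grid)) < second_p
    if (cfg$unload_drop_days > 0L && length(train_days)) {
      heavy <- train_days[order(-day_profile[as.character(train_days)])]
      drop_days <- head(heavy, cfg$unload_drop_days)
      keep <- !(wt_row == "unload" & grid$day %in% drop_days)
      grid <- grid[keep, , drop = FALSE]
      second <- second[keep]
    }
    g1 <- grid; g1$idx <- 1L
    g2 <- grid[second, , drop = FALSE]
    g2$idx <- rep(2L, nrow(g2))
    skel <- rbind(g1, g2)
    skel <- skel[order(skel$player, skel$week, skel$day, skel$idx), ,
                 drop = FALSE]

    mult <- wmult[cbind(skel$player, skel$week)]
    planned <- base_volume[skel$player] * mult
    is_match <- skel$type == "match"
    planned[is_match] <- planned[is_match] * cfg$match_multiplier
    planned[!is_match] <- planned[!is_match] *
      day_profile[as.character(skel$day[!is_match])]
    planned[skel$idx == 2L] <- planned[skel$idx == 2L] * 0.5

    feats <- session_features(planned, skel$type)
    date <- cfg$start_date + (skel$week - 1L) * 7L + skel$day

    # latent fatigue per player-day over the full calendar
    all_days <- seq(cfg$start_date, by = 1, length.out = nw * 7L)
    nd <- length(all_days)
    day_of <- as.integer(date - cfg$start_date) + 1L
    imp <- matrix(0, np, nd)
    contr <- feats$total_distance / base_volume[skel$player]
    for (r in seq_len(nrow(skel)))
      imp[skel$player[r], day_of[r]] <- imp[skel$player[r], day_of[r]] +
        contr[r]
    fat <- t(apply(imp, 1, fatigue_series, tau_f = cfg$tau_f, k_f = cfg$k_f))
    if (np == 1L) fat <- matrix(fat, nrow = 1)
    # fatigue carried into a day: yesterday's end state after overnight decay
    fat_pre <- cbind(0, fat[, -nd, drop = FALSE]) * exp(-1 / cfg$tau_f)

    pl <- true_playerload(feats, coef_mat[skel$player, , drop = FALSE],
                          fatigue = fat_pre[cbind(skel$player, day_of)],
                          gamma = cfg$gamma, noise_sd = cfg$noise_sd)

    sessions <- data.frame(
      player_id = ids[skel$player], date = date,
      season = ifelse(skel$week <= cfg$season_length, 1L, 2L),
      week_index = skel$week, session_index_in_day = skel$idx,
      feats, player_load = pl)
    rownames(sessions) <- NULL

    truth <- data.frame(
      player_id = rep(ids, each = nd), date = rep(all_days, np),
      impulse = as.vector(t(imp)), fatigue = as.vector(t(fat)))

    players <- data.frame(player_id = ids, base_volume = base_volume,
                          coef_mat, check.names = FALSE)
    rownames(players) <- NULL
    structure(list(sessions = sessions, truth = truth, players = players,
                   config = cfg),
              class = "squad_sim")
  })
}

#' @export
#' @method print squad_sim
print.squad_sim <- function(x, ...) {
  cat("Simulated squad monitoring data\n")
  cat(sprintf("  %d players, %d weeks, %d sessions, %d player-days of truth\n",
              x$config$n_players, x$config$n_weeks, nrow(x$sessions),
              nrow(x$truth)))
  cat(sprintf("  mean session PlayerLoad: %.1f AU; mean end-of-day fatigue: %.2f\n",
              mean(x$sessions$player_load), mean(x$truth$fatigue)))
  invisible(x)
}

#' Write a simulated squad to CSV
#'
#' Emits `sessions.csv` and `ground_truth.csv` (ISO-8601 dates) under
#' `out_dir`.
#'
#' @param sim A `squad_sim`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_squad_csv <- function(sim, out_dir) {
  stopifnot(inherits(sim, "squad_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("sessions.csv", "ground_truth.csv"))
  write.csv(sim$sessions, paths[1], row.names = FALSE)
  write.csv(sim$truth, paths[2], row.names = FALSE)
  invisible(paths)
}
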