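#' Drop players with poor training continuity
#'
#' Removes players who attended fewer than `threshold` of the team's session
#' days (injuries, absences), mirroring standard practice in longitudinal
#' squad monitoring. A player attending exactly the threshold fraction is
#' retained (only strictly-below is excluded).
#'
#' @param sessions Session table with `player_id` and `date`.
#' @param schedule Vector of team session dates; defaults to every distinct
#'   date present in `sessions`.
#' @param threshold Minimum attended/scheduled fraction (default 0.60).
#' @return The retained rows of `sessions`; the exclusion table (player,
#'   attended, scheduled) is in `attr(, "excluded_players")`.
#' @export
filter_participation <- function(sessions, schedule = NULL, threshold = 0.60) {
  stopifnot(all(c("player_id", "date") %in% names(sessions)))
  if (is.null(schedule)) schedule <- unique(sessions$date)
  schedule <- unique(as.Date(schedule))
  if (length(schedule) == 0L) stop("team schedule is empty")
  players <- unique(as.character(sessions$player_id))
  attended <- vapply(players, function(p) {
    length(intersect(unique(sessions$date[sessions$player_id == p]), schedule))
  }, integer(1))
  ratio <- attended / length(schedule)
  drop <- players[ratio < threshold]
  excluded <- data.frame(player_id = drop,
                         attended = attended[match(drop, players)],
                         scheduled = rep(length(schedule), length(drop)),
                         ratio = ratio[match(drop, players)])
  out <- sessions[!(as.character(sessions$player_id) %in% drop), ,
                  drop = FALSE]
  attr(out, "excluded_players") <- excluded
  out
}

# Monday-anchored week index. Uses a `week_index` column if already present.
week_of <- function(date, origin = NULL) {
  date <- as.Date(date)
  if (is.null(origin)) {
    first <- min(date)
    origin <- first - (as.integer(format(first, "%u")) - 1L)
  }
  as.integer(floor(as.numeric(date - as.Date(origin)) / 7)) + 1L
}

#' Weekly load sums, mean LEI and readiness state
#'
#' Aggregates daily LEI and session loads into non-overlapping Monday-anchored
#' 7-day blocks, one row per player-week with at least one session. Weekly
#' load is the sum over all of the week's training sessions and matches for
#' three metrics: total distance, high-speed distance (> 25.2 km/h) and
#' mechanical load (count of accelerations > 3.5 m/s^2 plus decelerations
#' < -3.5 m/s^2). Weekly readiness follows the mean weekly LEI: below the
#' lower cutoff is `bad`, above the upper cutoff is `good`, the closed
#' interval between them is `normal`.
#'
#' @param daily Daily LEI table (`player_id`, `date`, `lei`), e.g.
#'   [daily_lei()].
#' @param sessions Session table with the load metric columns.
#' @param cutoffs Readiness cutoffs on weekly LEI, default `c(-0.5, 0.5)`.
#' @param origin Optional Monday anchoring the week grid; defaults to the
#'   Monday on or before the earliest session. Ignored when `sessions`
#'   carries a `week_index` column.
#' @return Data frame: `player_id`, `week_index`, (`season`,)
#'   `total_distance`, `dist_gt_25_2`, `mechanical_load`, `weekly_lei`,
#'   `readiness`, `n_sessions`.
#' @export
weekly_summaries <- function(daily, sessions, cutoffs = c(-0.5, 0.5),
                             origin = NULL) {
  stopifnot(all(c("player_id", "date", "lei") %in% names(daily)),
            cutoffs[1] < cutoffs[2])
  need <- c("player_id", "date", "dist_gt_25_2", "n_acc_gt_3_5",
            "n_dec_lt_m3_5", "total_distance")
  miss <- setdiff(need, names(sessions))
  if (length(miss)) stop("sessions table is missing: ",
                         paste(miss, collapse = ", "))
  if ("week_index" %in% names(sessions)) {
    sw <- sessions$week_index
    anchor <- min(sessions$date) - (sessions$week_index[
      which.min(sessions$date)] - 1L) * 7L
    dw <- week_of(daily$date, origin = anchor)
  } else {
    first <- min(sessions$date)
    anchor <- if (is.null(origin))
      first - (as.integer(format(first, "%u")) - 1L) else as.Date(origin)
    sw <- week_of(sessions$date, origin = anchor)
    dw <- week_of(daily$date, origin = anchor)
  }
  if (nrow(daily) == 0L)
    return(data.frame(player_id = character(), week_index = integer(),
                      total_distance = numeric(), dist_gt_25_2 = numeric(),
                      mechanical_load = numeric(), n_sessions = integer(),
                      weekly_lei = numeric(),
                      readiness = factor(character(),
                                         levels = readiness_levels())))
  mech <- sessions$n_acc_gt_3_5 + sessions$n_dec_lt_m3_5
  key <- list(player_id = as.character(sessions$player_id), week_index = sw)
  loads <- aggregate(cbind(total_distance = sessions$total_distance,
                           dist_gt_25_2 = sessions$dist_gt_25_2,
                           mechanical_load = mech),
                     by = key, FUN = sum)
  nses <- aggregate(list(n_sessions = rep(1L, nrow(sessions))),
                    by = key, FUN = sum)
  wlei <- aggregate(list(weekly_lei = daily$lei),
                    by = list(player_id = as.character(daily$player_id),
                              week_index = dw),
                    FUN = mean)
  out <- merge(merge(loads, nses, by = c("player_id", "week_index")),
               wlei, by = c("player_id", "week_index"))
  if ("season" %in% names(sessions)) {
    seas <- aggregate(list(season = sessions$season), by = key, FUN = max)
    out <- merge(out, seas, by = c("player_id", "week_index"))
  }
  out$readiness <- factor(
    ifelse(out$weekly_lei < cutoffs[1], "bad",
           ifelse(out$weekly_lei > cutoffs[2], "good", "normal")),
    levels = readiness_levels())
  out <- out[order(out$player_id, out$week_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage change between consecutive weekly loads
#'
#' `(load_w1 - load_w) / load_w * 100`, where `load_w1` is the most recent
#' week. A fall from 200 m to 100 m is a change of -50 (a 50% reduction).
#'
#' @param load_w Previous week's load (> 0; a zero denominator yields `NA`
#'   with a warning, and such transitions are dropped and counted upstream).
#' @param load_w1 Most recent week's load.
#' @return Percentage change, same length as the inputs.
#' @examples
#' pct_change(200, 100)
#' @export
pct_change <- function(load_w, load_w1) {
  if (any(!is.finite(load_w)) || any(!is.finite(load_w1)))
    stop("weekly loads must be finite")
  if (any(load_w < 0) || any(load_w1 < 0)) stop("weekly loads must be >= 0")
  out <- (load_w1 - load_w) / load_w * 100
  if (any(load_w == 0)) {
    warning("zero previous-week load: percentage change undefined (NA)",
            call. = FALSE)
    out[load_w == 0] <- NA_real_
  }
  out
}

#' Classify a week-to-week load fluctuation
#'
#' Bins the percentage change into five ordered categories. With the default
#' bounds (-30, -10, 10, 30): below -30 is a large decrease; \[-30, -10) a
#' moderate decrease; \[-10, 10\] no variation; (10, 30\] a moderate
#' increase; above 30 a large increase. The mapping is total and mutually
#' exclusive; endpoint inclusivity is a documented convention (the source
#' bounds are ambiguous at the endpoints) and configurable via `bounds`.
#'
#' @param pct Percentage change(s); must be finite (`NA` passes through).
#' @param bounds Increasing vector of four cut points.
#' @return Ordered factor with levels `large_decrease`, `moderate_decrease`,
#'   `no_variation`, `moderate_increase`, `large_increase`.
#' @examples
#' classify_fluctuation(c(-50, 0, 12, 31))
#' @export
classify_fluctuation <- function(pct, bounds = c(-30, -10, 10, 30)) {
  stopifnot(length(bounds) == 4, !is.unsorted(bounds, strictly = TRUE))
  if (any(is.nan(pct) | is.infinite(pct)))
    stop("percentage change must be finite")
  lv <- fluctuation_levels()
  out <- ifelse(pct < bounds[1], lv[1],
         ifelse(pct < bounds[2], lv[2],
         ifelse(pct <= bounds[3], lv[3],
         ifelse(pct <= bounds[4], lv[4], lv[5]))))
  factor(out, levels = lv, ordered = TRUE)
}

#' Signed week-to-week LEI variation
#'
#' Weekly LEI of the most recent week minus the preceding week. The sign is
#' kept (a positive value is an improvement in readiness) so that loading and
#' unloading effects remain distinguishable.
#'
#' @param lei_w,lei_w1 Weekly mean LEI of the previous and most recent week.
#' @return `lei_w1 - lei_w`.
#' @examples
#' lei_variation(-0.8, 0.1)
#' @export
lei_variation <- function(lei_w, lei_w1) {
  if (any(!is.finite(lei_w)) || any(!is.finite(lei_w1)))
    stop("weekly LEI values must be finite")
  lei_w1 - lei_w
}

#' Consecutive-week training-scenario table
#'
#' Builds one row per player per consecutive week pair in which both weeks
#' have at least `min_week_sessions` sessions: the percentage change and
#' fluctuation category for each load metric, the signed LEI variation, and
#' the reference readiness state conditioning the scenario.
#'
#' @param weeks A [weekly_summaries()] table.
#' @param min_week_sessions Minimum sessions for a week to enter a
#'   transition (default 3).
#' @param readiness_ref `"from"` (default; the readiness of the earlier week
#'   conditions next week's load prescription) or `"to"`.
#' @param bounds Fluctuation cut points, see [classify_fluctuation()].
#' @return Data frame with `player_id`, `week_from`, `week_to`, (`season`,)
#'   `pct_<metric>` and `cat_<metric>` for the three load metrics,
#'   `lei_variation`, `readiness_ref`. Transitions whose previous-week load
#'   is zero get `NA` for that metric; counts of such drops are in
#'   `attr(, "dropped_zero_load")`.
#' @export
build_transitions <- function(weeks, min_week_sessions = 3,
                              readiness_ref = c("from", "to"),
                              bounds = c(-30, -10, 10, 30)) {
  readiness_ref <- match.arg(readiness_ref)
  metrics <- load_metrics()
  stopifnot(all(c("player_id", "week_index", "weekly_lei", "readiness",
                  "n_sessions", metrics) %in% names(weeks)))
  w <- weeks[weeks$n_sessions >= min_week_sessions, , drop = FALSE]
  w <- w[order(w$player_id, w$week_index), , drop = FALSE]
  same <- as.character(w$player_id[-nrow(w)]) ==
    as.character(w$player_id[-1])
  consec <- w$week_index[-1] == w$week_index[-nrow(w)] + 1L
  i <- which(if (nrow(w) > 1) same & consec else logical(0))
  from <- w[i, , drop = FALSE]; to <- w[i + 1L, , drop = FALSE]
  out <- data.frame(player_id = as.character(from$player_id),
                    week_from = from$week_index, week_to = to$week_index)
  if ("season" %in% names(weeks)) out$season <- to$season
  dropped <- integer(0)
  for (m in metrics) {
    pct <- suppressWarnings(pct_change(from[[m]], to[[m]]))
    dropped[m] <- sum(is.na(pct))
    out[[paste0("pct_", m)]] <- pct
    out[[paste0("cat_", m)]] <- classify_fluctuation(pct, bounds)
  }
  out$lei_variation <- lei_variation(from$weekly_lei, to$weekly_lei)
  out$readiness_ref <- if (readiness_ref == "from") from$readiness else
    to$readiness
  rownames(out) <- NULL
  attr(out, "dropped_zero_load") <- dropped
  out
}
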