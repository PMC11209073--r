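# Small simulated squads shared across tests (built once per file load).
small_sim <- function(seed = 1, ...) {
  simulate_squad(squad_config(n_players = 6, n_weeks = 8, seed = seed, ...))
}

# Transitions-shaped table built by hand: `spec` is a data.frame with
# player_id, category (total-distance), y. Other metrics are filled with
# no_variation so scenario-level code has all columns.
toy_transitions <- function(player_id, category, y,
                            readiness = "normal") {
  n <- length(y)
  data.frame(
    player_id = player_id,
    week_from = seq_len(n), week_to = seq_len(n) + 1L,
    pct_total_distance = 0,
    cat_total_distance = factor(category, levels = fluctuation_levels()),
    pct_dist_gt_25_2 = 0,
    cat_dist_gt_25_2 = factor(category, levels = fluctuation_levels()),
    pct_mechanical_load = 0,
    cat_mechanical_load = factor(category, levels = fluctuation_levels()),
    lei_variation = y,
    readiness_ref = factor(readiness, levels = readiness_levels()))
}

# Week-summary table built by hand from per-week loads and LEIs.
toy_weeks <- function(player_id, week_index, total_distance,
                      dist_gt_25_2 = total_distance * 0.04,
                      mechanical_load = round(total_distance / 100),
                      weekly_lei = 0, n_sessions = 6) {
  data.frame(player_id = player_id, week_index = week_index,
             total_distance = total_distance, dist_gt_25_2 = dist_gt_25_2,
             mechanical_load = mechanical_load, weekly_lei = weekly_lei,
             readiness = factor(
               ifelse(weekly_lei < -0.5, "bad",
                      ifelse(weekly_lei > 0.5, "good", "normal")),
               levels = readiness_levels()),
             n_sessions = n_sessions)
}
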