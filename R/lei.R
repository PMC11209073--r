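#' Fit the session PlayerLoad model
#'
#' Regresses measured session PlayerLoad on the seven locomotor predictors
#' (total distance, running distance > 7.2 km/h, moderate acceleration and
#' deceleration counts, maximal speed, maximal acceleration, maximal
#' deceleration). Predictions are out-of-fold by default: sessions are split
#' into `folds` groups and each session's prediction comes from a model that
#' never saw it, so a flexible regressor cannot memorize the target and
#' collapse the residual.
#'
#' @param sessions Session table with the seven predictor columns and
#'   `player_load`.
#' @param scheme `"oof"` (out-of-fold, default) or `"insample"`.
#' @param folds Number of folds under `"oof"`.
#' @param regressor `"rf"` (random-forest-style ensemble, default) or `"lm"`
#'   (pooled linear model), or a function `f(x, y)` returning an object with a
#'   `predict(object, newdata)` method.
#' @param ntree Trees in the `"rf"` ensemble.
#' @param seed Seed controlling fold assignment and ensemble randomness.
#' @return An object of class `load_model`: the model fit on all sessions
#'   (used for new data), per-session predictions `pl_pred` aligned with
#'   `sessions`, the fold assignment, and metadata.
#' @export
fit_load_model <- function(sessions, scheme = c("oof", "insample"), folds = 5,
                           regressor = c("rf", "lm"), ntree = 200, seed = 1) {
  scheme <- match.arg(scheme)
  preds <- lei_predictors()
  missing_cols <- setdiff(c(preds, "player_load"), names(sessions))
  if (length(missing_cols))
    stop("sessions table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(sessions[preds])
  y <- sessions$player_load
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("predictors and player_load must be finite")
  n <- nrow(x)
  if (n < 50) stop("need at least 50 sessions to fit the load model")
  if (scheme == "oof" && folds > n)
    stop("more folds than sessions")

  fit_fun <- if (is.function(regressor)) {
    regressor
  } else {
    switch(match.arg(regressor),
      rf = function(x, y, seed) pl_forest(x, y, ntree = ntree, seed = seed),
      lm = function(x, y, seed) {
        d <- data.frame(y = y, x)
        lm(y ~ ., data = d)
      })
  }
  predict_fun <- function(fit, x) {
    if (inherits(fit, "lm")) predict(fit, newdata = as.data.frame(x))
    else predict(fit, x)
  }
  wrap <- function(f, x, y, seed) {
    if (is.function(regressor)) f(x, y) else f(x, y, seed = seed)
  }

  fold_id <- rep(1L, n)
  pl_pred <- numeric(n)
  with_seed(seed, {
    if (scheme == "oof") {
      fold_id <- sample(rep_len(seq_len(folds), n))
      for (k in seq_len(folds)) {
        hold <- fold_id == k
        fit_k <- wrap(fit_fun, x[!hold, , drop = FALSE], y[!hold],
                      seed = seed + k)
        pl_pred[hold] <- predict_fun(fit_k, x[hold, , drop = FALSE])
      }
    }
    full <- wrap(fit_fun, x, y, seed = seed)
    if (scheme == "insample") pl_pred <- predict_fun(full, x)
    structure(list(model = full, pl_pred = pl_pred, scheme = scheme,
                   folds = if (scheme == "oof") folds else NA_integer_,
                   fold_id = if (scheme == "oof") fold_id else NULL,
                   features = preds, seed = seed,
                   regressor = if (is.function(regressor)) "custom"
                               else match.arg(regressor)),
              class = "load_model")
  })
}

#' @export
#' @method print load_model
print.load_model <- function(x, ...) {
  cat(sprintf("PlayerLoad model (%s, %s%s) over %d predictors\n",
              x$regressor, x$scheme,
              if (x$scheme == "oof") paste0(", K = ", x$folds) else "",
              length(x$features)))
  invisible(x)
}

#' @export
predict.load_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[object$features])
  if (inherits(object$model, "lm"))
    predict(object$model, newdata = as.data.frame(x))
  else predict(object$model, x)
}

#' Predicted-minus-actual PlayerLoad residual
#'
#' Positive values mean the session's measured body load fell below the value
#' expected for its locomotor output (an efficient session); negative values
#' mean the player accumulated more load than expected (reduced locomotor
#' efficiency).
#'
#' @param pl_pred,pl_actual Predicted and measured PlayerLoad.
#' @return `pl_pred - pl_actual`.
#' @examples
#' delta_playerload(320, 300)
#' @export
delta_playerload <- function(pl_pred, pl_actual) {
  if (any(!is.finite(pl_pred)) || any(!is.finite(pl_actual)))
    stop("pl_pred and pl_actual must be finite")
  pl_pred - pl_actual
}

#' Standardize the residual within each player
#'
#' Converts each player's residual series to z-scores using that player's
#' mean and sample (n-1) standard deviation over the full supplied window,
#' absorbing between-player differences in habitual load. Players with too
#' few sessions, or with (numerically) zero residual spread, are excluded
#' with a warning rather than divided by zero.
#'
#' @param delta_pl Residual series.
#' @param player Player identifier, same length.
#' @param min_sessions Minimum records per player (default 20).
#' @param tol Relative spread below which a player counts as zero-spread.
#' @return Numeric vector of z-scores, `NA` for excluded players, with the
#'   exclusion table in `attr(, "excluded")` (`player_id`, `reason`).
#' @examples
#' standardize_player(c(1, 2, 3), rep("A", 3))
#' @export
standardize_player <- function(delta_pl, player, min_sessions = 20,
                               tol = 1e-8) {
  stopifnot(length(delta_pl) == length(player))
  player <- as.character(player)
  n_p <- tapply(delta_pl, player, length)
  m_p <- tapply(delta_pl, player, mean)
  s_p <- tapply(delta_pl, player, sd)
  scale_ref <- max(1, mean(abs(delta_pl)), na.rm = TRUE)
  too_few <- names(n_p)[n_p < min_sessions]
  flat <- setdiff(names(n_p)[is.na(s_p) | s_p <= tol * scale_ref], too_few)
  excluded <- data.frame(
    player_id = c(too_few, flat),
    reason = rep(c("below_min_sessions", "zero_spread"),
                 c(length(too_few), length(flat))))
  if (nrow(excluded))
    warning(sprintf("excluding %d player(s): %s",
                    nrow(excluded),
                    paste(excluded$player_id, "(", excluded$reason, ")",
                          collapse = ", ")), call. = FALSE)
  z <- (delta_pl - m_p[player]) / s_p[player]
  z[player %in% excluded$player_id] <- NA_real_
  z <- as.numeric(z)
  attr(z, "excluded") <- excluded
  z
}

#' Average session scores into one value per player-day
#'
#' When a player completes two sessions in a day, the day's index is the
#' arithmetic mean of the session values.
#'
#' @param records Data frame with `player_id`, `date` and a score column.
#' @param value Name of the score column (default `"lei"`).
#' @return Data frame `player_id`, `date`, one averaged value per player-day.
#' @examples
#' aggregate_daily(data.frame(player_id = "A",
#'                            date = as.Date("2021-08-02"),
#'                            lei = c(0.2, 0.6)))
#' @export
aggregate_daily <- function(records, value = "lei") {
  stopifnot(all(c("player_id", "date", value) %in% names(records)))
  out <- aggregate(records[[value]],
                   by = list(player_id = records$player_id,
                             date = records$date),
                   FUN = mean)
  names(out)[3] <- value
  out[order(out$player_id, out$date), , drop = FALSE]
}

#' Locomotor Efficiency Index from session monitoring data
#'
#' The main fitting function. Fits the PlayerLoad model (out-of-fold by
#' default), forms the predicted-minus-actual residual for every session,
#' standardizes it within each player over the full supplied window into the
#' Locomotor Efficiency Index (LEI), and averages multi-session days. A
#' positive LEI marks a session where the player produced their locomotor
#' output at a lower-than-usual body load (good neuromuscular readiness); a
#' negative LEI marks reduced locomotor efficiency.
#'
#' @inheritParams fit_load_model
#' @param min_sessions Minimum sessions a player needs to be standardized.
#' @param zero_spread_tol Relative residual-spread tolerance below which a
#'   player is excluded (guards the degenerate perfectly-predicted case).
#' @return An object of class `lei` with components `records` (per session:
#'   `player_id`, `date`, `session_index_in_day`, `pl_pred`, `pl_actual`,
#'   `delta_pl`, `lei`), `daily` (one LEI per player-day), `model` (the
#'   [fit_load_model()] object), `excluded` (players dropped and why), and
#'   `call`. Methods: `print`, `summary`, `fitted` (predicted PL),
#'   `residuals` (delta PL), `predict` (PL for new sessions), `plot`.
#' @examples
#' sim <- simulate_squad(squad_config(n_players = 6, n_weeks = 8, seed = 3))
#' fit <- lei(sim$sessions, regressor = "lm", min_sessions = 10)
#' summary(fit)
#' @export
lei <- function(sessions, scheme = c("oof", "insample"), folds = 5,
                regressor = c("rf", "lm"), ntree = 200, min_sessions = 20,
                zero_spread_tol = 1e-8, seed = 1) {
  stopifnot(all(c("player_id", "date") %in% names(sessions)))
  model <- fit_load_model(sessions, scheme = scheme, folds = folds,
                          regressor = regressor, ntree = ntree, seed = seed)
  delta <- delta_playerload(model$pl_pred, sessions$player_load)
  z <- standardize_player(delta, sessions$player_id,
                          min_sessions = min_sessions, tol = zero_spread_tol)
  records <- data.frame(
    player_id = as.character(sessions$player_id), date = sessions$date,
    session_index_in_day = if ("session_index_in_day" %in% names(sessions))
      sessions$session_index_in_day else 1L,
    pl_pred = model$pl_pred, pl_actual = sessions$player_load,
    delta_pl = delta, lei = as.numeric(z))
  scored <- records[!is.na(records$lei), , drop = FALSE]
  daily <- if (nrow(scored)) aggregate_daily(scored) else
    data.frame(player_id = character(), date = as.Date(character()),
               lei = numeric())
  structure(list(records = records, daily = daily, model = model,
                 excluded = attr(z, "excluded"), min_sessions = min_sessions,
                 call = match.call()),
            class = "lei")
}

#' @export
#' @method print lei
print.lei <- function(x, ...) {
  np <- length(unique(x$records$player_id))
  cat("Locomotor Efficiency Index fit\n")
  cat(sprintf("  %d sessions, %d players (%d excluded), %d player-days scored\n",
              nrow(x$records), np, nrow(x$excluded), nrow(x$daily)))
  print(x$model)
  invisible(x)
}

#' @export
#' @method summary lei
summary.lei <- function(object, ...) {
  r <- object$records
  ok <- !is.na(r$lei)
  rmse <- sqrt(mean(r$delta_pl^2))
  r2 <- 1 - sum(r$delta_pl^2) / sum((r$pl_actual - mean(r$pl_actual))^2)
  out <- list(n_sessions = nrow(r),
              n_players = length(unique(r$player_id)),
              n_excluded = nrow(object$excluded),
              rmse = rmse, r_squared = r2,
              lei_quartiles = quantile(r$lei[ok], c(0.25, 0.5, 0.75)),
              scheme = object$model$scheme, regressor = object$model$regressor)
  class(out) <- "summary.lei"
  out
}

#' @export
#' @method print summary.lei
print.summary.lei <- function(x, ...) {
  cat("Locomotor Efficiency Index fit\n")
  cat(sprintf("  sessions: %d  players: %d (%d excluded)\n",
              x$n_sessions, x$n_players, x$n_excluded))
  cat(sprintf("  load model: %s, %s predictions; RMSE %.2f AU, R^2 %.3f\n",
              x$regressor, x$scheme, x$rmse, x$r_squared))
  cat(sprintf("  LEI quartiles: %.2f / %.2f / %.2f\n",
              x$lei_quartiles[1], x$lei_quartiles[2], x$lei_quartiles[3]))
  invisible(x)
}

#' @export
fitted.lei <- function(object, ...) object$records$pl_pred

#' @export
residuals.lei <- function(object, ...) object$records$delta_pl

#' @export
predict.lei <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$records$pl_pred)
  predict(object$model, newdata)
}

#' @export
plot.lei <- function(x, ...) {
  d <- x$daily
  plot(d$date, d$lei, col = as.integer(factor(d$player_id)), pch = 16,
       cex = 0.5, xlab = "date", ylab = "daily LEI (z)", ...)
  graphics::abline(h = c(-0.5, 0.5), lty = 2, col = "grey40")
  invisible(x)
}

#' Daily LEI table from a fitted index
#'
#' @param object A [lei()] fit.
#' @return Data frame `player_id`, `date`, `lei` (one row per player-day).
#' @export
daily_lei <- function(object) {
  stopifnot(inherits(object, "lei"))
  object$daily
}
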