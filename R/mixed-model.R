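#' Effect of load fluctuation on week-to-week LEI change in one readiness
#' state
#'
#' Within one readiness subset and for one weekly load metric, fits a linear
#' mixed model of the (subset-standardized) week-to-week LEI variation on the
#' five fluctuation categories with a per-player random intercept, estimated
#' by restricted maximum likelihood via \pkg{lme4}. Contrasts are against the
#' `no_variation` reference category, so each coefficient answers: compared
#' with holding the weekly load constant, did this load manipulation change
#' next week's readiness? Inference is Wald (normal approximation), matching
#' common practice for large longitudinal squads; no small-sample df
#' correction is applied.
#'
#' @param transitions A [build_transitions()] table.
#' @param readiness Readiness subset to analyse: `"bad"`, `"normal"` or
#'   `"good"`.
#' @param metric Load metric: `"total_distance"`, `"dist_gt_25_2"` or
#'   `"mechanical_load"`.
#' @param standardize Z-score the outcome within the fitted subset (default
#'   `TRUE`), making the coefficients standardized effect sizes. Category
#'   indicators stay 0/1; set `standardize_predictors = TRUE` to also scale
#'   them.
#' @param standardize_predictors Also divide each category indicator by its
#'   standard deviation (off by default).
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `readiness_model`: `table` (category, beta,
#'   ci_low, ci_high, p_value, n — the reference row has beta 0 and no
#'   interval; empty categories are absent), `fit` (the `lmerMod`),
#'   `var_intercept`, `var_residual`, `boundary` (singular-fit flag),
#'   `n_obs`, `n_players`, `readiness`, `metric`.
#' @export
readiness_model <- function(transitions, readiness, metric,
                            standardize = TRUE,
                            standardize_predictors = FALSE,
                            conf_level = 0.95) {
  readiness <- match.arg(readiness, readiness_levels())
  metric <- match.arg(metric, load_metrics())
  catcol <- paste0("cat_", metric)
  stopifnot(all(c("player_id", "readiness_ref", "lei_variation", catcol)
                %in% names(transitions)))
  d <- transitions[transitions$readiness_ref == readiness &
                     !is.na(transitions[[catcol]]) &
                     is.finite(transitions$lei_variation), , drop = FALSE]
  size_stop <- function(msg) {
    stop(errorCondition(sprintf("readiness '%s', metric '%s': %s",
                                readiness, metric, msg),
                        class = c("locoeff_size_error", "error")))
  }
  if (nrow(d) < 10) size_stop("fewer than 10 transitions")
  if (length(unique(d$player_id)) < 2) size_stop("fewer than 2 players")
  cat_f <- droplevels(factor(d[[catcol]], levels = fluctuation_levels(),
                             ordered = FALSE))
  if (!"no_variation" %in% levels(cat_f))
    size_stop("reference category 'no_variation' unoccupied")
  if (nlevels(cat_f) < 2) size_stop("fewer than 2 occupied categories")
  cat_f <- stats::relevel(cat_f, ref = "no_variation")

  y <- d$lei_variation
  if (standardize) y <- (y - mean(y)) / sd(y)
  md <- data.frame(y = y, category = cat_f,
                   player_id = factor(d$player_id))
  xmat <- stats::model.matrix(~category, md)
  if (standardize_predictors) {
    sds <- apply(xmat[, -1, drop = FALSE], 2, sd)
    xmat[, -1] <- sweep(xmat[, -1, drop = FALSE], 2, sds, "/")
  }
  fit <- lme4::lmer(
    y ~ 0 + xmat + (1 | player_id), data = md, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  rn <- sub("^xmat", "", rownames(sm))
  keep <- grepl("^category", rn)
  cats <- sub("^category", "", rn[keep])
  beta <- sm[keep, "Estimate"]
  se <- sm[keep, "Std. Error"]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    category = factor(c("no_variation", cats), levels = fluctuation_levels()),
    beta = c(0, beta), ci_low = c(NA, beta - zq * se),
    ci_high = c(NA, beta + zq * se),
    p_value = c(NA, 2 * pnorm(-abs(beta / se))),
    n = as.integer(table(md$category)[c("no_variation", cats)]))
  tab <- tab[order(tab$category), , drop = FALSE]
  rownames(tab) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(table = tab, fit = fit,
                 var_intercept = vc$vcov[vc$grp == "player_id"],
                 var_residual = vc$vcov[vc$grp == "Residual"],
                 boundary = lme4::isSingular(fit),
                 n_obs = nrow(md),
                 n_players = nlevels(md$player_id),
                 readiness = readiness, metric = metric,
                 conf_level = conf_level, standardize = standardize),
            class = "readiness_model")
}

#' @export
#' @method print readiness_model
print.readiness_model <- function(x, digits = 3, ...) {
  cat(sprintf("Week-to-week LEI variation ~ %s fluctuation | %s readiness\n",
              x$metric, x$readiness))
  cat(sprintf("  %d transitions, %d players; random-intercept var %.3g, residual var %.3g%s\n",
              x$n_obs, x$n_players, x$var_intercept, x$var_residual,
              if (x$boundary) " (boundary fit)" else ""))
  tab <- x$table
  tab$beta <- round(tab$beta, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method summary readiness_model
summary.readiness_model <- function(object, ...) object

#' @export
coef.readiness_model <- function(object, ...) {
  setNames(object$table$beta, as.character(object$table$category))
}

#' @export
confint.readiness_model <- function(object, ...) {
  m <- as.matrix(object$table[, c("ci_low", "ci_high")])
  rownames(m) <- as.character(object$table$category)
  m
}

#' Fit the full readiness-by-metric scenario grid
#'
#' Runs [readiness_model()] for every readiness subset crossed with every
#' weekly load metric (up to nine fits), skipping — with a logged reason —
#' any combination with too little data, and assembles a single coefficient
#' report.
#'
#' @inheritParams readiness_model
#' @param metrics Load metrics to analyse.
#' @param subsets Readiness subsets to analyse.
#' @return Object of class `scenario_grid`: `table` (subset, metric,
#'   category, beta, ci_low, ci_high, p_value, n, n_obs, n_players,
#'   boundary), `fits` (named list of `readiness_model`s), `skipped`
#'   (subset, metric, reason).
#' @export
scenario_grid <- function(transitions, subsets = readiness_levels(),
                          metrics = load_metrics(), standardize = TRUE,
                          conf_level = 0.95) {
  fits <- list(); rows <- list()
  skipped <- data.frame(readiness = character(), metric = character(),
                        reason = character())
  for (s in subsets) for (m in metrics) {
    key <- paste(s, m, sep = ".")
    res <- tryCatch(
      readiness_model(transitions, s, m, standardize = standardize,
                      conf_level = conf_level),
      locoeff_size_error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(readiness = s, metric = m,
                                  reason = conditionMessage(res)))
      next
    }
    fits[[key]] <- res
    tb <- res$table
    rows[[key]] <- data.frame(readiness = s, metric = m, tb,
                              n_obs = res$n_obs, n_players = res$n_players,
                              boundary = res$boundary)
  }
  if (nrow(skipped))
    warning(sprintf("%d subset x metric fits skipped (too little data)",
                    nrow(skipped)), call. = FALSE)
  structure(list(table = if (length(rows)) do.call(rbind, c(rows,
                   make.row.names = FALSE)) else NULL,
                 fits = fits, skipped = skipped),
            class = "scenario_grid")
}

#' @export
#' @method print scenario_grid
print.scenario_grid <- function(x, digits = 2, ...) {
  cat("Week-to-week LEI variation by load fluctuation (vs no variation)\n")
  if (is.null(x$table)) {
    cat("  no fits (all subsets skipped)\n")
    return(invisible(x))
  }
  tb <- x$table
  ci <- ifelse(is.na(tb$ci_low), "  (ref)",
               sprintf("[%6.2f, %6.2f]", tb$ci_low, tb$ci_high))
  p <- ifelse(is.na(tb$p_value), "", formatC(tb$p_value, format = "f",
                                             digits = 3))
  star <- ifelse(!is.na(tb$p_value) & tb$p_value < 0.05, " *", "")
  for (m in unique(tb$metric)) {
    cat("\n", m, "\n", sep = "")
    sub <- tb$metric == m
    lines <- sprintf("  %-7s %-18s %7.2f %s %7s%s",
                     tb$readiness[sub], as.character(tb$category[sub]),
                     tb$beta[sub], ci[sub], p[sub], star[sub])
    cat(lines, sep = "\n")
  }
  if (nrow(x$skipped)) cat(sprintf("\n%d fits skipped\n", nrow(x$skipped)))
  invisible(x)
}

#' @export
as.data.frame.scenario_grid <- function(x, ...) x$table

#' Descriptive summary of week-to-week LEI variation
#'
#' Mean, SD and count of the signed LEI variation per fluctuation category
#' and load metric, optionally split by season. Categories with no rows are
#' omitted; the SD of a single transition is reported as `NA`.
#'
#' @param transitions A [build_transitions()] table.
#' @param by_season Split by the `season` column when present.
#' @return Data frame: (`season`,) `metric`, `category`, `n`, `mean`, `sd`.
#' @export
lei_descriptives <- function(transitions, by_season = FALSE) {
  stopifnot(nrow(transitions) > 0)
  metrics <- load_metrics()
  groups <- if (by_season && "season" %in% names(transitions))
    unique(transitions$season) else NA
  out <- list()
  for (g in groups) {
    d <- if (is.na(g)) transitions else
      transitions[transitions$season == g, , drop = FALSE]
    for (m in metrics) {
      cc <- d[[paste0("cat_", m)]]
      ok <- !is.na(cc)
      if (!any(ok)) next
      agg <- aggregate(list(v = d$lei_variation[ok]),
                       by = list(category = cc[ok]), FUN = length,
                       drop = TRUE)
      mu <- tapply(d$lei_variation[ok], droplevels(cc[ok]), mean)
      sdv <- tapply(d$lei_variation[ok], droplevels(cc[ok]), sd)
      row <- data.frame(metric = m, category = agg$category,
                        n = agg$v,
                        mean = as.numeric(mu[as.character(agg$category)]),
                        sd = as.numeric(sdv[as.character(agg$category)]))
      if (!is.na(g)) row <- cbind(season = g, row)
      out[[paste(g, m)]] <- row
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  o <- if ("season" %in% names(res))
    order(res$season, match(res$metric, metrics), res$category)
  else order(match(res$metric, metrics), res$category)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}
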