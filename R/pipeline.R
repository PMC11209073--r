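#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one validated object so
#' that thresholds are never hard-coded at call sites: readiness cutoffs on
#' weekly LEI, fluctuation bounds on the weekly percentage change,
#' participation threshold, the load-model scheme, and the seed.
#'
#' @param readiness_cutoffs Weekly-LEI cutoffs, default `c(-0.5, 0.5)`.
#' @param fluctuation_bounds Four increasing percentage cut points, default
#'   `c(-30, -10, 10, 30)`.
#' @param participation Minimum attended/scheduled fraction (default 0.60).
#' @param scheme,folds,regressor,ntree Load-model settings, see
#'   [fit_load_model()].
#' @param min_sessions Minimum sessions per player for standardization.
#' @param min_week_sessions Minimum sessions for a week to enter a
#'   transition.
#' @param readiness_ref Which week's readiness conditions a transition,
#'   `"from"` or `"to"`.
#' @param standardize Standardize the mixed-model outcome within subsets.
#' @param seed Seed for fold assignment / ensemble randomness.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(readiness_cutoffs = c(-0.5, 0.5),
                            fluctuation_bounds = c(-30, -10, 10, 30),
                            participation = 0.60,
                            scheme = "oof", folds = 5, regressor = "rf",
                            ntree = 200, min_sessions = 20,
                            min_week_sessions = 3, readiness_ref = "from",
                            standardize = TRUE, seed = 1) {
  cfg <- list(readiness_cutoffs = as.numeric(readiness_cutoffs),
              fluctuation_bounds = as.numeric(fluctuation_bounds),
              participation = participation, scheme = scheme,
              folds = as.integer(folds), regressor = regressor,
              ntree = as.integer(ntree),
              min_sessions = as.integer(min_sessions),
              min_week_sessions = as.integer(min_week_sessions),
              readiness_ref = readiness_ref, standardize = standardize,
              seed = as.integer(seed))
  if (length(cfg$readiness_cutoffs) != 2 ||
      cfg$readiness_cutoffs[1] >= cfg$readiness_cutoffs[2])
    stop("readiness_cutoffs must be two increasing numbers")
  if (length(cfg$fluctuation_bounds) != 4 ||
      is.unsorted(cfg$fluctuation_bounds, strictly = TRUE))
    stop("fluctuation_bounds must be four strictly increasing numbers")
  if (cfg$participation < 0 || cfg$participation > 1)
    stop("participation must lie in [0, 1]")
  stopifnot(cfg$folds >= 2, cfg$ntree >= 1, cfg$min_sessions >= 2,
            cfg$min_week_sessions >= 1)
  cfg$readiness_ref <- match.arg(cfg$readiness_ref, c("from", "to"))
  cfg$scheme <- match.arg(cfg$scheme, c("oof", "insample"))
  structure(cfg, class = "pipeline_config")
}

#' @export
#' @method print pipeline_config
print.pipeline_config <- function(x, ...) {
  cat("LEI pipeline configuration\n")
  cat(sprintf("  readiness cutoffs: %g / %g; fluctuation bounds: %s %%\n",
              x$readiness_cutoffs[1], x$readiness_cutoffs[2],
              paste(x$fluctuation_bounds, collapse = " / ")))
  cat(sprintf("  participation >= %g; load model: %s (%s, K = %d, seed %d)\n",
              x$participation, x$regressor, x$scheme, x$folds, x$seed))
  invisible(x)
}

#' Run the full readiness analysis
#'
#' End-to-end orchestration: participation filter, LEI scoring, weekly
#' summaries, transition construction, descriptives and the mixed-model
#' scenario grid. Every input row is accounted for in the run log as
#' retained or excluded with a reason. The result is a pure function of the
#' session table, the configuration and its seed.
#'
#' @param sessions Session table (e.g. `simulate_squad(...)$sessions` or a
#'   sessions CSV read with [read.csv()] and `date` converted to `Date`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `lei.csv`,
#'   `weeks.csv`, `transitions.csv`, `coefficients.csv`,
#'   `descriptives.csv` and `run_log.csv`.
#' @return Object of class `lei_pipeline`: `lei` (the [lei()] fit), `weeks`,
#'   `transitions`, `grid` (the [scenario_grid()]), `descriptives`, `log`
#'   (stage, rows in/out, exclusions), `config`.
#' @export
run_pipeline <- function(sessions, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sessions$date <- as.Date(sessions$date)
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1]] <<- data.frame(stage = stage, n_in = n_in,
                                          n_out = n_out, detail = detail)
  }

  kept <- filter_participation(sessions, threshold = config$participation)
  excl_part <- attr(kept, "excluded_players")
  note("participation_filter", nrow(sessions), nrow(kept),
       sprintf("%d player(s) below %g", nrow(excl_part),
               config$participation))

  fit <- lei(kept, scheme = config$scheme, folds = config$folds,
             regressor = config$regressor, ntree = config$ntree,
             min_sessions = config$min_sessions, seed = config$seed)
  note("lei_scoring", nrow(kept), sum(!is.na(fit$records$lei)),
       sprintf("%d player(s) excluded (%s)", nrow(fit$excluded),
               paste(unique(fit$excluded$reason), collapse = "/")))

  weeks <- weekly_summaries(fit$daily, kept,
                            cutoffs = config$readiness_cutoffs)
  note("weekly_summaries", nrow(fit$daily), nrow(weeks))

  trans <- build_transitions(weeks,
                             min_week_sessions = config$min_week_sessions,
                             readiness_ref = config$readiness_ref,
                             bounds = config$fluctuation_bounds)
  note("transitions", nrow(weeks), nrow(trans),
       sprintf("zero-load drops: %s",
               paste(attr(trans, "dropped_zero_load"), collapse = "/")))

  desc <- lei_descriptives(trans, by_season = "season" %in% names(trans))
  grid <- suppressWarnings(
    scenario_grid(trans, standardize = config$standardize))
  note("scenario_grid", nrow(trans),
       if (is.null(grid$table)) 0L else nrow(grid$table),
       sprintf("%d fit(s) skipped", nrow(grid$skipped)))

  out <- structure(list(lei = fit, weeks = weeks, transitions = trans,
                        grid = grid, descriptives = desc,
                        log = do.call(rbind, log),
                        excluded_participation = excl_part,
                        config = config),
                   class = "lei_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(fit$records, file.path(out_dir, "lei.csv"), row.names = FALSE)
    write.csv(weeks, file.path(out_dir, "weeks.csv"), row.names = FALSE)
    write.csv(trans, file.path(out_dir, "transitions.csv"),
              row.names = FALSE)
    if (!is.null(grid$table))
      write.csv(grid$table, file.path(out_dir, "coefficients.csv"),
                row.names = FALSE)
    write.csv(desc, file.path(out_dir, "descriptives.csv"),
              row.names = FALSE)
    write.csv(out$log, file.path(out_dir, "run_log.csv"), row.names = FALSE)
  }
  out
}

#' @export
#' @method print lei_pipeline
print.lei_pipeline <- function(x, ...) {
  cat("LEI readiness pipeline\n")
  print(x$log, row.names = FALSE)
  cat("\n")
  print(x$grid)
  invisible(x)
}

#' Parameter-recovery and calibration harness
#'
#' Repeatedly simulates a squad with known fatigue dynamics, runs the full
#' pipeline, and tabulates the mixed-model contrasts against the ground
#' truth. With `gamma = 0` (no fatigue effect on PlayerLoad) every contrast
#' is null, so the fraction of p-values below `alpha` estimates the type-I
#' error. With `gamma > 0` the harness reports how often the qualitative
#' effects of load manipulation are recovered: unloading helps players in bad
#' readiness (positive large-decrease contrast) and overloading hurts
#' players in normal readiness (negative large-increase contrast).
#'
#' The replicate pipelines use the pooled linear load model: the simulator's
#' fatigue-free PlayerLoad is linear in the predictors, so the linear model
#' is the correctly specified regressor and keeps the harness fast.
#'
#' @param n_replicates Number of simulated squads.
#' @param seeds Simulation seeds, one per replicate.
#' @param sim_args Named list of [squad_config()] overrides (e.g.
#'   `list(gamma = 0)` for the null harness). Defaults target a mid-size
#'   squad: 40 players, 30 weeks.
#' @param config A [pipeline_config()]; the regressor is forced to `"lm"`.
#' @param alpha Significance level for the tabulations.
#' @return Object of class `recovery_report`: `contrasts` (one row per
#'   replicate x subset x metric x category: beta, p), `rates` (named list:
#'   `type1_rate`, `n_contrasts`, `sign_recovery_bad_large_decrease`,
#'   `sign_recovery_normal_large_increase`), `alpha`, `gamma`.
#' @export
run_recovery <- function(n_replicates = 20, seeds = seq_len(n_replicates),
                         sim_args = list(), config = pipeline_config(),
                         alpha = 0.05) {
  stopifnot(n_replicates >= 1, length(seeds) == n_replicates)
  config$regressor <- "lm"
  base_args <- list(n_players = 40, n_weeks = 30)
  base_args[names(sim_args)] <- sim_args
  rows <- list()
  for (r in seq_len(n_replicates)) {
    base_args$seed <- seeds[r]
    sim <- simulate_squad(do.call(squad_config, base_args))
    cfg <- config
    cfg$seed <- seeds[r]
    pipe <- suppressWarnings(run_pipeline(sim$sessions, cfg))
    tb <- pipe$grid$table
    if (is.null(tb)) next
    tb <- tb[tb$category != "no_variation", , drop = FALSE]
    rows[[r]] <- data.frame(replicate = r, seed = seeds[r],
                            tb[c("readiness", "metric", "category", "beta",
                                 "p_value", "n")])
  }
  contrasts <- do.call(rbind, c(rows, make.row.names = FALSE))
  gamma <- if (!is.null(base_args$gamma)) base_args$gamma else
    squad_config()$gamma
  pick <- function(subset, category, metric = "total_distance") {
    contrasts[contrasts$readiness == subset &
                contrasts$category == category &
                contrasts$metric == metric, , drop = FALSE]
  }
  bad_ld <- pick("bad", "large_decrease")
  nrm_li <- pick("normal", "large_increase")
  per_rep_rate <- function(d, test) {
    if (!nrow(d)) return(NA_real_)
    mean(vapply(split(d, d$replicate),
                function(x) any(test(x)), logical(1)))
  }
  rates <- list(
    type1_rate = mean(contrasts$p_value < alpha),
    n_contrasts = nrow(contrasts),
    sign_recovery_bad_large_decrease =
      per_rep_rate(bad_ld, function(x) x$beta > 0 & x$p_value < alpha),
    sign_recovery_normal_large_increase =
      per_rep_rate(nrm_li, function(x) x$beta < 0))
  structure(list(contrasts = contrasts, rates = rates, alpha = alpha,
                 gamma = gamma, seeds = seeds),
            class = "recovery_report")
}

#' @export
#' @method print recovery_report
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery harness: %d replicate squads (gamma = %g)\n",
              length(x$seeds), x$gamma))
  r <- x$rates
  cat(sprintf("  contrasts fitted: %d; share with p < %g: %.3f\n",
              r$n_contrasts, x$alpha, r$type1_rate))
  if (x$gamma > 0) {
    cat(sprintf("  unloading helps bad readiness (beta > 0, p < %g): %.0f%% of replicates\n",
                x$alpha, 100 * r$sign_recovery_bad_large_decrease))
    cat(sprintf("  overloading hurts normal readiness (beta < 0): %.0f%% of replicates\n",
                100 * r$sign_recovery_normal_large_increase))
  }
  invisible(x)
}
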