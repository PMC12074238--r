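# End-to-end replication driver: the four-condition within-subject design,
# one simulated session per participant and condition, aggregated into a
# mean (SD) measures table.

#' Define an experiment plan
#'
#' Mirrors the within-subject design: every participant plays every listed
#' condition once. Each participant-condition session receives a distinct
#' seed derived from `seed_base`, so the whole experiment is reproducible
#' from the plan alone.
#'
#' @param conditions Conditions to run (each at most once); defaults to
#'   all four.
#' @param n_participants Number of simulated participants (default 19).
#' @param n_trials Reel attempts per session (default 20).
#' @param agent Name of a [preset_profiles()] entry, or an
#'   [agent_profile()].
#' @param augmented_variant Variant used for `AUGMENTED_SUCCESS` sessions.
#' @param seed_base Base seed; session seeds are
#'   `seed_base + participant_index * length(conditions) + condition_index`.
#' @param ... Further arguments passed to [game_config()] (rates, lanes,
#'   ticks).
#' @return A `pam_experiment_plan` list.
#' @export
experiment_plan <- function(conditions = pam_conditions(),
                            n_participants = 19L,
                            n_trials = 20L,
                            agent = "ideal",
                            augmented_variant = "CONSTRAINED",
                            seed_base = 1L,
                            ...) {
  conditions <- match.arg(conditions, pam_conditions(), several.ok = TRUE)
  if (anyDuplicated(conditions)) {
    stop("each condition may be listed at most once", call. = FALSE)
  }
  if (is.character(agent)) {
    presets <- preset_profiles()
    agent <- presets[[match.arg(agent, names(presets))]]
  }
  stopifnot(inherits(agent, "pam_agent"), n_participants >= 1L)
  structure(
    list(
      conditions = conditions,
      n_participants = as.integer(n_participants),
      n_trials = as.integer(n_trials),
      agent = agent,
      augmented_variant = augmented_variant,
      seed_base = as.integer(seed_base),
      config_args = list(...)
    ),
    class = "pam_experiment_plan"
  )
}

#' Run a planned experiment
#'
#' Simulates one session per participant and condition, computes the
#' per-session measures, and aggregates them into a mean (SD) table shaped
#' like the printed condition summaries (fraction measures as percentages,
#' counts to two decimals).
#'
#' @param plan An [experiment_plan()].
#' @param output_dir Optional directory; if given, per-session event logs
#'   (`log_<participant>_<condition>.csv`), the per-session measures
#'   (`measures.csv`) and the summary (`summary.csv`) are written there.
#'   On any error the partially written files are removed.
#' @return List with `measures` (one row per session, with `participant`,
#'   `condition`, `seed` columns), `summary` (formatted wide table,
#'   measures x conditions), and `logs` (named list of event logs).
#' @examples
#' res <- run_experiment(experiment_plan(n_participants = 3, seed_base = 1))
#' res$summary
#' @export
run_experiment <- function(plan, output_dir = NULL) {
  stopifnot(inherits(plan, "pam_experiment_plan"))
  written <- character()
  on_error_cleanup <- function() if (length(written)) unlink(written)

  res <- tryCatch({
    rows <- list()
    logs <- list()
    for (pi in seq_len(plan$n_participants)) {
      for (ci in seq_along(plan$conditions)) {
        cond <- plan$conditions[ci]
        seed <- plan$seed_base + (pi - 1L) * length(plan$conditions) + ci - 1L
        args <- plan$config_args
        if (cond == "REFERENCE") args$help_rate <- 0
        cfg <- do.call(game_config, c(
          list(condition = cond,
               augmented_variant = plan$augmented_variant,
               n_trials = plan$n_trials, seed = seed),
          args
        ))
        log <- run_session(cfg, plan$agent)
        key <- sprintf("p%02d_%s", pi, cond)
        logs[[key]] <- log
        m <- compute_session_measures(log)
        m$participant <- pi
        rows[[key]] <- m
        if (!is.null(output_dir)) {
          if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
          f <- file.path(output_dir, paste0("log_", key, ".csv"))
          write_event_log(log, f)
          written <- c(written, f)
        }
      }
    }
    measures <- do.call(rbind, rows)
    rownames(measures) <- NULL
    summary <- summarize_measures(measures, plan$conditions)
    if (!is.null(output_dir)) {
      f1 <- file.path(output_dir, "measures.csv")
      utils::write.csv(measures, f1, row.names = FALSE, fileEncoding = "UTF-8")
      f2 <- file.path(output_dir, "summary.csv")
      utils::write.csv(summary, f2, row.names = FALSE, fileEncoding = "UTF-8")
      written <- c(written, f1, f2)
    }
    list(measures = measures, summary = summary, logs = logs)
  }, error = function(e) {
    on_error_cleanup()
    stop(e)
  })
  res
}

fraction_measures <- c("blink_recognition", "blink_conv_rate",
                       "pos_feedback", "help_rate")
count_measures <- c("fish_caught", "fish_lost", "fish_reel", "fish_unreel",
                    "duration_ticks")

summarize_measures <- function(measures, conditions) {
  fmt <- function(x, pct) {
    if (pct) sprintf("%.0f%% (%.2f)", mean(x) * 100, stats::sd(x))
    else sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  }
  out <- data.frame(measure = c(fraction_measures, count_measures))
  for (cond in conditions) {
    sub <- measures[measures$condition == cond, , drop = FALSE]
    out[[cond]] <- c(
      vapply(fraction_measures, function(v) fmt(sub[[v]], TRUE), character(1)),
      vapply(count_measures, function(v) fmt(sub[[v]], FALSE), character(1))
    )
  }
  out
}
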