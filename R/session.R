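# The trial loop: schedule -> agent blinks -> trial resolution -> event log.

#' Run one full game session
#'
#' Plays `n_trials` reel trials against the predefined schedule built by
#' [build_trial_schedule()]. A new fish is spawned and hooked at the start
#' of the session and whenever the previous fish was caught or lost. Every
#' source of randomness (failure positions, spawn lanes, agent blinks)
#' derives from the session seed, so the log is reproducible bit-for-bit
#' from `(config, agent, seed)`.
#'
#' @param config A [game_config()].
#' @param agent An [agent_profile()]; defaults to the ideal agent.
#' @param seed Optional override of `config$seed`.
#' @return A `pam_event_log`: a data frame with one row per trial and
#'   columns `trial`, `fish_id`, `lane_before`, `lane_after`,
#'   `escape_before`, `escape_after`, `blink_count`, `in_range`,
#'   `scheduled_recognized`, `effective_recognized`, `help_scheduled`,
#'   `help`, `outcome`, `ticks` (`lane_after`/`escape_after` are `NA` when
#'   the fish left the lake). The config, agent label and seed are attached
#'   as attributes.
#' @examples
#' log <- run_session(game_config("MITIGATED_FAILURE", seed = 1))
#' table(log$outcome)
#' @export
run_session <- function(config, agent = preset_profiles()$ideal,
                        seed = NULL) {
  stopifnot(inherits(config, "pam_game_config"), inherits(agent, "pam_agent"))
  if (!is.null(seed)) config$seed <- as.integer(seed)

  schedule <- build_trial_schedule(config)
  n <- config$n_trials

  rec <- vector("list", n)
  withr::with_seed(config$seed, {
    fish_id <- 1L
    fish <- spawn_fish(config, fish_id)
    for (i in seq_len(n)) {
      blinks <- simulate_trial_blinks(agent)
      res <- resolve_trial(
        fish,
        scheduled_recognized = schedule$recognized[i],
        any_in_range_blink = blinks$any_in_range,
        help_flag = schedule$help_flag[i],
        config = config
      )
      rec[[i]] <- data.frame(
        trial = i,
        fish_id = fish$fish_id,
        lane_before = fish$lane,
        lane_after = if (is.null(res$fish_after)) NA_integer_
                     else res$fish_after$lane,
        escape_before = fish$escape_progress,
        escape_after = if (is.null(res$fish_after)) NA_integer_
                       else res$fish_after$escape_progress,
        blink_count = blinks$blink_count,
        in_range = blinks$any_in_range,
        scheduled_recognized = schedule$recognized[i],
        effective_recognized = schedule$recognized[i] && blinks$any_in_range,
        help_scheduled = schedule$help_flag[i],
        help = res$help_feedback,
        outcome = res$outcome,
        ticks = config$trial_ticks + config$rest_ticks +
          if (res$help_feedback) config$help_ticks else 0L
      )
      if (is.null(res$fish_after)) {
        fish_id <- fish_id + 1L
        fish <- spawn_fish(config, fish_id)
      } else {
        fish <- res$fish_after
      }
    }
  })

  log <- do.call(rbind, rec)
  structure(
    log,
    config = config,
    agent_label = agent$label,
    seed = config$seed,
    class = c("pam_event_log", "data.frame")
  )
}

event_log_columns <- c(
  "trial", "fish_id", "lane_before", "lane_after", "escape_before",
  "escape_after", "blink_count", "in_range", "scheduled_recognized",
  "effective_recognized", "help_scheduled", "help", "outcome", "ticks"
)

validate_event_log <- function(log) {
  if (!is.data.frame(log)) stop("event log must be a data frame", call. = FALSE)
  missing_cols <- setdiff(event_log_columns, names(log))
  if (length(missing_cols)) {
    stop("event log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(log) == 0L) stop("event log has no trials", call. = FALSE)
  if (!identical(as.integer(log$trial), seq_len(nrow(log)))) {
    stop("event log has missing or out-of-order trials", call. = FALSE)
  }
  bad <- !log$outcome %in% pam_outcomes
  if (any(bad)) {
    stop("unknown outcome(s): ", paste(unique(log$outcome[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(log)
}
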