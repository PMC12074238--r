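# Fish state and single-trial resolution.

#' Spawn a hooked fish
#'
#' Draws the spawn lane from the configured spawn-lane distribution (which
#' assigns probability 0 to the top lane) and hooks a fresh fish with zero
#' escape progress. Uses the current R random-number stream; [run_session()]
#' seeds that stream from the session seed so spawn sequences are
#' reproducible.
#'
#' @param config A [game_config()].
#' @param fish_id Integer id of the new fish (strictly increasing within a
#'   session).
#' @return A `pam_fish`: list with `lane`, `escape_progress`, `fish_id`.
#' @examples
#' withr::with_seed(1, spawn_fish(game_config(seed = 1)))
#' @export
spawn_fish <- function(config, fish_id = 1L) {
  stopifnot(inherits(config, "pam_game_config"))
  p <- config$spawn_lane_distribution
  lanes <- as.integer(names(p))
  lane <- lanes[sample.int(length(lanes), 1L, prob = p)]
  structure(
    list(lane = lane, escape_progress = 0L, fish_id = as.integer(fish_id)),
    class = "pam_fish"
  )
}

pam_outcomes <- c(
  "PLAYER_REEL", "PLAYER_CATCH",
  "HELP_DOUBLE_REEL", "HELP_DOUBLE_CATCH",
  "HELP_OVERRIDE_REEL", "HELP_OVERRIDE_CATCH",
  "HELP_CLAMP", "UNREEL", "LOSS"
)

positive_outcomes <- c(
  "PLAYER_REEL", "PLAYER_CATCH",
  "HELP_DOUBLE_REEL", "HELP_DOUBLE_CATCH",
  "HELP_OVERRIDE_REEL", "HELP_OVERRIDE_CATCH"
)

catch_outcomes <- c("PLAYER_CATCH", "HELP_DOUBLE_CATCH", "HELP_OVERRIDE_CATCH")
reel_outcomes <- c("PLAYER_REEL", "HELP_DOUBLE_REEL", "HELP_OVERRIDE_REEL")

#' Resolve one reel trial
#'
#' Applies the game rules of one trial period to a hooked fish. The trial
#' is effectively successful only when the schedule recognizes blinks in
#' this trial *and* the agent produced at least one in-range blink.
#'
#' On success the fish is reeled up one lane (`PLAYER_REEL`) or caught when
#' already in the top lane (`PLAYER_CATCH`). With augmented-success help the
#' fisherman reels two lanes (`HELP_DOUBLE_REEL`); under the `REDESIGNED`
#' variant the boost may also complete the catch when the fish is within two
#' lanes of the top (`HELP_DOUBLE_CATCH`), while under `CONSTRAINED` the
#' help only activates when two full lanes can be reeled without catching —
#' otherwise the trial degrades to a plain player reel/catch and the help
#' flag is left unconsumed.
#'
#' On failure, mitigated-failure help clamps the rod (`HELP_CLAMP`, escape
#' progress unchanged, not positive feedback), input-override help has the
#' helper reel exactly as a player success (`HELP_OVERRIDE_REEL`/`_CATCH`),
#' and without help the fish moves one step towards escaping (`UNREEL`) or
#' escapes (`LOSS`) when its failed-trial count reaches the escape
#' threshold; the loss replaces the unreel event.
#'
#' @param fish A live `pam_fish` (escape progress below the threshold).
#' @param scheduled_recognized Does the schedule recognize blinks here?
#' @param any_in_range_blink Did the agent blink in range during the trial?
#' @param help_flag Is help scheduled on this trial?
#' @param config A [game_config()].
#' @return A `pam_trial_result`: list with `outcome`, `fish_before`,
#'   `fish_after` (`NULL` after a catch or loss), `positive` (reel-up or
#'   catch, by blink or by help), `help_feedback` (a help animation played),
#'   and `help_consumed`.
#' @examples
#' cfg <- game_config("MITIGATED_FAILURE", seed = 1)
#' fish <- structure(list(lane = 2L, escape_progress = 0L, fish_id = 1L),
#'                   class = "pam_fish")
#' resolve_trial(fish, FALSE, TRUE, TRUE, cfg)$outcome  # "HELP_CLAMP"
#' @export
resolve_trial <- function(fish, scheduled_recognized, any_in_range_blink,
                          help_flag, config) {
  stopifnot(inherits(fish, "pam_fish"), inherits(config, "pam_game_config"))
  if (fish$escape_progress >= config$escape_threshold) {
    stop("fish is not live: escape progress at or above the threshold",
         call. = FALSE)
  }
  help_flag <- isTRUE(help_flag)
  success <- isTRUE(scheduled_recognized) && isTRUE(any_in_range_blink)

  if (help_flag) {
    trigger_ok <- switch(config$condition,
      REFERENCE = FALSE,
      AUGMENTED_SUCCESS = isTRUE(scheduled_recognized),
      MITIGATED_FAILURE = ,
      INPUT_OVERRIDE = !isTRUE(scheduled_recognized)
    )
    if (!trigger_ok) {
      stop("help flag inconsistent with the condition's trigger direction",
           call. = FALSE)
    }
  }

  after <- fish
  if (success) {
    if (help_flag && config$condition == "AUGMENTED_SUCCESS" &&
        isTRUE(any_in_range_blink)) {
      if (config$augmented_variant == "REDESIGNED") {
        if (fish$lane <= 2L) {
          outcome <- "HELP_DOUBLE_CATCH"
          after <- NULL
        } else {
          outcome <- "HELP_DOUBLE_REEL"
          after$lane <- fish$lane - 2L
        }
      } else { # CONSTRAINED: needs two full lanes without catching
        if (fish$lane >= 3L) {
          outcome <- "HELP_DOUBLE_REEL"
          after$lane <- fish$lane - 2L
        } else if (fish$lane == 1L) {
          outcome <- "PLAYER_CATCH"
          after <- NULL
        } else {
          outcome <- "PLAYER_REEL"
          after$lane <- fish$lane - 1L
        }
      }
    } else if (fish$lane == 1L) {
      outcome <- "PLAYER_CATCH"
      after <- NULL
    } else {
      outcome <- "PLAYER_REEL"
      after$lane <- fish$lane - 1L
    }
    if (!is.null(after) && config$escape_reset_on_success) {
      after$escape_progress <- 0L
    }
  } else {
    if (help_flag && config$condition == "MITIGATED_FAILURE") {
      outcome <- "HELP_CLAMP"
    } else if (help_flag && config$condition == "INPUT_OVERRIDE") {
      if (fish$lane == 1L) {
        outcome <- "HELP_OVERRIDE_CATCH"
        after <- NULL
      } else {
        outcome <- "HELP_OVERRIDE_REEL"
        after$lane <- fish$lane - 1L
      }
    } else {
      progress <- fish$escape_progress + 1L
      if (progress >= config$escape_threshold) {
        outcome <- "LOSS"
        after <- NULL
      } else {
        outcome <- "UNREEL"
        after$escape_progress <- progress
      }
    }
  }

  structure(
    list(
      outcome = outcome,
      fish_before = fish,
      fish_after = after,
      positive = outcome %in% positive_outcomes,
      help_feedback = startsWith(outcome, "HELP_"),
      help_consumed = help_flag && startsWith(outcome, "HELP_")
    ),
    class = "pam_trial_result"
  )
}
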