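# Trial schedules: the predefined recognition/help flags that emulate
# imprecise input. The game recognizes blinks only in scheduled-success
# trials; help conditions additionally pre-assign help to specific trials.

#' Build the predefined trial schedule of a session
#'
#' The schedule fixes, before play, which trial periods will recognize
#' blinks (exactly `round(success_rate * n_trials)` of them, positions drawn
#' by a seeded uniform permutation) and which trials carry help. For the
#' failure-triggered mechanisms (mitigated failure, input override) help is
#' assigned to the first `round(help_rate * n_trials)` unrecognized trials
#' in trial order; for augmented success, to the first
#' `round(help_rate * n_trials)` recognized trials (the constrained variant
#' may still fail to consume a flag at resolution time if the fish position
#' does not allow a double reel). The reference condition carries no help.
#'
#' @param config A [game_config()].
#' @return A `pam_trial_schedule`: list with logical vectors `recognized`
#'   and `help_flag`, both of length `n_trials`.
#' @examples
#' sched <- build_trial_schedule(game_config("MITIGATED_FAILURE", seed = 1))
#' sum(sched$recognized)  # 14 of 20
#' sum(sched$help_flag)   # 6, all on unrecognized trials
#' @export
build_trial_schedule <- function(config) {
  stopifnot(inherits(config, "pam_game_config"))
  n <- config$n_trials
  n_success <- as.integer(round_away(config$success_rate * n))
  n_fail <- n - n_success
  if (n_fail < 1L) {
    stop("no scheduled imprecision: `success_rate` leaves no failed trial",
         call. = FALSE)
  }

  recognized <- rep(TRUE, n)
  fail_pos <- withr::with_seed(config$seed, sample.int(n, n_fail))
  recognized[fail_pos] <- FALSE

  n_help <- as.integer(round_away(config$help_rate * n))
  help_flag <- rep(FALSE, n)
  if (config$condition %in% c("MITIGATED_FAILURE", "INPUT_OVERRIDE")) {
    help_flag[which(!recognized)[seq_len(n_help)]] <- TRUE
  } else if (config$condition == "AUGMENTED_SUCCESS") {
    help_flag[which(recognized)[seq_len(n_help)]] <- TRUE
  }

  structure(
    list(recognized = recognized, help_flag = help_flag),
    class = "pam_trial_schedule"
  )
}

#' @export
print.pam_trial_schedule <- function(x, ...) {
  cat(sprintf("<pam_trial_schedule> %d trials, %d recognized, %d help\n",
              length(x$recognized), sum(x$recognized), sum(x$help_flag)))
  invisible(x)
}
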