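#' @keywords internal
"_PACKAGE"

# Conditions and augmented-success variants -----------------------------------

#' Game conditions
#'
#' The four experimental conditions of the fishing game: the unassisted
#' reference condition and the three performance accommodation mechanisms
#' (augmented success, mitigated failure, input override).
#'
#' @return Character vector of the condition names.
#' @export
pam_conditions <- function() {
  c("REFERENCE", "AUGMENTED_SUCCESS", "MITIGATED_FAILURE", "INPUT_OVERRIDE")
}

#' @rdname pam_conditions
#' @export
pam_variants <- function() c("CONSTRAINED", "REDESIGNED")

# round-half-away-from-zero; used for all rate-to-count conversions so that
# e.g. 0.5 * 5 trials -> 3, never banker's-rounded to 2
round_away <- function(x) trunc(x + 0.5 * sign(x))

#' Build a game session configuration
#'
#' Constructs and validates the configuration of one fishing-game session:
#' the help condition, the scheduled per-trial recognition (success) rate
#' emulating imprecise brain-computer-interface style input, the help rate
#' (the designed cap on extra help), and the lane geometry.
#'
#' The success rate must be strictly below 1: every session is designed to
#' contain at least one scheduled failure so the player always experiences
#' system imprecision. For the failure-triggered mechanisms (mitigated
#' failure, input override) the help rate cannot exceed the failure rate;
#' for augmented success it cannot exceed the success rate.
#'
#' @param condition One of [pam_conditions()].
#' @param augmented_variant Activation rule for augmented success:
#'   `"CONSTRAINED"` (help applies only when two full lanes can be reeled
#'   without catching; otherwise the trial degrades to a plain reel and the
#'   help is left unconsumed) or `"REDESIGNED"` (the boost may also complete
#'   a catch when the fish is within two lanes of the top).
#' @param n_trials Number of reel attempts in the session (default 20).
#' @param success_rate Fraction of trial periods in which blinks are
#'   recognized (default 0.70). Must lie in (0, 1).
#' @param help_rate Designed fraction of trials receiving help feedback
#'   (default 0.30 for help conditions, 0 for the reference condition).
#' @param n_lanes Number of horizontal lanes; lane 1 is the top-most,
#'   closest to the fisherman.
#' @param spawn_lane_distribution Probability vector over lanes `2..n_lanes`
#'   (named or in lane order) from which a newly hooked fish's lane is
#'   drawn. The top lane gets probability 0 by construction: a fish hooked
#'   there would need no reel-up before the catch attempt.
#' @param escape_threshold Number of failed reel periods after which a fish
#'   escapes (default 3).
#' @param escape_reset_on_success Should a successful reel reset the fish's
#'   escape progress? Default `FALSE`: progress is cumulative per fish.
#' @param trial_ticks,rest_ticks,help_ticks Simulated time units per trial
#'   period, per rest period, and per played help animation. Durations are
#'   reported in ticks, never wall-clock.
#' @param seed Integer seed; all schedule, spawn and agent randomness in
#'   [run_session()] derives from it.
#'
#' @return A `pam_game_config` list.
#' @examples
#' cfg <- game_config("MITIGATED_FAILURE", seed = 1)
#' cfg$help_rate
#' @export
game_config <- function(condition = "REFERENCE",
                        augmented_variant = "CONSTRAINED",
                        n_trials = 20L,
                        success_rate = 0.70,
                        help_rate = if (condition == "REFERENCE") 0 else 0.30,
                        n_lanes = 3L,
                        spawn_lane_distribution = NULL,
                        escape_threshold = 3L,
                        escape_reset_on_success = FALSE,
                        trial_ticks = 5L,
                        rest_ticks = 2L,
                        help_ticks = 3L,
                        seed = 1L) {
  condition <- match.arg(condition, pam_conditions())
  augmented_variant <- match.arg(augmented_variant, pam_variants())
  n_trials <- as.integer(n_trials)
  n_lanes <- as.integer(n_lanes)
  escape_threshold <- as.integer(escape_threshold)

  if (n_trials < 1L) stop("`n_trials` must be a positive integer", call. = FALSE)
  if (n_lanes < 2L) stop("`n_lanes` must be at least 2", call. = FALSE)
  if (escape_threshold < 1L) stop("`escape_threshold` must be positive", call. = FALSE)
  if (!is.numeric(success_rate) || success_rate <= 0 || success_rate >= 1) {
    stop("`success_rate` must lie in (0, 1): every session must contain ",
         "at least one scheduled failure (no scheduled imprecision otherwise)",
         call. = FALSE)
  }
  if (!is.numeric(help_rate) || help_rate < 0 || help_rate >= 1) {
    stop("`help_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (condition == "REFERENCE" && help_rate > 0) {
    stop("the reference condition provides no help; `help_rate` must be 0",
         call. = FALSE)
  }
  if (condition %in% c("MITIGATED_FAILURE", "INPUT_OVERRIDE") &&
      help_rate > 1 - success_rate + 1e-12) {
    stop("failure-triggered help requires `help_rate` <= 1 - `success_rate`",
         call. = FALSE)
  }
  if (condition == "AUGMENTED_SUCCESS" && help_rate > success_rate + 1e-12) {
    stop("success-triggered help requires `help_rate` <= `success_rate`",
         call. = FALSE)
  }

  if (is.null(spawn_lane_distribution)) {
    spawn_lane_distribution <- rep(1 / (n_lanes - 1), n_lanes - 1)
    names(spawn_lane_distribution) <- as.character(2:n_lanes)
  }
  spawn_lane_distribution <- validate_spawn_distribution(
    spawn_lane_distribution, n_lanes
  )

  if (any(c(trial_ticks, rest_ticks, help_ticks) < 0)) {
    stop("tick constants must be nonnegative", call. = FALSE)
  }

  structure(
    list(
      condition = condition,
      augmented_variant = augmented_variant,
      n_trials = n_trials,
      success_rate = success_rate,
      help_rate = help_rate,
      n_lanes = n_lanes,
      spawn_lane_distribution = spawn_lane_distribution,
      escape_threshold = escape_threshold,
      escape_reset_on_success = isTRUE(escape_reset_on_success),
      trial_ticks = as.integer(trial_ticks),
      rest_ticks = as.integer(rest_ticks),
      help_ticks = as.integer(help_ticks),
      seed = as.integer(seed)
    ),
    class = "pam_game_config"
  )
}

validate_spawn_distribution <- function(p, n_lanes) {
  if (length(p) != n_lanes - 1L) {
    stop("`spawn_lane_distribution` must have one probability per lane 2..",
         n_lanes, call. = FALSE)
  }
  if (is.null(names(p))) names(p) <- as.character(2:n_lanes)
  if (!setequal(names(p), as.character(2:n_lanes))) {
    stop("`spawn_lane_distribution` names must be lanes 2..", n_lanes,
         " (the top lane is never a spawn lane)", call. = FALSE)
  }
  p <- p[as.character(2:n_lanes)]
  if (any(p < 0)) stop("spawn probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("`spawn_lane_distribution` must sum to 1 (tolerance 1e-9), got ",
         format(sum(p)), call. = FALSE)
  }
  p
}

#' @export
print.pam_game_config <- function(x, ...) {
  cat("<pam_game_config>\n")
  cat(sprintf("  condition: %s%s\n", x$condition,
              if (x$condition == "AUGMENTED_SUCCESS")
                paste0(" (", x$augmented_variant, ")") else ""))
  cat(sprintf("  trials: %d  success rate: %.2f  help rate: %.2f\n",
              x$n_trials, x$success_rate, x$help_rate))
  cat(sprintf("  lanes: %d  escape threshold: %d  seed: %d\n",
              x$n_lanes, x$escape_threshold, x$seed))
  invisible(x)
}
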