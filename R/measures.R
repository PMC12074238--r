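# Session summary measures, screening, and violin-plot preparation.

#' Compute the summary measures of one session
#'
#' From a complete event log, computes the per-session game measures:
#'
#' * `blink_recognition` — fraction of trials containing at least one
#'   in-range blink (superfluous blinks in failed trials are ignored).
#' * `blink_conv_rate` — player reel-up and catch events divided by the
#'   total number of blinks across all trial windows (0 when no blinks
#'   occurred). Catches count (the catch is the final reel); help-driven
#'   reels do not (no blink of the player caused them).
#' * `pos_feedback` — fraction of trials ending in a reel-up or catch, by
#'   blink or by help. Clamps, unreels and losses are not positive.
#' * `help_rate` — fraction of trials ending with help feedback.
#' * `fish_caught`, `fish_lost`, `fish_reel`, `fish_unreel` — event counts
#'   (a loss requires `escape_threshold` failed trials and replaces the
#'   final unreel).
#' * `duration_ticks` — total simulated time units.
#'
#' @param log A `pam_event_log` from [run_session()] or [read_event_log()].
#' @return A `pam_session_measures` one-row data frame.
#' @examples
#' m <- compute_session_measures(run_session(game_config(seed = 1)))
#' m$pos_feedback  # 0.70 with the ideal agent
#' @export
compute_session_measures <- function(log) {
  validate_event_log(log)
  n <- nrow(log)
  total_blinks <- sum(log$blink_count)
  player_pos <- sum(log$outcome %in% c("PLAYER_REEL", "PLAYER_CATCH"))
  positive <- log$outcome %in% positive_outcomes

  out <- data.frame(
    blink_recognition = mean(log$in_range),
    blink_conv_rate = if (total_blinks > 0) player_pos / total_blinks else 0,
    pos_feedback = mean(positive),
    help_rate = mean(log$help),
    fish_caught = sum(log$outcome %in% catch_outcomes),
    fish_lost = sum(log$outcome == "LOSS"),
    fish_reel = sum(log$outcome %in% reel_outcomes),
    fish_unreel = sum(log$outcome == "UNREEL"),
    duration_ticks = sum(log$ticks)
  )
  cfg <- attr(log, "config")
  if (!is.null(cfg)) {
    out$condition <- cfg$condition
    out$seed <- cfg$seed
  }
  lbl <- attr(log, "agent_label")
  if (!is.null(lbl)) out$agent <- lbl
  class(out) <- c("pam_session_measures", "data.frame")
  out
}

#' Screen sessions for absent blink recognition
#'
#' Flags sessions whose blink-recognition measure falls at or below a
#' threshold for exclusion from subsequent analysis. The default threshold
#' of 0 excludes only sessions with no blink recognition at all (total
#' sensor failure or a non-blinking participant).
#'
#' @param measures A data frame with a `blink_recognition` column (e.g.
#'   stacked rows of [compute_session_measures()]).
#' @param exclusion_threshold Sessions with
#'   `blink_recognition <= exclusion_threshold` are flagged `"exclude"`.
#' @return Character vector of `"keep"`/`"exclude"`, one per row.
#' @export
flag_recognition_anomalies <- function(measures, exclusion_threshold = 0) {
  stopifnot(is.data.frame(measures), "blink_recognition" %in% names(measures),
            nrow(measures) >= 1L)
  ifelse(measures$blink_recognition <= exclusion_threshold, "exclude", "keep")
}

#' Normalize and jitter ratings for violin plots
#'
#' Maps seven-point ratings from 1–7 onto 0–1 via `(v - 1) / 6` and adds
#' uniform jitter of plus/minus `jitter_fraction` to mitigate overplotting,
#' clipping to `[-jitter_fraction, 1 + jitter_fraction]`. This is a purely
#' visual transform; analysis always treats the ratings as ordinal.
#'
#' @param ratings Integer vector with values in 1..7.
#' @param jitter_fraction Half-width of the uniform jitter (default 0.02).
#' @param seed Seed for the jitter draws.
#' @return Data frame with columns `rating` and `value` (plot-ready).
#' @examples
#' prep_violin_data(c(1L, 4L, 7L), jitter_fraction = 0)$value  # 0, 0.5, 1
#' @export
prep_violin_data <- function(ratings, jitter_fraction = 0.02, seed = 1L) {
  if (!all(ratings %in% 1:7)) {
    stop("ratings must be integers in 1..7", call. = FALSE)
  }
  stopifnot(jitter_fraction >= 0)
  norm <- (as.numeric(ratings) - 1) / 6
  value <- withr::with_seed(seed, {
    norm + stats::runif(length(norm), -jitter_fraction, jitter_fraction)
  })
  value <- pmin(pmax(value, -jitter_fraction), 1 + jitter_fraction)
  data.frame(rating = as.integer(ratings), value = value)
}
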