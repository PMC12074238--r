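# Stochastic blink-behavior models. An agent decides, per reel trial,
# whether it blinks at all (compliance), how many times (1 + truncated
# Poisson when it blinks), and whether at least one blink lands inside the
# eye tracker's range.

#' Define an agent's blink behavior
#'
#' @param blink_lambda Mean parameter of the truncated `1 + Poisson(lambda)`
#'   blink-count distribution used on compliant trials (players blink one or
#'   more times per attempted trial). `blink_lambda = 0` gives exactly one
#'   blink per compliant trial.
#' @param max_blinks Upper truncation for the per-trial blink count.
#' @param in_range_probability Per-trial probability that at least one blink
#'   lands in the tracker's range, given the agent blinked (models leaning
#'   out of range as an independent per-trial Bernoulli draw).
#' @param compliance_probability Probability the agent blinks at all during
#'   a trial window (models forgetting to blink as instructed).
#' @param label Free-text name of the profile.
#'
#' @details The expected per-trial blink recognition of a profile is
#'   `compliance_probability * in_range_probability`, and the expected
#'   blink count is `compliance_probability * (1 + E[truncated Poisson])`.
#'
#' @return A `pam_agent` list.
#' @seealso [preset_profiles()] for the cohort presets.
#' @export
agent_profile <- function(blink_lambda = 0,
                          max_blinks = 10L,
                          in_range_probability = 1,
                          compliance_probability = 1,
                          label = "custom") {
  stopifnot(
    is.numeric(blink_lambda), blink_lambda >= 0,
    max_blinks >= 1,
    in_range_probability >= 0, in_range_probability <= 1,
    compliance_probability >= 0, compliance_probability <= 1
  )
  structure(
    list(
      blink_lambda = blink_lambda,
      max_blinks = as.integer(max_blinks),
      in_range_probability = in_range_probability,
      compliance_probability = compliance_probability,
      label = label
    ),
    class = "pam_agent"
  )
}

#' Simulate the agent's blinks for one trial window
#'
#' @param profile A [agent_profile()].
#' @return List with `blink_count` (0 on non-compliant trials) and
#'   `any_in_range` (`TRUE` only when the agent blinked and the in-range
#'   draw succeeded). Draws from the current R random-number stream.
#' @examples
#' withr::with_seed(1, simulate_trial_blinks(preset_profiles()$ideal))
#' @export
simulate_trial_blinks <- function(profile) {
  stopifnot(inherits(profile, "pam_agent"))
  if (stats::runif(1) >= profile$compliance_probability) {
    return(list(blink_count = 0L, any_in_range = FALSE))
  }
  extra <- stats::rpois(1, profile$blink_lambda)
  blink_count <- 1L + min(as.integer(extra), profile$max_blinks - 1L)
  any_in_range <- stats::runif(1) < profile$in_range_probability
  list(blink_count = blink_count, any_in_range = any_in_range)
}

#' Cohort-calibrated agent presets
#'
#' * `ideal` — exactly one in-range blink every trial (recognition 1.0).
#' * `study1_patient` — a sub-acute stroke-patient-like profile: about 2.1
#'   blinks per trial, per-trial recognition 0.88 (split between occasional
#'   non-compliance, 0.95, and leaning out of tracker range).
#' * `study2_gamer` — an experienced-gamer profile: always blinks, near-
#'   perfect recognition (0.99), about 2.7 blinks per trial.
#' * `absent` — never blinks (compliance 0); yields zero recognition.
#'
#' @return Named list of [agent_profile()] objects.
#' @export
preset_profiles <- function() {
  list(
    ideal = agent_profile(0, 1L, 1, 1, label = "ideal"),
    study1_patient = agent_profile(
      blink_lambda = 2.1 / 0.95 - 1, # overall mean 2.1 blinks per trial
      in_range_probability = 0.88 / 0.95, # recognition = .95 * this = .88
      compliance_probability = 0.95,
      label = "study1_patient"
    ),
    study2_gamer = agent_profile(
      blink_lambda = 1.7, # mean 2.7 blinks per trial
      in_range_probability = 0.99,
      compliance_probability = 1,
      label = "study2_gamer"
    ),
    absent = agent_profile(0, 1L, 0, 0, label = "absent")
  )
}

#' Analytic per-trial recognition probability of a profile
#' @param profile A [agent_profile()].
#' @return `compliance_probability * in_range_probability`.
#' @export
expected_recognition <- function(profile) {
  stopifnot(inherits(profile, "pam_agent"))
  profile$compliance_probability * profile$in_range_probability
}
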