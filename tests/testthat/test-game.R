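fish_at <- function(lane, progress = 0L, id = 1L) {
  structure(list(lane = as.integer(lane), escape_progress = as.integer(progress),
                 fish_id = as.integer(id)), class = "pam_fish")
}

test_that("spawning respects the lane distribution and never uses the top lane", {
  cfg <- game_config(spawn_lane_distribution = c(`2` = 1, `3` = 0), seed = 1)
  f <- withr::with_seed(1, spawn_fish(cfg))
  expect_equal(f$lane, 2)
  expect_equal(f$escape_progress, 0)

  # same seed -> identical lane sequence
  draw <- function() withr::with_seed(11, {
    replicate(50, spawn_fish(game_config(seed = 11))$lane)
  })
  expect_identical(draw(), draw())

  # uniform over {2, 3}: mean within 3 binomial SEs of 2.5
  lanes <- withr::with_seed(2, replicate(1e4, spawn_fish(game_config())$lane))
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(lanes) - 2.5), 3 * se)
  expect_true(all(lanes %in% 2:3))
})

test_that("single-trial resolution follows the game rules", {
  ref <- game_config("REFERENCE", seed = 1)
  as_r <- game_config("AUGMENTED_SUCCESS", augmented_variant = "REDESIGNED",
                      seed = 1)
  as_c <- game_config("AUGMENTED_SUCCESS", augmented_variant = "CONSTRAINED",
                      seed = 1)
  mf <- game_config("MITIGATED_FAILURE", seed = 1)
  io <- game_config("INPUT_OVERRIDE", seed = 1)

  # catch from the top lane on a recognized blink
  r <- resolve_trial(fish_at(1), TRUE, TRUE, FALSE, ref)
  expect_equal(r$outcome, "PLAYER_CATCH")
  expect_true(r$positive)
  expect_null(r$fish_after)

  # augmented success reels two lanes
  r <- resolve_trial(fish_at(3), TRUE, TRUE, TRUE, as_r)
  expect_equal(r$outcome, "HELP_DOUBLE_REEL")
  expect_equal(r$fish_after$lane, 1)

  # redesigned boost completes the catch within two lanes of the top
  expect_equal(resolve_trial(fish_at(2), TRUE, TRUE, TRUE, as_r)$outcome,
               "HELP_DOUBLE_CATCH")
  expect_equal(resolve_trial(fish_at(1), TRUE, TRUE, TRUE, as_r)$outcome,
               "HELP_DOUBLE_CATCH")

  # constrained boost degrades when a double reel would overshoot;
  # the help flag is not consumed
  r <- resolve_trial(fish_at(2), TRUE, TRUE, TRUE, as_c)
  expect_equal(r$outcome, "PLAYER_REEL")
  expect_false(r$help_feedback)
  expect_equal(resolve_trial(fish_at(3), TRUE, TRUE, TRUE, as_c)$outcome,
               "HELP_DOUBLE_REEL")

  # third failed reel period loses the fish (loss replaces the unreel)
  r <- resolve_trial(fish_at(2, progress = 2), FALSE, TRUE, FALSE, ref)
  expect_equal(r$outcome, "LOSS")
  expect_false(r$positive)
  expect_null(r$fish_after)

  # clamp freezes escape progress and is not positive feedback
  r <- resolve_trial(fish_at(2, progress = 1), FALSE, TRUE, TRUE, mf)
  expect_equal(r$outcome, "HELP_CLAMP")
  expect_equal(r$fish_after$escape_progress, 1)
  expect_false(r$positive)
  expect_true(r$help_feedback)

  # override help reels exactly as a player success would
  r <- resolve_trial(fish_at(1), FALSE, TRUE, TRUE, io)
  expect_equal(r$outcome, "HELP_OVERRIDE_CATCH")
  expect_true(r$positive)

  # a recognized trial without an in-range blink is a failure
  r <- resolve_trial(fish_at(2), TRUE, FALSE, FALSE, ref)
  expect_equal(r$outcome, "UNREEL")

  # help against the trigger direction is rejected
  expect_error(resolve_trial(fish_at(2), TRUE, TRUE, TRUE, mf),
               "trigger direction")
  expect_error(resolve_trial(fish_at(2), FALSE, FALSE, TRUE, as_r),
               "trigger direction")
  expect_error(resolve_trial(fish_at(2), TRUE, TRUE, TRUE, ref),
               "trigger direction")
})

test_that("sessions are reproducible and respect the schedule counts", {
  cfg <- game_config("REFERENCE", seed = 3)
  expect_identical(run_session(cfg), run_session(cfg))

  log <- run_session(cfg)
  expect_equal(nrow(log), 20)
  expect_equal(sum(log$outcome %in%
                     c("PLAYER_REEL", "PLAYER_CATCH", "HELP_DOUBLE_REEL",
                       "HELP_DOUBLE_CATCH", "HELP_OVERRIDE_REEL",
                       "HELP_OVERRIDE_CATCH")), 14)

  # never-blinking agent: zero positive trials regardless of schedule
  absent <- run_session(cfg, preset_profiles()$absent)
  expect_equal(sum(absent$effective_recognized), 0)
  expect_true(all(absent$outcome %in% c("UNREEL", "LOSS")))

  # override help on every failure: no unreels, no losses
  io <- run_session(game_config("INPUT_OVERRIDE", seed = 3))
  expect_equal(sum(io$outcome %in% c("UNREEL", "LOSS")), 0)
})

test_that("positive- and negative-side conservation identities hold across random sessions", {
  set.seed(123)
  for (rep in 1:60) {
    cond <- sample(pam_conditions(), 1)
    n <- sample(5:30, 1)
    success <- runif(1, 0.3, min(0.9, 1 - 0.6 / n))
    max_help <- if (cond == "REFERENCE") 0 else
      if (cond == "AUGMENTED_SUCCESS") success else 1 - success
    help <- if (cond == "REFERENCE") 0 else runif(1, 0, max_help)
    agent <- sample(c("ideal", "study1_patient", "study2_gamer"), 1)
    cfg <- game_config(cond, augmented_variant = sample(pam_variants(), 1),
                       n_trials = n, success_rate = success, help_rate = help,
                       n_lanes = sample(2:5, 1), seed = rep)
    log <- run_session(cfg, preset_profiles()[[agent]])

    eff <- log$effective_recognized
    override <- log$outcome %in% c("HELP_OVERRIDE_REEL", "HELP_OVERRIDE_CATCH")
    pos <- log$outcome %in% c("PLAYER_REEL", "PLAYER_CATCH",
                              "HELP_DOUBLE_REEL", "HELP_DOUBLE_CATCH",
                              "HELP_OVERRIDE_REEL", "HELP_OVERRIDE_CATCH")
    expect_equal(sum(pos), sum(eff) + sum(override))
    neg <- log$outcome %in% c("UNREEL", "LOSS", "HELP_CLAMP")
    expect_equal(sum(neg) + sum(override), sum(!eff))
  }
})

test_that("an independent state machine reproduces every session outcome", {
  set.seed(9)
  for (rep in 1:40) {
    cond <- sample(pam_conditions(), 1)
    cfg <- game_config(cond, augmented_variant = sample(pam_variants(), 1),
                       n_trials = sample(4:6, 1), success_rate = 0.5,
                       help_rate = if (cond == "REFERENCE") 0 else 0.25,
                       n_lanes = 3, seed = rep)
    log <- run_session(cfg, preset_profiles()$study1_patient)
    oracle <- oracle_session(
      recognized = log$scheduled_recognized, in_range = log$in_range,
      help_flag = log$help_scheduled, condition = cond,
      variant = cfg$augmented_variant,
      spawn_lanes = observed_spawn_lanes(log),
      escape_threshold = cfg$escape_threshold
    )
    expect_equal(log$outcome, oracle$outcome)
    expect_equal(log$fish_id, oracle$fish_id)
    expect_equal(log$lane_before, oracle$lane_before)
  }
})

test_that("small sessions stay within the exhaustively enumerated reachable set", {
  # enumerate all spawn-lane sequences (at most 4 fish, lanes {2, 3})
  seqs <- as.matrix(expand.grid(rep(list(2:3), 4)))
  for (cond in c("AUGMENTED_SUCCESS", "MITIGATED_FAILURE", "REFERENCE")) {
    for (seed in 1:8) {
      cfg <- game_config(cond, augmented_variant = "CONSTRAINED",
                         n_trials = 4, success_rate = 0.5,
                         help_rate = if (cond == "REFERENCE") 0 else 0.25,
                         n_lanes = 3, seed = seed)
      sched <- build_trial_schedule(cfg)
      reachable <- apply(seqs, 1, function(lanes) {
        paste(oracle_session(sched$recognized, rep(TRUE, 4), sched$help_flag,
                             cond, "CONSTRAINED", lanes)$outcome,
              collapse = "|")
      })
      log <- run_session(cfg)
      expect_true(paste(log$outcome, collapse = "|") %in% reachable)
    }
  }
})

test_that("switching reference to input override never hurts the catch tally", {
  for (seed in 1:25) {
    ref <- compute_session_measures(
      run_session(game_config("REFERENCE", seed = seed)))
    io <- compute_session_measures(
      run_session(game_config("INPUT_OVERRIDE", seed = seed)))
    expect_gte(io$fish_caught, ref$fish_caught)
    expect_lte(io$fish_lost, ref$fish_lost)
  }
})

test_that("escape progress can optionally reset on success", {
  cfg <- game_config("REFERENCE", escape_reset_on_success = TRUE, seed = 1)
  f <- fish_at(3, progress = 2)
  r <- resolve_trial(f, TRUE, TRUE, FALSE, cfg)
  expect_equal(r$fish_after$escape_progress, 0)
  cfg2 <- game_config("REFERENCE", seed = 1)
  expect_equal(resolve_trial(f, TRUE, TRUE, FALSE, cfg2)$fish_after$escape_progress, 2)
})
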