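# Independent oracles used across the suite. These deliberately do not
# share code with the package internals they check.

# ---- ordinal likelihood oracles --------------------------------------------

# fixed-effects cumulative-logit log-likelihood by direct summation
oracle_direct_loglik <- function(theta, beta, data, fixed = character()) {
  up <- c(theta, Inf)
  lo <- c(-Inf, theta)
  eta <- if (length(fixed)) {
    drop(as.matrix(data[fixed]) %*% beta)
  } else {
    rep(0, nrow(data))
  }
  sum(log(plogis(up[data$rating] - eta) - plogis(lo[data$rating] - eta)))
}

# marginal log-likelihood by adaptive Gauss-Hermite quadrature (61 nodes),
# centered and scaled at each group's conditional mode
oracle_agq_loglik <- function(theta, beta, sigma, data, fixed = character(),
                              n_nodes = 61) {
  nodes <- pracma::gaussHermite(n_nodes)
  up <- c(theta, Inf)
  lo <- c(-Inf, theta)
  eta_all <- if (length(fixed)) {
    drop(as.matrix(data[fixed]) %*% beta)
  } else {
    rep(0, nrow(data))
  }
  total <- 0
  for (g in unique(data$participant)) {
    idx <- which(data$participant == g)
    y <- data$rating[idx]
    eta <- eta_all[idx]
    condll <- function(u) {
      sum(log(pmax(plogis(up[y] - eta - u) - plogis(lo[y] - eta - u),
                   1e-300)))
    }
    h <- function(u) -condll(u) + u^2 / (2 * sigma^2)
    mu <- optimize(h, c(-50, 50), tol = 1e-10)$minimum
    s2 <- 1 / ((h(mu + 1e-4) - 2 * h(mu) + h(mu - 1e-4)) / 1e-8)
    s <- sqrt(s2)
    u <- mu + sqrt(2) * s * nodes$x
    lf <- vapply(u, condll, numeric(1)) + dnorm(u, 0, sigma, log = TRUE) +
      (u - mu)^2 / (2 * s2)
    m <- max(lf)
    total <- total + log(sum(nodes$w * exp(lf - m))) + m + log(sqrt(2) * s)
  }
  total
}

# closed-form cell probabilities of the cumulative-logit model (sd = 0)
oracle_cell_probs <- function(theta, eta) {
  cum <- c(plogis(theta - eta), 1)
  diff(c(0, cum))
}

# ---- game-session oracle ----------------------------------------------------

# Minimal independent state machine for the reel loop: given the schedule,
# the agent's in-range outcomes, and the spawn-lane sequence, recompute the
# outcome of every trial.
oracle_session <- function(recognized, in_range, help_flag, condition,
                           variant = "CONSTRAINED", spawn_lanes,
                           escape_threshold = 3, reset_on_success = FALSE) {
  n <- length(recognized)
  outcome <- character(n)
  fish_ids <- integer(n)
  lanes_before <- integer(n)
  fid <- 0L
  next_spawn <- 1L
  need_fish <- TRUE
  lane <- NA_integer_
  prog <- 0L
  for (i in seq_len(n)) {
    if (need_fish) {
      fid <- fid + 1L
      lane <- spawn_lanes[next_spawn]
      next_spawn <- next_spawn + 1L
      prog <- 0L
      need_fish <- FALSE
    }
    fish_ids[i] <- fid
    lanes_before[i] <- lane
    succ <- recognized[i] && in_range[i]
    hf <- help_flag[i]
    if (succ) {
      if (condition == "AUGMENTED_SUCCESS" && hf) {
        if (variant == "REDESIGNED") {
          if (lane <= 2L) {
            o <- "HELP_DOUBLE_CATCH"; need_fish <- TRUE
          } else {
            o <- "HELP_DOUBLE_REEL"; lane <- lane - 2L
          }
        } else {
          if (lane >= 3L) {
            o <- "HELP_DOUBLE_REEL"; lane <- lane - 2L
          } else if (lane == 1L) {
            o <- "PLAYER_CATCH"; need_fish <- TRUE
          } else {
            o <- "PLAYER_REEL"; lane <- lane - 1L
          }
        }
      } else if (lane == 1L) {
        o <- "PLAYER_CATCH"; need_fish <- TRUE
      } else {
        o <- "PLAYER_REEL"; lane <- lane - 1L
      }
      if (!need_fish && reset_on_success) prog <- 0L
    } else {
      if (hf && condition == "MITIGATED_FAILURE") {
        o <- "HELP_CLAMP"
      } else if (hf && condition == "INPUT_OVERRIDE") {
        if (lane == 1L) {
          o <- "HELP_OVERRIDE_CATCH"; need_fish <- TRUE
        } else {
          o <- "HELP_OVERRIDE_REEL"; lane <- lane - 1L
        }
      } else {
        prog <- prog + 1L
        if (prog >= escape_threshold) {
          o <- "LOSS"; need_fish <- TRUE
        } else {
          o <- "UNREEL"
        }
      }
    }
    outcome[i] <- o
  }
  data.frame(trial = seq_len(n), fish_id = fish_ids,
             lane_before = lanes_before, outcome = outcome)
}

# spawn lanes actually used in a session, in spawn order
observed_spawn_lanes <- function(log) {
  log$lane_before[!duplicated(log$fish_id)]
}

# ---- rank/correlation oracles ----------------------------------------------

# brute-force midranks: 1 + count(smaller) + (count(equal) - 1) / 2
oracle_midrank <- function(v) {
  vapply(seq_along(v), function(i) {
    1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  cor(oracle_midrank(x), oracle_midrank(y))
}
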