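# Synthetic ordinal (Likert) self-report data, generated from the inverse
# of the cumulative-logit mixed model: participant random intercepts plus
# game-measure fixed effects on the log-odds scale.

#' Specify a generative cumulative-logit rating model
#'
#' @param outcome_label Name of the self-report outcome (e.g.
#'   `"perceived_control"`).
#' @param fixed_effects Named numeric vector mapping covariate columns
#'   (game measures or condition indicators) to log-odds coefficients per
#'   raw unit.
#' @param random_intercept_sd Standard deviation of the Gaussian
#'   participant random intercept (log-odds scale).
#' @param cutpoints Strictly increasing vector of 6 cutpoints for the
#'   7-point scale, or `NULL` (the default) to center 6 equally spaced
#'   cutpoints (spacing 1) on the covariate-mean linear predictor at
#'   generation time, which keeps the generated ratings non-degenerate
#'   across covariate ranges.
#' @param seed Default seed for [generate_ratings()].
#' @return A `pam_rating_spec` list.
#' @export
rating_model_spec <- function(outcome_label,
                              fixed_effects = numeric(),
                              random_intercept_sd = 0,
                              cutpoints = NULL,
                              seed = 1L) {
  stopifnot(is.numeric(random_intercept_sd), random_intercept_sd >= 0)
  fixed_effects <- unlist(fixed_effects)
  if (length(fixed_effects) && is.null(names(fixed_effects))) {
    stop("`fixed_effects` must be named by covariate", call. = FALSE)
  }
  if (!is.null(cutpoints)) {
    cutpoints <- as.numeric(cutpoints)
    if (length(cutpoints) != 6L || any(diff(cutpoints) <= 0)) {
      stop("`cutpoints` must be 6 strictly increasing values", call. = FALSE)
    }
  }
  structure(
    list(
      outcome_label = outcome_label,
      fixed_effects = fixed_effects,
      random_intercept_sd = random_intercept_sd,
      cutpoints = cutpoints,
      seed = as.integer(seed)
    ),
    class = "pam_rating_spec"
  )
}

#' Default generative rating specifications
#'
#' Parameterized by the fitted feedback-based models of the stroke-patient
#' cohort: perceived control rises by 0.61 log-odds per fish reeled with a
#' participant random-intercept SD of 2.31; frustration falls by 0.24 per
#' fish reeled and rises by 0.37 per fish lost.
#'
#' @return Named list of [rating_model_spec()] objects
#'   (`perceived_control`, `frustration`).
#' @export
default_rating_specs <- function() {
  list(
    perceived_control = rating_model_spec(
      "perceived_control",
      fixed_effects = c(fish_reel = 0.61),
      random_intercept_sd = 2.31
    ),
    frustration = rating_model_spec(
      "frustration",
      fixed_effects = c(fish_reel = -0.24, fish_lost = 0.37),
      random_intercept_sd = 1.5
    )
  )
}

#' Generate ordinal ratings from a cumulative-logit model
#'
#' For each participant `i` a random intercept `u_i ~ Normal(0, sd^2)` is
#' drawn; the rating of each row is then drawn from the cumulative-logit
#' cell probabilities `P(Y <= j) = plogis(cutpoint_j - x'beta - u_i)`.
#'
#' @param covariates Data frame of per-participant-per-condition measures;
#'   must contain every fixed-effect column of `spec`. If it has a
#'   `participant` column, one random intercept is drawn per unique
#'   participant; otherwise `n_participants` copies of the table are
#'   stacked, one per synthetic participant.
#' @param spec A [rating_model_spec()].
#' @param n_participants Number of synthetic participants when `covariates`
#'   has no `participant` column.
#' @param seed Seed; defaults to `spec$seed`.
#' @return A `pam_rating_dataset` data frame in long format: `participant`,
#'   `condition` (if present in `covariates`), the covariate columns,
#'   `outcome`, and `rating` in 1..7.
#' @examples
#' cov <- data.frame(condition = pam_conditions(),
#'                   fish_reel = c(8, 6, 12, 9))
#' gen <- generate_ratings(cov, default_rating_specs()$perceived_control,
#'                         n_participants = 5, seed = 1)
#' table(gen$rating)
#' @export
generate_ratings <- function(covariates, spec, n_participants = NULL,
                             seed = NULL) {
  stopifnot(inherits(spec, "pam_rating_spec"), is.data.frame(covariates))
  missing_cov <- setdiff(names(spec$fixed_effects), names(covariates))
  if (length(missing_cov)) {
    stop("covariates are missing fixed-effect column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (is.null(seed)) seed <- spec$seed

  if (!"participant" %in% names(covariates)) {
    if (is.null(n_participants)) {
      stop("`n_participants` is required when `covariates` has no ",
           "`participant` column", call. = FALSE)
    }
    covariates <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
      cbind(participant = i, covariates)
    }))
  }

  eta_fixed <- linear_predictor(covariates, spec$fixed_effects)
  cutpoints <- spec$cutpoints
  if (is.null(cutpoints)) {
    cutpoints <- mean(eta_fixed) + seq(-2.5, 2.5, by = 1)
  }

  participants <- unique(covariates$participant)
  rating <- withr::with_seed(seed, {
    u <- stats::rnorm(length(participants), 0, spec$random_intercept_sd)
    names(u) <- as.character(participants)
    eta <- eta_fixed + u[as.character(covariates$participant)]
    draw_ordinal(eta, cutpoints)
  })

  out <- covariates
  out$outcome <- spec$outcome_label
  out$rating <- rating
  rownames(out) <- NULL
  class(out) <- c("pam_rating_dataset", "data.frame")
  out
}

linear_predictor <- function(data, beta) {
  if (!length(beta)) return(rep(0, nrow(data)))
  X <- as.matrix(data[names(beta)])
  storage.mode(X) <- "double"
  drop(X %*% beta)
}

# Inverse-CDF draw from the cumulative-logit cell probabilities.
draw_ordinal <- function(eta, cutpoints) {
  cum <- stats::plogis(outer(eta, cutpoints, function(e, c) c - e))
  u <- stats::runif(length(eta))
  as.integer(rowSums(u > cum) + 1L)
}

validate_rating_dataset <- function(ratings) {
  stopifnot(is.data.frame(ratings))
  need <- c("participant", "rating")
  missing_cols <- setdiff(need, names(ratings))
  if (length(missing_cols)) {
    stop("rating dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(ratings$rating %in% 1:7)) {
    stop("ratings must be integers in 1..7", call. = FALSE)
  }
  invisible(ratings)
}
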