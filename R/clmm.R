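# Cumulative link mixed models (proportional odds with a Gaussian
# participant random intercept), fitted by maximizing the Laplace-
# approximated marginal likelihood. The cumulative-logit parameterization
# has no separate fixed intercept: it is absorbed into the cutpoints.

# ---- data preparation -------------------------------------------------------

prepare_clmm_data <- function(dataset, fixed = character()) {
  validate_rating_dataset(dataset)
  y_raw <- as.integer(dataset$rating)
  observed <- sort(unique(y_raw))
  if (length(observed) < 2L) {
    stop("need at least 2 distinct rating categories", call. = FALSE)
  }
  unobserved <- setdiff(seq(min(y_raw), max(y_raw)), observed)
  if (length(unobserved) || min(y_raw) > 1L || max(y_raw) < 7L) {
    # unused categories carry no likelihood contribution; their cutpoints
    # are unidentified, so adjacent cutpoints are collapsed
    warning("unobserved rating categories collapsed: ",
            paste(setdiff(1:7, observed), collapse = ", "), call. = FALSE)
  }
  y <- match(y_raw, observed)
  g <- factor(dataset$participant)
  if (any(table(g) == 0L)) stop("empty participant group", call. = FALSE)

  if (length(fixed)) {
    missing_cov <- setdiff(fixed, names(dataset))
    if (length(missing_cov)) {
      stop("dataset is missing covariate(s): ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    X <- stats::model.matrix(stats::reformulate(fixed), dataset)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  } else {
    X <- matrix(0, nrow = length(y), ncol = 0L)
  }

  list(
    y = y, X = X, gi = as.integer(g), n_groups = nlevels(g),
    n_cat = length(observed), observed = observed,
    fingerprint = c(n = length(y), sum_y = sum(y_raw),
                    sum_y2 = sum(y_raw^2), sum_g = sum(as.integer(g)))
  )
}

# ---- likelihood core --------------------------------------------------------

# logistic density derivative: f'(x) = f(x) (1 - 2 F(x))
dlogis_prime <- function(x) stats::dlogis(x) * (1 - 2 * stats::plogis(x))

# second derivative of the logistic density:
# f''(x) = f(x) ((1 - 2 F(x))^2 - 2 f(x))
dlogis_second <- function(x) {
  f <- stats::dlogis(x)
  s <- 1 - 2 * stats::plogis(x)
  f * (s^2 - 2 * f)
}

# Cell log-probability and its first/second derivatives with respect to
# the random intercept u, for the cumulative-logit cell
# p = F(upper - eta - u) - F(lower - eta - u). Where the difference of
# CDFs underflows, the logistic tail is linear on the log scale, so
# logp ~ za (left tail) or -zb (right tail) with slope +/-1 in u and
# vanishing curvature; those limits are substituted to keep the Newton
# iteration and the log-likelihood finite.
cell_terms <- function(upper, lower, eta, u_obs) {
  za <- upper - eta - u_obs
  zb <- lower - eta - u_obs
  p <- stats::plogis(za) - stats::plogis(zb)
  logp <- log(p)
  g1 <- (stats::dlogis(zb) - stats::dlogis(za)) / p
  g2 <- (dlogis_prime(za) - dlogis_prime(zb)) / p - g1^2

  tiny <- which(!is.finite(logp) | p < 1e-250)
  if (length(tiny)) {
    left <- za[tiny] < 0 # both cut distances in the lower tail
    logp[tiny] <- ifelse(left, za[tiny], -zb[tiny])
    g1[tiny] <- ifelse(left, -1, 1)
    g2[tiny] <- 0
  }
  list(logp = logp, g1 = g1, g2 = g2)
}

# Laplace-approximated marginal log-likelihood. theta: K-1 increasing
# cutpoints; beta aligned with columns of X; sigma >= 0. Vectorized over
# groups: the per-group conditional modes are found by a damped Newton
# iteration run simultaneously for all groups (each mode is a 1-D,
# log-concave problem, so the iteration is globally well behaved).
clmm_loglik_core <- function(theta, beta, sigma, y, X, gi, n_groups) {
  if (!all(is.finite(c(theta, beta, sigma)))) return(-Inf)
  K <- length(theta) + 1L
  upper <- c(theta, Inf)[y]
  lower <- c(-Inf, theta)[y]
  eta <- if (ncol(X)) drop(X %*% beta) else rep(0, length(y))

  if (sigma == 0) {
    return(sum(cell_terms(upper, lower, eta, rep(0, length(y)))$logp))
  }

  u <- clmm_modes(upper, lower, eta, sigma, gi, n_groups)
  if (is.null(u)) return(-Inf)

  cc <- cell_terms(upper, lower, eta, u[gi])
  hpp <- pmax(-drop(rowsum(cc$g2, gi)) + 1 / sigma^2, 1e-10)
  sum(cc$logp) - sum(u^2) / (2 * sigma^2) -
    n_groups * log(sigma) - 0.5 * sum(log(hpp))
}

# Logistic CDF, density, and density derivative from a single exp() call.
logistic_parts <- function(z) {
  e <- exp(-abs(z))
  d <- 1 + e
  F <- ifelse(z >= 0, 1 / d, e / d)
  f <- e / d^2
  list(F = F, f = f, f1 = f * (1 - 2 * F))
}

# First/second u-derivatives of the cell log-probability, log-free (used
# inside the Newton iteration for the conditional modes). Underflowing
# cells take their logistic tail limits.
cell_g12 <- function(upper, lower, eta, u_obs) {
  la <- logistic_parts(upper - eta - u_obs)
  lb <- logistic_parts(lower - eta - u_obs)
  p <- la$F - lb$F
  g1 <- (lb$f - la$f) / p
  g2 <- (la$f1 - lb$f1) / p - g1^2
  tiny <- which(p < 1e-250)
  if (length(tiny)) {
    left <- (upper - eta - u_obs)[tiny] < 0
    g1[tiny] <- ifelse(left, -1, 1)
    g2[tiny] <- 0
  }
  list(g1 = g1, g2 = g2)
}

# Conditional modes of the random intercepts (damped Newton, vectorized
# over groups, always cold-started at 0 so the iteration starts inside
# the concave basin); returns NULL when it fails to produce converged,
# finite modes.
clmm_modes <- function(upper, lower, eta, sigma, gi, n_groups) {
  u <- rep(0, n_groups)
  converged <- FALSE
  for (iter in 1:100) {
    cc <- cell_g12(upper, lower, eta, u[gi])
    hp <- -drop(rowsum(cc$g1, gi)) + u / sigma^2
    hpp <- pmax(-drop(rowsum(cc$g2, gi)) + 1 / sigma^2, 1e-10)
    if (!all(is.finite(hp))) return(NULL)
    if (max(abs(hp)) < 1e-8) { converged <- TRUE; break }
    u <- u - pmin(pmax(hp / hpp, -10), 10)
  }
  if (!converged) return(NULL)
  u
}

# Full per-cell derivative stack for the analytic gradient: logp, its
# first three derivatives in u, and the partials with respect to the two
# bounding cutpoints (via za and zb). Tail-underflowing cells use the
# log-linear logistic tail limits (slope +/-1, zero curvature).
cell_grad_terms <- function(upper, lower, eta, u_obs) {
  za <- upper - eta - u_obs
  zb <- lower - eta - u_obs
  Fa <- stats::plogis(za); fa <- stats::dlogis(za)
  Fb <- stats::plogis(zb); fb <- stats::dlogis(zb)
  f1a <- fa * (1 - 2 * Fa); f1b <- fb * (1 - 2 * Fb)
  f2a <- dlogis_second(za); f2b <- dlogis_second(zb)
  p <- Fa - Fb
  logp <- log(p)
  g1 <- (fb - fa) / p
  g2 <- (f1a - f1b) / p - g1^2
  dg1_dza <- -f1a / p - g1 * fa / p
  dg1_dzb <- f1b / p + g1 * fb / p
  dg2_dza <- f2a / p - (f1a - f1b) * fa / p^2 - 2 * g1 * dg1_dza
  dg2_dzb <- -f2b / p + (f1a - f1b) * fb / p^2 - 2 * g1 * dg1_dzb
  g3 <- -(dg2_dza + dg2_dzb)
  t1a <- fa / p
  t1b <- -fb / p

  tiny <- which(!is.finite(logp) | p < 1e-250)
  if (length(tiny)) {
    left <- za[tiny] < 0
    logp[tiny] <- ifelse(left, za[tiny], -zb[tiny])
    g1[tiny] <- ifelse(left, -1, 1)
    t1a[tiny] <- ifelse(left, 1, 0)
    t1b[tiny] <- ifelse(left, 0, -1)
    for (v in c("g2", "g3", "dg1_dza", "dg1_dzb", "dg2_dza", "dg2_dzb")) {
      vec <- get(v); vec[tiny] <- 0; assign(v, vec)
    }
  }
  list(logp = logp, g1 = g1, g2 = g2, g3 = g3,
       dg1_dza = dg1_dza, dg1_dzb = dg1_dzb,
       dg2_dza = dg2_dza, dg2_dzb = dg2_dzb,
       t1a = t1a, t1b = t1b)
}

# Laplace marginal log-likelihood with its analytic gradient in
# (cutpoints, slopes, sigma). The gradient uses the implicit-function
# theorem for the dependence of the conditional modes on the parameters:
# with H_g the per-group curvature and S3_g the third derivative of the
# conditional log-likelihood at the mode,
#   d l_g / d psi = A_psi + (C_psi + S3_g B_psi / H_g) / (2 H_g)
# where A, B, C are the group sums of the cell derivatives of logp, g1,
# g2 with respect to psi (the A-term envelope-cancels the mode shift in
# everything except the 0.5 log H curvature correction).
clmm_loglik_grad <- function(theta, beta, sigma, y, X, gi, n_groups) {
  K <- length(theta) + 1L
  upper <- c(theta, Inf)[y]
  lower <- c(-Inf, theta)[y]
  eta <- if (ncol(X)) drop(X %*% beta) else rep(0, length(y))
  p_slopes <- ncol(X)

  if (sigma == 0) {
    cc <- cell_grad_terms(upper, lower, eta, rep(0, length(y)))
    gr_theta <- vapply(seq_len(K - 1L), function(k) {
      sum(cc$t1a[y == k]) + sum(cc$t1b[y == k + 1L])
    }, numeric(1))
    gr_beta <- if (p_slopes) drop(crossprod(X, cc$g1)) else numeric(0)
    return(list(loglik = sum(cc$logp),
                grad = c(gr_theta, gr_beta, 0)))
  }

  u <- clmm_modes(upper, lower, eta, sigma, gi, n_groups)
  if (is.null(u)) return(list(loglik = -Inf, grad = NULL))
  cc <- cell_grad_terms(upper, lower, eta, u[gi])
  H <- pmax(-drop(rowsum(cc$g2, gi)) + 1 / sigma^2, 1e-10)
  S3 <- drop(rowsum(cc$g3, gi))

  loglik <- sum(cc$logp) - sum(u^2) / (2 * sigma^2) -
    n_groups * log(sigma) - 0.5 * sum(log(H))

  # dl/dpsi accumulated from per-group A (value), B (mode-shift through
  # the curvature), C (explicit curvature) contributions
  contrib <- function(wA, wB, wC) {
    A <- drop(rowsum(wA, gi))
    B <- drop(rowsum(wB, gi))
    C <- drop(rowsum(wC, gi))
    sum(A + (C + S3 * B / H) / (2 * H))
  }
  gr_theta <- vapply(seq_len(K - 1L), function(k) {
    ia <- y == k            # this cell's upper cutpoint is theta_k
    ib <- y == k + 1L       # this cell's lower cutpoint is theta_k
    contrib(cc$t1a * ia + cc$t1b * ib,
            cc$dg1_dza * ia + cc$dg1_dzb * ib,
            cc$dg2_dza * ia + cc$dg2_dzb * ib)
  }, numeric(1))
  gr_beta <- if (p_slopes) {
    vapply(seq_len(p_slopes), function(j) {
      contrib(X[, j] * cc$g1, X[, j] * cc$g2, X[, j] * cc$g3)
    }, numeric(1))
  } else {
    numeric(0)
  }
  du_dsigma <- 2 * u / (sigma^3 * H)
  gr_sigma <- sum(u^2 / sigma^3 - 1 / sigma +
                    (S3 * du_dsigma + 2 / sigma^3) / (2 * H))
  list(loglik = loglik, grad = c(gr_theta, gr_beta, gr_sigma))
}

#' Laplace-approximated marginal log-likelihood of a CLMM
#'
#' Evaluates the marginal log-likelihood of a cumulative-logit model with a
#' Gaussian participant random intercept at the supplied parameters. The
#' random intercept is integrated out per participant by the Laplace
#' approximation: a second-order expansion around the conditional mode of
#' the intercept, found by Newton iteration. With
#' `random_intercept_sd = 0` the function returns the plain fixed-effects
#' cumulative-logit log-likelihood exactly.
#'
#' @param params List with `cutpoints` (strictly increasing), `beta`
#'   (slope per model-matrix column implied by `fixed`; may be empty), and
#'   `random_intercept_sd` (nonnegative scalar).
#' @param dataset Long-format data frame with `rating` (1..7),
#'   `participant`, and the covariate columns.
#' @param fixed Character vector of covariate names entering as fixed
#'   effects (factors are expanded by treatment contrasts; no separate
#'   intercept — it is absorbed into the cutpoints).
#' @return The marginal log-likelihood (sum over participants). The number
#'   of rating categories is `length(cutpoints) + 1`; ratings above that
#'   are rejected.
#' @examples
#' d <- data.frame(participant = 1, rating = 1L)
#' clmm_marginal_loglik(list(cutpoints = 0, beta = numeric(),
#'                           random_intercept_sd = 0), d)  # log(0.5)
#' @export
clmm_marginal_loglik <- function(params, dataset, fixed = character()) {
  validate_rating_dataset(dataset)
  theta <- as.numeric(params$cutpoints)
  if (length(theta) < 1L) stop("need at least one cutpoint", call. = FALSE)
  if (any(diff(theta) <= 0)) {
    stop("invalid parameters: cutpoints must be strictly increasing",
         call. = FALSE)
  }
  y <- as.integer(dataset$rating)
  if (max(y) > length(theta) + 1L) {
    stop("rating ", max(y), " exceeds the ", length(theta) + 1L,
         " categories implied by the cutpoints", call. = FALSE)
  }
  sigma <- params$random_intercept_sd
  if (is.null(sigma)) sigma <- 0
  if (sigma < 0) stop("`random_intercept_sd` must be nonnegative", call. = FALSE)

  g <- factor(dataset$participant)
  if (length(fixed)) {
    missing_cov <- setdiff(fixed, names(dataset))
    if (length(missing_cov)) {
      stop("dataset is missing covariate(s): ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    X <- stats::model.matrix(stats::reformulate(fixed), dataset)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  } else {
    X <- matrix(0, nrow = length(y), ncol = 0L)
  }
  beta <- as.numeric(params$beta)
  if (length(beta) != ncol(X)) {
    stop("`beta` must have one coefficient per model-matrix column (",
         ncol(X), ")", call. = FALSE)
  }
  clmm_loglik_core(theta, beta, sigma, y, X, as.integer(g), nlevels(g))
}

# ---- fitting ----------------------------------------------------------------

#' Fit a cumulative link mixed model
#'
#' Maximizes the Laplace-approximated marginal likelihood over the
#' cutpoints, the fixed-effect slopes, and (optionally) the random-
#' intercept standard deviation, by quasi-Newton (BFGS) search. The
#' cutpoints are parameterized as (first cutpoint, log-spacings) so they
#' stay strictly increasing; the random-intercept variance is optimized on
#' the log scale so it stays positive. Initialization: cutpoints at the
#' logit of the empirical cumulative proportions, slopes 0, log-SD 0.
#'
#' @inheritParams clmm_marginal_loglik
#' @param estimate_random Estimate the random-intercept SD? With `FALSE`
#'   the SD is fixed at 0 and the fit is a plain proportional-odds model.
#' @param options List of optimizer options: `maxit` (default 500),
#'   `reltol` (default 1e-12). The search uses the analytic gradient of
#'   the Laplace objective (implicit-function differentiation of the
#'   conditional modes).
#' @return A `pam_clmm` object: `cutpoints` (named by the observed
#'   category boundaries), `slopes`, `se_slopes`, `random_intercept_sd`,
#'   `loglik`, `n_params`, `aic`, `converged`, `n_obs`, `n_groups`.
#'   Non-convergence is reported in `converged`, never silently; slopes of
#'   very large magnitude trigger a complete-separation warning.
#' @examples
#' cov <- data.frame(condition = pam_conditions(), fish_reel = c(8, 6, 12, 9))
#' d <- generate_ratings(cov, default_rating_specs()$perceived_control,
#'                       n_participants = 30, seed = 1)
#' fit <- fit_clmm(d, fixed = "fish_reel")
#' fit$slopes
#' @export
fit_clmm <- function(dataset, fixed = character(), estimate_random = TRUE,
                     options = list()) {
  prep <- prepare_clmm_data(dataset, fixed)
  K <- prep$n_cat
  p <- ncol(prep$X)
  opt <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), options)

  # center the model matrix: cutpoints and slopes are nearly collinear
  # for covariates with large means, which stalls the quasi-Newton
  # search; the likelihood is invariant and the cutpoints are shifted
  # back to the raw-covariate scale afterwards
  xbar <- if (p > 0) colMeans(prep$X) else numeric(0)
  Xc <- if (p > 0) sweep(prep$X, 2, xbar) else prep$X

  cum_prop <- cumsum(tabulate(prep$y, K) / length(prep$y))[seq_len(K - 1L)]
  theta0 <- stats::qlogis(cum_prop)
  par0 <- c(theta0[1], log(pmax(diff(theta0), 1e-6)), rep(0, p),
            if (estimate_random) 0)

  unpack <- function(par) {
    theta <- cumsum(c(par[1], exp(par[seq_len(K - 2L) + 1L])))
    beta <- par[K - 1L + seq_len(p)]
    sigma <- if (estimate_random) exp(par[length(par)]) else 0
    list(theta = theta, beta = beta, sigma = sigma)
  }
  # objective and gradient share one evaluation per parameter point
  cache <- new.env(parent = emptyenv())
  eval_point <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    pp <- unpack(par)
    res <- if (all(is.finite(c(pp$theta, pp$beta, pp$sigma)))) {
      clmm_loglik_grad(pp$theta, pp$beta, pp$sigma,
                       prep$y, Xc, prep$gi, prep$n_groups)
    } else {
      list(loglik = -Inf, grad = NULL)
    }
    cache$par <- par
    cache$res <- res
    res
  }
  negll <- function(par) {
    ll <- eval_point(par)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  neggr <- function(par) {
    r <- eval_point(par)
    if (!is.finite(r$loglik) || is.null(r$grad)) return(rep(0, length(par)))
    pp <- unpack(par)
    g_theta <- r$grad[seq_len(K - 1L)]
    g <- numeric(length(par))
    g[1] <- sum(g_theta)
    if (K > 2L) {
      for (j in 2L:(K - 1L)) { # theta_k = t1 + sum(exp(l_2..l_k))
        g[j] <- exp(par[j]) * sum(g_theta[j:(K - 1L)])
      }
    }
    if (p > 0) g[K - 1L + seq_len(p)] <- r$grad[K - 1L + seq_len(p)]
    if (estimate_random) g[length(par)] <- pp$sigma * r$grad[K + p]
    -g
  }

  res <- stats::optim(
    par0, negll, gr = neggr, method = "BFGS", hessian = TRUE,
    control = list(maxit = opt$maxit, reltol = opt$reltol)
  )

  pp <- unpack(res$par)
  # shift cutpoints back to the raw-covariate scale
  if (p > 0) pp$theta <- pp$theta + sum(xbar * pp$beta)
  se_slopes <- rep(NA_real_, p)
  if (p > 0) {
    vc <- tryCatch(solve(res$hessian), error = function(e) NULL)
    if (!is.null(vc)) {
      se_slopes <- sqrt(pmax(diag(vc)[K - 1L + seq_len(p)], 0))
    }
  }
  slopes <- stats::setNames(pp$beta, colnames(prep$X))
  if (any(abs(pp$beta) > 10)) {
    warning("slope magnitude exceeds 10: possible complete separation",
            call. = FALSE)
  }

  n_params <- (K - 1L) + p + as.integer(estimate_random)
  loglik <- -res$value
  structure(
    list(
      cutpoints = stats::setNames(
        pp$theta,
        paste(prep$observed[-K], prep$observed[-1], sep = "|")
      ),
      slopes = slopes,
      se_slopes = stats::setNames(se_slopes, colnames(prep$X)),
      random_intercept_sd = pp$sigma,
      loglik = loglik,
      n_params = n_params,
      aic = 2 * n_params - 2 * loglik,
      converged = res$convergence == 0L,
      n_obs = length(prep$y),
      n_groups = prep$n_groups,
      fixed = fixed,
      estimate_random = estimate_random,
      fingerprint = prep$fingerprint
    ),
    class = "pam_clmm"
  )
}

#' @export
print.pam_clmm <- function(x, ...) {
  cat("<pam_clmm>", if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  obs: %d  participants: %d  logLik: %.3f  AIC: %.3f\n",
              x$n_obs, x$n_groups, x$loglik, x$aic))
  cat(sprintf("  random intercept SD: %.3f%s\n", x$random_intercept_sd,
              if (!x$estimate_random) " (fixed)" else ""))
  if (length(x$slopes)) {
    cat("  slopes:\n")
    print(round(rbind(estimate = x$slopes, se = x$se_slopes), 4))
  }
  invisible(x)
}

# ---- inference --------------------------------------------------------------

#' Likelihood-ratio test between nested CLMM fits
#'
#' @param full,null Two [fit_clmm()] results on the same observations, with
#'   the null's fixed effects nested in the full's.
#' @return A `pam_lr_test` list: `statistic` (`2 * (loglik_full -
#'   loglik_null)`), `df` (difference in parameter count), and `p_value`
#'   from the chi-square upper tail. For identical models the statistic is
#'   0 and the p-value 1. Tests against a boundary null
#'   (`random_intercept_sd = 0`) use the naive chi-square reference.
#' @export
lr_test <- function(full, null) {
  stopifnot(inherits(full, "pam_clmm"), inherits(null, "pam_clmm"))
  if (!identical(full$fingerprint, null$fingerprint)) {
    stop("fits are not on the same dataset", call. = FALSE)
  }
  null_cols <- names(null$slopes)
  if (!all(null_cols %in% names(full$slopes)) ||
      (null$estimate_random && !full$estimate_random)) {
    stop("`null` is not nested in `full`", call. = FALSE)
  }
  df <- full$n_params - null$n_params
  if (df < 0) stop("`null` has more parameters than `full`", call. = FALSE)
  statistic <- 2 * (full$loglik - null$loglik)
  p_value <- if (df == 0L) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(
    list(statistic = statistic, df = df, p_value = p_value),
    class = "pam_lr_test"
  )
}

#' @export
print.pam_lr_test <- function(x, ...) {
  cat(sprintf("LR test: chisq = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Fit and rank candidate CLMMs by AIC
#'
#' Fits the participant-intercept-only null model and one model per
#' candidate fixed-effect set on the same observations, ranks them by AIC
#' (ascending; ties keep input order), and reports each model's
#' log-likelihood and likelihood-ratio test against the null.
#'
#' @inheritParams fit_clmm
#' @param candidates List of character vectors, each a fixed-effect set.
#' @return A `pam_model_table` data frame with columns `fixed_effects`,
#'   `aic`, `loglik`, `lr`, `df`, `p_value`, `converged`; the fitted
#'   objects are attached as attribute `fits`. A fit failure fills its row
#'   with `NA` and the remaining candidates are still fitted.
#' @export
rank_models <- function(dataset, candidates, estimate_random = TRUE,
                        options = list()) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  null_fit <- fit_clmm(dataset, character(), estimate_random, options)
  labels <- vapply(
    candidates,
    function(fx) if (length(fx)) paste(fx, collapse = " + ") else "(null)",
    character(1)
  )
  rows <- vector("list", length(candidates))
  fits <- stats::setNames(vector("list", length(candidates)), labels)
  for (i in seq_along(candidates)) {
    fx <- candidates[[i]]
    row <- tryCatch({
      fit <- if (length(fx)) {
        fit_clmm(dataset, fx, estimate_random, options)
      } else {
        null_fit
      }
      fits[[i]] <- fit
      lt <- lr_test(fit, null_fit)
      data.frame(
        fixed_effects = labels[i], aic = fit$aic, loglik = fit$loglik,
        lr = lt$statistic, df = lt$df, p_value = lt$p_value,
        converged = fit$converged
      )
    }, error = function(e) {
      message("model '", labels[i], "' failed: ", conditionMessage(e))
      data.frame(
        fixed_effects = labels[i], aic = NA_real_, loglik = NA_real_,
        lr = NA_real_, df = NA_integer_, p_value = NA_real_,
        converged = FALSE
      )
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE] # stable: ties keep input order
  rownames(out) <- NULL
  structure(out, fits = fits, null_fit = null_fit,
            class = c("pam_model_table", "data.frame"))
}
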