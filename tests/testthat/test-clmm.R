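make_sim <- function(theta, beta, sigma, n_groups, n_per, seed,
                     x_sd = 1) {
  withr::with_seed(seed, {
    g <- rep(seq_len(n_groups), each = n_per)
    x <- rnorm(length(g), 0, x_sd)
    u <- rnorm(n_groups, 0, sigma)
    eta <- beta * x + u[g]
    cum <- plogis(outer(eta, theta, function(e, c) c - e))
    y <- as.integer(rowSums(runif(length(g)) > cum) + 1L)
    data.frame(participant = g, rating = y, x = x)
  })
}

test_that("the marginal log-likelihood has the exact fixed-effects limit", {
  # single observation, single cutpoint at 0, no random effect: log(0.5)
  d <- data.frame(participant = 1, rating = 1L)
  ll <- clmm_marginal_loglik(list(cutpoints = 0, beta = numeric(),
                                  random_intercept_sd = 0), d)
  expect_equal(ll, log(0.5))

  # sd = 0 equals direct summation on random datasets and parameters
  set.seed(21)
  for (rep in 1:10) {
    theta <- sort(rnorm(6, 0, 2))
    beta <- rnorm(1)
    d <- make_sim(theta, beta, 1, n_groups = 8, n_per = 4, seed = rep)
    ll <- clmm_marginal_loglik(list(cutpoints = theta, beta = beta,
                                    random_intercept_sd = 0), d, "x")
    expect_equal(ll, oracle_direct_loglik(theta, beta, d, "x"),
                 tolerance = 1e-12)
  }
})

test_that("invalid parameters and inputs are signalled", {
  d <- data.frame(participant = 1:4, rating = c(1L, 3L, 5L, 7L))
  expect_error(clmm_marginal_loglik(list(cutpoints = c(1, 0, 2, 3, 4, 5),
                                         beta = numeric(),
                                         random_intercept_sd = 0), d),
               "increasing")
  expect_error(clmm_marginal_loglik(list(cutpoints = c(0, 1),
                                         beta = numeric(),
                                         random_intercept_sd = 0), d),
               "exceeds")
  expect_error(clmm_marginal_loglik(list(cutpoints = 0, beta = 1,
                                         random_intercept_sd = -1),
                                    data.frame(participant = 1, rating = 1L)),
               "nonnegative")
})

test_that("Laplace agrees with 61-node adaptive quadrature where the expansion is tight", {
  set.seed(33)
  for (sigma in c(0.05, 0.1, 0.2)) {
    theta <- sort(rnorm(6, 0, 2))
    d <- make_sim(theta, 0.5, sigma, n_groups = 5, n_per = 4, seed = 100)
    lap <- clmm_marginal_loglik(list(cutpoints = theta, beta = 0.5,
                                     random_intercept_sd = sigma), d, "x")
    agq <- oracle_agq_loglik(theta, 0.5, sigma, d, "x")
    expect_lt(abs(lap - agq), 1e-3)
  }
  # single group, single observation, small variance
  d1 <- data.frame(participant = 1, rating = 4L)
  theta <- seq(-2.5, 2.5, 1)
  lap <- clmm_marginal_loglik(list(cutpoints = theta, beta = numeric(),
                                   random_intercept_sd = 0.1), d1)
  expect_lt(abs(lap - oracle_agq_loglik(theta, numeric(0), 0.1, d1)), 1e-4)
})

test_that("the Laplace gap grows with the random-intercept SD as expected", {
  # the approximation degrades as the intercept variance grows; these
  # bounds document the measured order of magnitude of the gap
  theta <- seq(-2.5, 2.5, 1)
  d <- make_sim(theta, 0.5, 1, n_groups = 5, n_per = 4, seed = 200)
  gap <- function(sigma) {
    abs(clmm_marginal_loglik(list(cutpoints = theta, beta = 0.5,
                                  random_intercept_sd = sigma), d, "x") -
          oracle_agq_loglik(theta, 0.5, sigma, d, "x"))
  }
  g_small <- gap(0.1)
  g_mid <- gap(1)
  g_large <- gap(2.31)
  expect_lt(g_small, 1e-3)
  expect_lt(g_mid, 0.1)
  expect_lt(g_large, 1)
  expect_gt(g_large, g_small)
})

test_that("null-model cutpoints equal the logit of cumulative proportions", {
  set.seed(41)
  y <- sample(1:7, 300, replace = TRUE, prob = c(1, 2, 4, 6, 4, 2, 1))
  d <- data.frame(participant = rep(1:30, each = 10), rating = y)
  fit <- fit_clmm(d, estimate_random = FALSE)
  prop <- cumsum(tabulate(y, 7) / 300)[1:6]
  expect_equal(unname(fit$cutpoints), qlogis(prop), tolerance = 1e-6)
  expect_equal(fit$loglik, oracle_direct_loglik(qlogis(prop), numeric(0), d),
               tolerance = 1e-8)
})

test_that("the fixed-effects fit matches an independent proportional-odds fitter", {
  theta <- sort(rnorm(6, 0, 1.5))
  d <- make_sim(theta, 0.7, 0, n_groups = 40, n_per = 5, seed = 77)
  fit <- fit_clmm(d, fixed = "x", estimate_random = FALSE)
  po <- MASS::polr(ordered(rating) ~ x, data = d, method = "logistic")
  expect_equal(unname(fit$slopes["x"]), unname(coef(po)["x"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$cutpoints), unname(po$zeta), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(po)), tolerance = 1e-6)
})

test_that("the AIC identity and parameter count hold for every fit", {
  d <- make_sim(seq(-2.5, 2.5, 1), 0.4, 1, n_groups = 25, n_per = 4,
                seed = 13)
  for (est in c(TRUE, FALSE)) {
    fit <- fit_clmm(d, fixed = "x", estimate_random = est)
    expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
    expect_equal(fit$n_params,
                 length(fit$cutpoints) + length(fit$slopes) + as.integer(est))
    expect_true(fit$converged)
  }
})

test_that("the likelihood is invariant to a location shift absorbed by the cutpoints", {
  theta <- seq(-2.5, 2.5, 1)
  d <- make_sim(theta, 0.5, 0.8, n_groups = 10, n_per = 4, seed = 55)
  const <- 1.7
  ll1 <- clmm_marginal_loglik(list(cutpoints = theta, beta = 0.5,
                                   random_intercept_sd = 0.8), d, "x")
  d2 <- d
  d2$x <- d$x + const / 0.5 # raises x'beta by `const` everywhere
  ll2 <- clmm_marginal_loglik(list(cutpoints = theta + const, beta = 0.5,
                                   random_intercept_sd = 0.8), d2, "x")
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("null-effect data rarely yield slopes beyond three standard errors", {
  set.seed(61)
  inside <- vapply(1:40, function(rep) {
    d <- make_sim(seq(-2.5, 2.5, 1), 0, 0, n_groups = 50, n_per = 8,
                  seed = 1000 + rep)
    fit <- fit_clmm(d, fixed = "x", estimate_random = FALSE)
    abs(fit$slopes["x"]) < 3 * fit$se_slopes["x"]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("unobserved extreme categories are collapsed with a warning", {
  d <- data.frame(participant = rep(1:10, each = 3),
                  rating = sample(rep(2:5, length.out = 30)))
  expect_warning(fit <- fit_clmm(d, estimate_random = FALSE), "collapsed")
  expect_equal(length(fit$cutpoints), 3) # 4 observed categories
})

test_that("complete separation is flagged, not silent", {
  d <- data.frame(participant = rep(1:10, each = 2),
                  rating = rep(c(1L, 7L), each = 10),
                  x = rep(c(0, 1), each = 10))
  expect_warning(
    expect_warning(fit_clmm(d, fixed = "x", estimate_random = FALSE),
                   "separation"),
    "collapsed")
})

test_that("likelihood-ratio tests compare nested fits on identical data", {
  d <- make_sim(seq(-2.5, 2.5, 1), 0.6, 0, n_groups = 30, n_per = 6,
                seed = 91)
  null <- fit_clmm(d, estimate_random = FALSE)
  full <- fit_clmm(d, fixed = "x", estimate_random = FALSE)
  lt <- lr_test(full, null)
  expect_equal(lt$statistic, 2 * (full$loglik - null$loglik))
  expect_equal(lt$df, 1)
  expect_equal(lt$p_value,
               pchisq(lt$statistic, 1, lower.tail = FALSE))

  self <- lr_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  d_other <- make_sim(seq(-2.5, 2.5, 1), 0.6, 0, 30, 6, seed = 92)
  other <- fit_clmm(d_other, estimate_random = FALSE)
  expect_error(lr_test(full, other), "same dataset")
  expect_error(lr_test(null, full), "not nested")
})

test_that("model ranking is stable, AIC-ordered, and robust to row order", {
  d <- make_sim(seq(-2.5, 2.5, 1), 0.8, 0.5, n_groups = 40, n_per = 4,
                seed = 17)
  d$noise <- withr::with_seed(18, rnorm(nrow(d)))
  tab <- rank_models(d, list("x", "noise", character(0)))
  expect_equal(tab$aic, sort(tab$aic))
  expect_equal(tab$fixed_effects[1], "x") # the true effect wins
  expect_equal(tab$lr[tab$fixed_effects == "(null)"], 0)

  # identical candidates tie and keep input order
  tab2 <- rank_models(d, list("x", "x"))
  expect_equal(tab2$aic[1], tab2$aic[2], tolerance = 1e-6)

  # observation order does not change the ranking
  perm <- withr::with_seed(19, sample(nrow(d)))
  tab3 <- rank_models(d[perm, ], list("x", "noise", character(0)))
  expect_equal(tab3$fixed_effects, tab$fixed_effects)
  expect_equal(tab3$aic, tab$aic, tolerance = 1e-4)
})
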