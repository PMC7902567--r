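one_rec <- function(t, event = 1) {
  aft_data(matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)")), t, event)
}

test_that("lognormal likelihood matches closed forms on single records", {
  # event at t = 1 month, x'beta = 0, sigma = 1: standard normal density at 0
  expect_equal(log_likelihood(0, 0, one_rec(1)), -0.5 * log(2 * pi))
  expect_equal(log_likelihood(0, 0, one_rec(1)), -0.9189385, tolerance = 1e-6)
  # censored exactly at the median: log survival = log(1/2)
  mu <- 1.7
  expect_equal(log_likelihood(mu, 0.3, one_rec(exp(mu), event = 0)),
               log(0.5))
  # additivity over records
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  both <- aft_data(X, c(2, 7), c(1, 0))
  expect_equal(log_likelihood(0.5, 0.1, both),
               log_likelihood(0.5, 0.1, one_rec(2)) +
                 log_likelihood(0.5, 0.1, one_rec(7, event = 0)))
  expect_error(log_likelihood(NA, 0, one_rec(1)), "finite")
})

test_that("analytic likelihood gradient matches central finite differences", {
  set.seed(8)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(40), x2 = rbinom(40, 1, 0.4))
  t <- exp(0.5 + 0.3 * X[, 2] + rnorm(40))
  ev <- rbinom(40, 1, 0.7)
  dat <- aft_data(X, t, ev)
  par <- c(0.4, 0.2, -0.3, -0.1)
  g <- bayesaft:::log_likelihood_grad(par[1:3], par[4], dat)
  h <- 1e-6
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h
    num <- (log_likelihood((par + e)[1:3], (par + e)[4], dat) -
              log_likelihood((par - e)[1:3], (par - e)[4], dat)) / (2 * h)
    expect_equal(unname(g[j]), num, tolerance = 1e-5)
  }
})

test_that("posterior differs from likelihood by a beta-constant under flat priors", {
  co <- quick_cohort(120, seed = 12)
  des <- build_design(small_spec(), co)
  dat <- aft_data(des$X, co$os_time, co$os_event)
  pri <- build_prior_spec(des, "OS", "flat")
  p <- length(des$labels)
  b1 <- rnorm(p, 0, 0.1); b2 <- rnorm(p, 0, 0.1)
  d_post <- log_posterior(b1, -0.1, dat, pri) -
    log_posterior(b2, -0.1, dat, pri)
  d_lik <- log_likelihood(b1, -0.1, dat) - log_likelihood(b2, -0.1, dat)
  expect_lt(abs(d_post - d_lik), 1e-4)  # sd-100 surrogate is nearly flat
  expect_error(log_posterior(b1, 0, dat, pri[-2, ]), "no prior")
})

test_that("with no data the posterior peaks at the prior mean", {
  X0 <- matrix(numeric(0), 0, 1, dimnames = list(NULL, "(Intercept)"))
  dat <- aft_data(X0, numeric(0), integer(0))
  pri <- manual_priors(c("(Intercept)", "log(scale)"),
                       c("intercept", "log-scale"), c(1.5, 0), c(0.5, 1))
  at_mean <- log_posterior(1.5, 0, dat, pri)
  for (b in c(0.5, 1, 2, 3))
    expect_lt(log_posterior(b, 0, dat, pri), at_mean)
})

test_that("posterior density ratios match normal-normal conjugacy", {
  # intercept-only, sigma pinned at 1: posterior N(sum(y)/(n+1), 1/(n+1))
  set.seed(14)
  y <- rnorm(10, 1, 1)
  dat <- aft_data(matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")),
                  exp(y), rep(1, 10))
  pri <- manual_priors(c("(Intercept)", "log(scale)"),
                       c("intercept", "log-scale"), c(0, 0), c(1, 1))
  m_post <- sum(y) / 11; s_post <- sqrt(1 / 11)
  a <- 0.3; b <- 1.4
  lhs <- exp(log_posterior(a, 0, dat, pri) - log_posterior(b, 0, dat, pri))
  rhs <- stats::dnorm(a, m_post, s_post) / stats::dnorm(b, m_post, s_post)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("sampler recovers the closed-form conjugate posterior", {
  set.seed(42)
  y <- exp(rnorm(25, 0.4, 1))
  dat <- aft_data(matrix(1, 25, 1, dimnames = list(NULL, "(Intercept)")),
                  y, rep(1, 25))
  pri <- manual_priors(c("(Intercept)", "log(scale)"),
                       c("intercept", "log-scale"), c(0, 0), c(1, 1e-4))
  dr <- sample_posterior(dat, pri, n_chains = 4, n_warmup = 500,
                         n_iter = 2000, seed = 5)
  b <- param_draws(dr, "(Intercept)")
  m_closed <- sum(log(y)) / 26; s_closed <- sqrt(1 / 26)
  ess <- min(rhat(dr)$ess)
  expect_lt(abs(mean(b) - m_closed), 3 * s_closed / sqrt(ess))
  expect_equal(stats::sd(b), s_closed, tolerance = 0.05)
})

test_that("sampling is reproducible under a fixed seed", {
  co <- quick_cohort(80, seed = 15)
  des <- build_design(small_spec(interactions = character(0)), co)
  dat <- aft_data(des$X, co$pfs_time, co$pfs_event)
  pri <- build_prior_spec(des, "PFS", "weak")
  d1 <- sample_posterior(dat, pri, n_chains = 2, n_warmup = 100,
                         n_iter = 100, seed = 77)
  d2 <- sample_posterior(dat, pri, n_chains = 2, n_warmup = 100,
                         n_iter = 100, seed = 77)
  expect_identical(d1$draws, d2$draws)
})

test_that("flat-prior posterior medians sit on the maximum-likelihood fit", {
  co <- quick_cohort(400, seed = 16)
  des <- build_design(small_spec(interactions = character(0)), co)
  dat <- aft_data(des$X, co$pfs_time, co$pfs_event)
  pri <- build_prior_spec(des, "PFS", "flat")
  dr <- sample_posterior(dat, pri, n_chains = 2, n_warmup = 300,
                         n_iter = 2000, seed = 6)
  med <- apply(draws_matrix(dr), 2, stats::median)
  sf <- survival::survreg(survival::Surv(co$pfs_time, co$pfs_event) ~
                            des$X[, -1], dist = "lognormal")
  ref <- c(stats::coef(sf)[1], stats::coef(sf)[-1], log(sf$scale))
  p <- length(des$labels)
  expect_lt(max(abs(med[1:p] - ref[1:p])), 0.01)
  # and the package's own optimizer agrees with the independent one
  mle <- aft_mle(dat)
  expect_equal(unname(mle$beta), unname(ref[1:p]), tolerance = 1e-4)
  expect_equal(mle$log_sigma, unname(ref[p + 1]), tolerance = 1e-4)
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(17)
  iid <- make_draws(matrix(rnorm(4000), ncol = 1,
                           dimnames = list(NULL, "b")),
                    matrix(rnorm(4000), ncol = 1,
                           dimnames = list(NULL, "b")))
  rep_iid <- rhat(iid)
  expect_lt(abs(rep_iid$rhat - 1), 0.01)
  expect_true(attr(rep_iid, "pass"))

  apart <- make_draws(matrix(rnorm(2000, 0), ncol = 1,
                             dimnames = list(NULL, "b")),
                      matrix(rnorm(2000, 10), ncol = 1,
                             dimnames = list(NULL, "b")))
  rep_apart <- rhat(apart)
  expect_gt(rep_apart$rhat, 1.1)
  expect_false(attr(rep_apart, "pass"))

  one <- make_draws(matrix(rnorm(100), ncol = 1,
                           dimnames = list(NULL, "b")))
  expect_error(rhat(one), "2 chains")
})

test_that("pass flag is false exactly when some parameter reaches the threshold", {
  set.seed(18)
  good <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  bad <- matrix(c(rnorm(1000), rnorm(1000, 5)), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  mixed <- make_draws(good, bad)
  rep <- rhat(mixed)
  expect_false(attr(rep, "pass"))
  expect_true(any(rep$rhat >= 1.1) || !attr(rep, "pass"))
})

test_that("mixture pooling across imputations behaves like a mixture", {
  m1 <- matrix(0, 100, 1, dimnames = list(NULL, "b"))
  m2 <- matrix(0.2, 100, 1, dimnames = list(NULL, "b"))
  d0 <- make_draws(m1, m1)
  d2 <- make_draws(m2, m2)
  pooled <- pool_imputations(list(d0, d2))
  expect_equal(mean(param_draws(pooled, "b")), 0.1)

  # pooling copies of the same draws leaves summaries unchanged
  set.seed(19)
  mm <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "b"))
  dd <- make_draws(mm, mm)
  same <- pool_imputations(list(dd, dd, dd))
  expect_equal(mean(param_draws(same, "b")), mean(mm))
  expect_equal(stats::median(param_draws(same, "b")), stats::median(mm))

  # law of total variance: pooled variance >= mean within-fit variance
  set.seed(20)
  f1 <- make_draws(matrix(rnorm(800, 0.0, 1), ncol = 1,
                          dimnames = list(NULL, "b")))
  f2 <- make_draws(matrix(rnorm(800, 0.6, 1), ncol = 1,
                          dimnames = list(NULL, "b")))
  pl <- pool_imputations(list(f1, f2))
  w <- mean(c(var(param_draws(f1, "b")), var(param_draws(f2, "b"))))
  expect_gte(var(param_draws(pl, "b")), w)

  bad <- make_draws(matrix(0, 100, 1, dimnames = list(NULL, "other")))
  expect_error(pool_imputations(list(d0, bad)), "labels differ")
})
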