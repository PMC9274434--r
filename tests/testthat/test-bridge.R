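# analytic-evidence toys for the bridge estimator
beta_binom_case <- function(n, y, a, b, ndraws = 8000, seed = 5) {
  set.seed(seed)
  draws <- matrix(qlogis(rbeta(ndraws, y + a, n - y + b)), ncol = 1)
  lq <- function(th) {
    p <- plogis(th[, 1])
    dbinom(y, n, p, log = TRUE) + dbeta(p, a, b, log = TRUE) +
      log(p) + log(1 - p)  # Jacobian of the logit transform
  }
  list(draws = draws, lq = lq,
       truth = lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

test_that("bridge sampling matches the beta-binomial evidence", {
  for (case in list(c(20, 13, 2, 2), c(20, 5, 1, 3), c(50, 42, 0.5, 0.5))) {
    bb <- beta_binom_case(case[1], case[2], case[3], case[4])
    est <- bridge_log_ml(bb$draws, bb$lq, seed = 2)
    expect_lt(abs(est$log_ml - bb$truth), 0.05)
  }
})

test_that("bridge sampling matches the normal-normal evidence", {
  set.seed(2)
  y <- rnorm(10, 1.5, 1)  # known unit observation SD
  tau0 <- 2
  n <- length(y)
  Sig <- diag(n) + tau0^2 * matrix(1, n, n)
  truth <- -0.5 * (n * log(2 * pi) +
                     as.numeric(determinant(Sig)$modulus) +
                     drop(t(y) %*% solve(Sig, y)))
  post_var <- 1 / (1 / tau0^2 + n)
  post_mean <- post_var * sum(y)
  draws <- matrix(rnorm(8000, post_mean, sqrt(post_var)), ncol = 1)
  lq <- function(th) vapply(th[, 1], function(m)
    sum(dnorm(y, m, 1, log = TRUE)) + dnorm(m, 0, tau0, log = TRUE),
    numeric(1))
  est <- bridge_log_ml(draws, lq, seed = 3)
  expect_lt(abs(est$log_ml - truth), 0.05)
  # two proposal seeds agree within combined Monte-Carlo error
  est2 <- bridge_log_ml(draws, lq, seed = 77)
  expect_lt(abs(est$log_ml - est2$log_ml),
            3 * sqrt(est$mc_error^2 + est2$mc_error^2) + 1e-6)
})

test_that("model Bayes factors are antisymmetric, transitive and detect
          the simulated hysteresis", {
  fa <- small_fit("full")
  fb <- small_fit("no-hyst")
  fc <- small_fit("no-adapt")
  self <- bf_bridge(fa, fa)
  expect_equal(self$log_bf, 0)
  ab <- bf_bridge(fa, fb)
  ba <- bf_bridge(fb, fa)
  expect_equal(ab$log_bf, -ba$log_bf)
  ac <- bf_bridge(fa, fc)
  bc <- bf_bridge(fb, fc)
  expect_equal(ac$log_bf, ab$log_bf + bc$log_bf, tolerance = 1e-10)
  # hysteresis of 2.3 logits: decisive evidence for including r1
  expect_gt(ab$log_bf, log(1000))
  # mismatched data are refused
  other <- small_cohort()$binary[-1, ]
  f_other <- fit_percept_model(other, "no-hyst", sampler = small_sampler(31))
  expect_error(bf_bridge(fa, f_other), "fingerprint")
})

test_that("encompassing Bayes factors equal brute-force draw counting", {
  # arithmetic on stated counts: 200/10000 posterior vs 5000/10000 prior
  post <- matrix(1, 10000, 3)
  post[201:10000, 1] <- -1
  pri <- matrix(1, 10000, 3)
  pri[5001:10000, 2] <- -1
  expect_equal(encompassing_bf(post, pri, "positive")$bf, 0.04)
  # exact agreement with an independent recount on random draws
  set.seed(6)
  post2 <- matrix(rnorm(5000 * 4, mean = 0.8), ncol = 4)
  pri2 <- matrix(rnorm(20000 * 4, mean = 0), ncol = 4)
  bf <- encompassing_bf(post2, pri2, "positive")
  recount <- (sum(apply(post2 > 0, 1, all)) / 5000) /
    (sum(apply(pri2 > 0, 1, all)) / 20000)
  expect_identical(bf$bf, recount)
  # two-participant standard-normal toy: prior proportion is 1/4
  expect_lt(abs(sum(apply(pri2[, 1:2] > 0, 1, all)) / 20000 - pnorm(0)^2),
            0.01)
  # all-positive posterior with prior proportion 1/2 gives BF near 2
  post3 <- matrix(abs(rnorm(4000)), ncol = 1)
  pri3 <- matrix(rnorm(20000), ncol = 1)
  expect_equal(encompassing_bf(post3, pri3, "positive")$bf, 2,
               tolerance = 0.05)
  # zero posterior hits: finite one-sided bound, flagged
  post4 <- matrix(-abs(rnorm(1000)), ncol = 1)
  b4 <- encompassing_bf(post4, pri3, "positive")
  expect_true(b4$bound)
  expect_true(is.finite(b4$log_bf))
  expect_error(encompassing_bf(post3, -post3, "positive"), "prior draws")
})

test_that("one-sided Savage-Dickey factors are posterior-odds arithmetic", {
  r <- c(rep(0.5, 999), -0.1)
  expect_equal(savage_dickey_onesided(r, "positive")$bf, 999)
  r50 <- c(rep(0.2, 500), rep(-0.2, 500))
  expect_equal(savage_dickey_onesided(r50, "positive")$bf, 1)
  allpos <- rep(0.3, 2000)
  b <- savage_dickey_onesided(allpos, "positive")
  expect_true(b$bound)
  expect_equal(b$bf, 1999)  # bound at one contrary draw
  # asymmetric prior mass changes the prior odds accordingly
  expect_equal(savage_dickey_onesided(r, "positive", prior_mass = 0.25)$bf,
               999 * 3)
})

test_that("a correlated bivariate sample yields decisive directional
          evidence", {
  set.seed(3)
  x <- rnorm(70)
  y <- 0.7 * x + rnorm(70, 0, sqrt(1 - 0.49))
  bc <- bayes_cor(x, y, sampler_config(2, 1500, 500, seed = 8))
  expect_gt(savage_dickey_onesided(bc$r_draws, "positive")$bf, 100)
  expect_lt(abs(bc$mean - cor(x, y)), 0.1)
  expect_error(bayes_cor(1:2, 1:2), "at least 3")
})

test_that("data simulated without individual differences favor the
          common-effects model", {
  wins <- 0L
  for (s in 1:10) {
    pop <- population_params(lapse_rate = 0, sd_hysteresis = 0)
    d <- design_spec(n_participants = 8, n_blocks = 2,
                     trials_per_block = 70)
    st <- simulate_study(d, pop, sessions = 1, tasks = "main",
                         seed = 900 + s)
    bt <- to_binary_trials(st$trials)
    sc <- sampler_config(2, 600, 500, seed = 900 + s)
    f <- fit_percept_model(bt, "full", sampler = sc)
    fc <- fit_percept_model(bt, "common-hyst", sampler = sc)
    if (bf_bridge(fc, f, seed = s)$log_bf > 0) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
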