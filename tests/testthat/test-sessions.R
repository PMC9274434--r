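test_that("the sequential stopping rule implements the 1/6-6 band", {
  ns <- seq(30, 75, 5)
  # decisive immediately
  s1 <- sequential_rule(data.frame(n = 30, h4_hyst = 7, h4_adapt = 8,
                                   h5_hyst = 0.1, h5_adapt = 9))
  expect_equal(attr(s1, "stop")$decision, "stop_threshold")
  expect_equal(attr(s1, "stop")$n, 30)
  # one indecisive BF throughout: runs to the maximum sample size
  s2 <- sequential_rule(data.frame(n = ns, bf1 = 2, bf2 = 7))
  expect_equal(attr(s2, "stop")$decision, "stop_max_n")
  expect_equal(attr(s2, "stop")$n, 75)
  # straddling until decisive at 55
  bf1 <- c(2, 3, 2, 4, 5, 7, 8, 9, 10, 11)
  s3 <- sequential_rule(data.frame(n = ns, bf1 = bf1, bf2 = 7))
  expect_equal(attr(s3, "stop")$decision, "stop_threshold")
  expect_equal(attr(s3, "stop")$n, 55)
  # a BF below 1/6 is decisive too
  s4 <- sequential_rule(data.frame(n = ns, bf1 = bf1, bf2 = 0.12))
  expect_equal(attr(s4, "stop")$n, 55)
  expect_error(sequential_rule(data.frame(n = c(30, 40), bf = 7)),
               "steps of 5")
  expect_error(sequential_rule(data.frame(n = c(35, 30), bf = 7)),
               "increasing")
})

test_that("boundary Bayes factors exactly at the thresholds stop", {
  s <- sequential_rule(data.frame(n = 30, bf1 = 6, bf2 = 1 / 6))
  expect_equal(attr(s, "stop")$decision, "stop_threshold")
})

test_that("cross-session comparison identifies shared individual effects", {
  # one compact check here: rho_session = 1 for the tested effect makes the
  # fully-correlated model beat the free-correlation model, and the free
  # correlation posterior concentrates near 1
  pop <- population_params(lapse_rate = 0, rho_hyst_adapt = 0,
                           rho_session = c(intercept_l1 = 0.8,
                                           proximity = 0.9, intercept = 0.8,
                                           hysteresis = 1, adaptation = 0.95))
  d <- design_spec(n_participants = 12, n_blocks = 3, trials_per_block = 70)
  st <- simulate_study(d, pop, sessions = 1:2, tasks = "main", seed = 311)
  bt <- to_binary_trials(st$trials)
  cmp <- compare_session_models(bt, "hysteresis",
                                sampler = sampler_config(2, 800, 600,
                                                         seed = 312),
                                seed = 313)
  expect_lt(cmp$bf_corr_vs_full$log_bf, 0)
  expect_gt(cmp$bf_corr_vs_uncorr$log_bf, 0)
  expect_gt(cmp$rho_mean, 0.7)
  expect_s3_class(cmp$fits$correlated, "percept_fit")
  expect_output(print(cmp), "hysteresis")
})
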