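test_that("main-task designs balance aspect ratios within blocks", {
  d <- design_spec(n_participants = 2)
  des <- make_design(d, seed = 3)
  for (p in unique(des$participant)) {
    tab <- table(des$aspect_ratio[des$participant == p])
    expect_equal(unname(c(tab)), rep(90, 7))  # 10 per block x 9 blocks
    one_block <- des[des$participant == p & des$block == 1, ]
    expect_equal(unname(c(table(one_block$aspect_ratio))), rep(10, 7))
  }
  expect_true(all(des$base_orientation %in% 0:89))
  # one trial per aspect ratio in a 1 x 7 design
  d7 <- design_spec(n_participants = 1, n_blocks = 1, trials_per_block = 7)
  expect_equal(sort(make_design(d7, seed = 1)$aspect_ratio),
               sort(design_aspect_ratios()))
  expect_error(design_spec(trials_per_block = 71), "divisible")
})

test_that("generation is fully deterministic under a fixed seed", {
  d <- design_spec(n_participants = 3, n_blocks = 2, trials_per_block = 14)
  a <- simulate_study(d, population_params(), sessions = 1:2, seed = 99)
  b <- simulate_study(d, population_params(), sessions = 1:2, seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$effects, b$effects)
  c <- simulate_study(d, population_params(), sessions = 1:2, seed = 100)
  expect_false(identical(a$trials$l1_response, c$trials$l1_response))
})

test_that("participant effects follow the population distribution", {
  pop0 <- population_params(sd_intercept = 0, sd_hysteresis = 0,
                            sd_adaptation = 0, sd_proximity = 0,
                            sd_intercept_l1 = 0)
  eff <- draw_participants(pop0, 5, sessions = 1:2, seed = 1)
  expect_true(all(eff$hysteresis == pop0$mu_hysteresis))
  expect_true(all(eff$proximity == pop0$mu_proximity))
  # full session correlation makes adaptation identical across sessions
  pop1 <- population_params(rho_session = c(intercept_l1 = 0.5,
                                            proximity = 0.5, intercept = 0.5,
                                            hysteresis = 0.5, adaptation = 1))
  eff1 <- draw_participants(pop1, 50, sessions = 1:2, seed = 2)
  s1 <- eff1[eff1$session == 1, ]
  s2 <- eff1[eff1$session == 2, ]
  expect_equal(s1$adaptation, s2$adaptation)
  expect_false(isTRUE(all.equal(s1$hysteresis, s2$hysteresis)))
  # hysteresis-adaptation correlation recovered in a large draw
  eff2 <- draw_participants(population_params(), 10000, sessions = 1,
                            seed = 3)
  expect_lt(abs(cor(eff2$hysteresis, eff2$adaptation) - 0.7), 0.03)
})

test_that("first-lattice response rates follow the stated logistic rule", {
  eff <- list(intercept_l1 = 0, proximity = -8, lapse_rate = 0)
  set.seed(41)
  resp <- simulate_l1(rep(1 / 1.3 - 1, 20000), eff)
  expect_lt(abs(mean(resp == "deg0") - plogis(-8 * (1 / 1.3 - 1))), 0.01)
  set.seed(42)
  resp0 <- simulate_l1(rep(0, 20000), eff)
  expect_lt(abs(mean(resp0 == "deg0") - 0.5), 0.015)
  # full lapsing produces only diagonals
  set.seed(43)
  lapsed <- simulate_l1(rep(0, 500), eff, lapse_rate = 1)
  expect_true(all(lapsed %in% c("diag1", "diag2")))
})

test_that("second-lattice response rates follow the stated logistic rule", {
  eff <- list(intercept = -1, adaptation = 2, hysteresis = 2.3,
              lapse_rate = 0)
  set.seed(44)
  r_pres <- simulate_l2(rep(0, 20000), rep(1L, 20000), eff)
  expect_lt(abs(mean(r_pres == "deg0") - plogis(1.3)), 0.01)
  set.seed(45)
  r_abs <- simulate_l2(rep(0, 20000), rep(0L, 20000), eff)
  # flipping r1 moves the log-odds by exactly the hysteresis coefficient
  expect_lt(abs(mean(r_abs == "deg0") - plogis(-1)), 0.01)
  expect_true(all(r_abs %in% c("deg0", "deg60", "deg120")))
  # null observer answers at chance regardless of context
  null_eff <- list(intercept = 0, adaptation = 0, hysteresis = 0,
                   lapse_rate = 0)
  set.seed(46)
  rn <- simulate_l2(runif(20000, -0.3, 0.3),
                    rbinom(20000, 1, 0.5), null_eff)
  expect_lt(abs(mean(rn == "deg0") - 0.5), 0.015)
})

test_that("with no lapses the binary reduction keeps every trial", {
  d <- design_spec(n_participants = 3, n_blocks = 1, trials_per_block = 70)
  st <- simulate_study(d, population_params(lapse_rate = 0), sessions = 1,
                       seed = 8)
  mc <- st$trials[st$trials$task %in% c("main", "control"), ]
  expect_equal(nrow(to_binary_trials(mc)), nrow(mc))
})

test_that("orientation-bias generator is flat at zero concentration and
          recoverable otherwise", {
  spec_big <- design_spec(n_participants = 1, orientation_blocks = 170L)
  flat <- list(participant = "P1", bias_concentration = 0,
               bias_direction = 0, lapse_rate = 0)
  tr <- simulate_orientation_task(flat, spec_big, seed = 9)
  props <- table(tr$l2_response) / nrow(tr)
  expect_lt(max(abs(props - 1 / 3)), 0.02)
  biased <- list(participant = "P1", bias_concentration = 1.5,
                 bias_direction = 0, lapse_rate = 0)
  tr2 <- simulate_orientation_task(biased, spec_big, seed = 10)
  off <- c(deg0 = 0, deg60 = 60, deg120 = 120)[tr2$l2_response]
  v <- orientation_vector((tr2$base_orientation + off) %% 180)
  expect_lt(axial_dist(v["direction"], 0), 3)
  expect_gt(v["L"], 20)
})

test_that("a single-level logistic fit recovers one observer's effects", {
  eff <- list(intercept_l1 = 0, proximity = -4, intercept = -0.6,
              adaptation = 2.0, hysteresis = 2.3, lapse_rate = 0)
  n <- 300000
  set.seed(12)
  car <- sample(design_aspect_ratios(), n, replace = TRUE) - 1
  l1 <- simulate_l1(car, eff)
  r1 <- as.integer(l1 == "deg0")
  y2 <- as.integer(simulate_l2(car, r1, eff) == "deg0")
  co <- coef(glm(y2 ~ car + r1, family = binomial()))
  expect_lt(abs(co[["r1"]] - 2.3), 0.05)
  expect_lt(abs(co[["car"]] - 2.0), 0.05)
})
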