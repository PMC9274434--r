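test_that("orientation vectors follow the doubled-angle formulas", {
  v <- orientation_vector(rep(30, 17))
  expect_equal(v[["L"]], 100)
  expect_equal(v[["direction"]], 30)
  # balanced tripod cancels exactly
  v0 <- orientation_vector(c(10, 70, 130))
  expect_lt(v0[["L"]], 1e-10)
  # worked three-trial case
  v3 <- orientation_vector(c(0, 0, 60))
  expect_equal(v3[["L"]], 100 * sqrt(sin(2 * pi / 3)^2 +
                                       (2 + cos(2 * pi / 3))^2) / 3,
               tolerance = 1e-12)
  expect_equal(v3[["L"]], 57.735, tolerance = 1e-4)
  expect_equal(v3[["direction"]], 15)
  expect_error(orientation_vector(numeric(0)), "empty")
})

test_that("orientation vectors are rotation-equivariant and axial", {
  set.seed(21)
  for (rep_i in 1:20) {
    th <- runif(sample(3:50, 1), 0, 180)
    delta <- runif(1, -360, 360)
    v <- orientation_vector(th)
    vr <- orientation_vector(th + delta)
    expect_equal(vr[["L"]], v[["L"]], tolerance = 1e-10)
    expect_lt(axial_dist(vr[["direction"]],
                         (v[["direction"]] + delta) %% 180), 1e-8)
    va <- orientation_vector(th + 180)
    expect_equal(va[["L"]], v[["L"]], tolerance = 1e-10)
    expect_lt(axial_dist(va[["direction"]], v[["direction"]]), 1e-8)
    expect_gte(v[["L"]], 0)
    expect_lte(v[["L"]], 100)
    expect_gte(v[["direction"]], 0)
    expect_lt(v[["direction"]], 180)
  }
})

test_that("per-participant bias drops 90-degree responses and flags
          all-lapse observers", {
  rows <- make_trial_rows(6, task = "orientation")
  rows$base_orientation <- c(10L, 10L, 20L, 30L, 40L, 50L)
  rows$l2_response <- c("deg0", "deg0", "deg60", "deg90", "deg90", "deg0")
  b <- bias_per_participant(rows)
  expect_equal(b$n_trials_used, 4L)
  expect_equal(b$vector_magnitude,
               orientation_vector(c(10, 10, 80, 50))[["L"]])
  # all-90 observer: flagged absent
  rows90 <- make_trial_rows(4, participant = "P2", task = "orientation")
  rows90$l2_response <- "deg90"
  b90 <- bias_per_participant(rows90)
  expect_true(is.na(b90$vector_magnitude))
  expect_equal(b90$n_trials_used, 0L)
  # identical responses in two sessions give identical rows
  rows2 <- rows
  rows2$session <- 2L
  b2 <- bias_per_participant(rbind(rows, rows2))
  expect_equal(b2$vector_magnitude[1], b2$vector_magnitude[2])
  expect_equal(b2$vector_direction[1], b2$vector_direction[2])
})

test_that("a flat-bias observer's magnitude is consistent with the null
          distribution", {
  spec <- design_spec(n_participants = 1)
  flat <- list(participant = "P1", bias_concentration = 0,
               bias_direction = 0, lapse_rate = 0)
  tr <- simulate_orientation_task(flat, spec, seed = 33)
  off <- c(deg0 = 0, deg60 = 60, deg120 = 120)[tr$l2_response]
  L_obs <- orientation_vector((tr$base_orientation + off) %% 180)[["L"]]
  # null distribution of L at n = 240 by direct simulation
  set.seed(34)
  L_null <- replicate(400, {
    th <- (rep(1:60, 4) + sample(c(0, 60, 120), 240, replace = TRUE)) %% 180
    orientation_vector(th)[["L"]]
  })
  expect_lt(L_obs, quantile(L_null, 0.95) + 1)
})

test_that("circular-circular correlation has the stated invariances", {
  set.seed(8)
  a <- runif(40, 0, 180)
  expect_equal(circular_circular_correlation(a, a), 1)
  expect_equal(circular_circular_correlation(a, (a + 37) %% 180), 1,
               tolerance = 1e-10)
  expect_error(circular_circular_correlation(a[1:2], a[1:2]), "3")
  # independent pairs: mean coefficient near zero
  r <- replicate(1000, {
    circular_circular_correlation(runif(75, 0, 180), runif(75, 0, 180))
  })
  expect_lt(abs(mean(r)), 0.05)
})

test_that("bias-effect relations recover a built-in positive correlation", {
  set.seed(91)
  n <- 40
  hyst <- rnorm(n, 2.3, 1)
  L <- 40 + 8 * scale(hyst)[, 1] * 0.3 / sd(scale(hyst)[, 1]) +
    rnorm(n, 0, 8)
  biases <- data.frame(participant = sprintf("P%03d", 1:n), session = 1L,
                       vector_magnitude = pmin(pmax(L, 0), 100),
                       vector_direction = runif(n, 0, 180),
                       n_trials_used = 240L)
  eff <- data.frame(participant = sprintf("P%03d", 1:n), mean = hyst)
  rel <- bias_effect_relation(biases, eff, "negative",
                              sampler_config(2, 1500, 500, seed = 5))
  expect_gt(rel$bf_opposite$bf, 1)
  expect_lt(rel$bf$bf, 1)
  expect_equal(rel$n, n)
})
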