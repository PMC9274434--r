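test_that("model construction validates its specification", {
  bt <- small_cohort()$binary
  expect_error(build_percept_model(bt, fixed = c("intercept", "ar"),
                                   random = c("intercept", "r1")),
               "subset of fixed")
  expect_error(build_percept_model(bt, fixed = c("intercept", "ar"),
                                   constraint = c(r1 = "positive")),
               "not in the model")
  ctrl <- bt
  ctrl$centered_ar <- NA_real_
  expect_error(build_percept_model(ctrl, fixed = c("intercept", "ar", "r1")),
               "aspect ratio")
  # joint model requires both sessions for everyone
  bt2 <- rbind(bt, transform(bt[bt$participant != bt$participant[1], ],
                             session = 2L))
  expect_error(build_percept_model(bt2, sessions = "joint"),
               "missing a session")
  expect_error(percept_model_spec("nonsense"), "unknown model variant")
})

test_that("the collapsed binomial cells preserve the trial counts", {
  bt <- small_cohort()$binary
  m <- build_percept_model(bt)
  expect_equal(sum(m$cells$n), nrow(bt))
  expect_equal(sum(m$cells$y), sum(bt$y2))
  expect_lte(nrow(m$cells), m$I * 14)
  # dropping the ar term merges aspect-ratio cells but keeps totals
  m2 <- build_percept_model(bt, fixed = c("intercept", "r1"))
  expect_equal(sum(m2$cells$n), nrow(bt))
  expect_lte(nrow(m2$cells), m$I * 2)
})

test_that("relabeling the outcome and negating the predictor terms leaves
          the likelihood unchanged", {
  bt <- small_cohort()$binary
  flip <- bt
  flip$y2 <- 1L - flip$y2
  m1 <- build_percept_model(bt)
  m2 <- build_percept_model(flip)
  lp1 <- dotlattice:::.make_lp(m1)
  lp2 <- dotlattice:::.make_lp(m2)
  set.seed(5)
  d <- length(dotlattice:::.param_nodes(m1))
  theta <- matrix(rnorm(6 * d, sd = 0.4), 6, d)
  # negate fixed effects and individual deviations (z); keep scales
  theta_neg <- theta
  theta_neg[, 1:3] <- -theta[, 1:3]
  zi <- (d - m1$I * 3 + 1):d
  theta_neg[, zi] <- -theta[, zi]
  expect_equal(lp1(theta), lp2(theta_neg), tolerance = 1e-10)
})

test_that("fits are deterministic and recover a small cohort", {
  f <- small_fit("full")
  f2 <- fit_percept_model(small_cohort()$binary, "full",
                          sampler = small_sampler())
  expect_identical(f$draws, f2$draws)
  co <- coef(f)
  expect_named(co, c("intercept", "ar", "r1"))
  # population values 2.0 / 2.3 within a generous small-sample margin
  expect_lt(abs(co[["r1"]] - 2.3), 1.0)
  expect_lt(abs(co[["ar"]] - 2.0), 1.2)
  expect_true(all(is.finite(f$lp(f$theta[seq(1, 1600, by = 100), ]))))
  expect_true(all(c("rhat", "ess", "reliable") %in%
                    names(f$diagnostics)))
})

test_that("a common-effects term is shared by every participant", {
  fc <- small_fit("common-hyst")
  tot <- individual_draws(fc, "r1")
  expect_equal(tot[, 1], tot[, 5])
  s <- individual_effect_summaries(fc, "r1")
  expect_equal(length(unique(round(s$mean, 10))), 1L)
  expect_error(individual_draws(fc, "ar_r1"), "not in the model")
})

test_that("highest density intervals match the normal closed form", {
  set.seed(9)
  x <- rnorm(20000, 2, 0.1)
  hd <- hdci(x, 0.95)
  expect_lt(abs(hd[["lower"]] - (2 - 1.96 * 0.1)), 0.01)
  expect_lt(abs(hd[["upper"]] - (2 + 1.96 * 0.1)), 0.01)
  # narrower mass gives a narrower interval
  hd80 <- hdci(x, 0.80)
  expect_lt(hd80[["upper"]] - hd80[["lower"]], hd[["upper"]] - hd[["lower"]])
})

test_that("with SD priors pinned near zero the fixed effects match a
          single-level logistic fit", {
  bt <- small_cohort()$binary
  f <- fit_percept_model(bt, "full", priors = percept_priors(scale_sd = 0.01),
                         sampler = small_sampler(21))
  g <- glm(y2 ~ centered_ar + r1, family = binomial(), data = bt)
  expect_lt(max(abs(coef(f) - coef(g)[c(1, 2, 3)])), 0.15)
})

test_that("prior-predictive response probability is centred at one half", {
  f <- small_fit("full")
  pri <- prior_individual_draws(f, "intercept", ndraws = 20000, seed = 3)
  expect_lt(abs(median(inv_logit(pri[, 1])) - 0.5), 0.02)
})

test_that("fit methods provide the standard modelling interface", {
  f <- small_fit("full")
  expect_output(print(f), "Hierarchical percept model")
  s <- summary(f)
  expect_true(all(c("b_intercept", "b_ar", "b_r1", "sd_r1",
                    "cor_ar_r1") %in% s$parameter))
  expect_true(all(s$hdci_low <= s$hdci_high))
  nd <- data.frame(centered_ar = c(-0.2, 0, 0.2), r1 = c(0, 1, 1))
  pr <- predict(f, nd, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  expect_true(predict(f, nd)[2] > predict(f, nd)[1])  # hysteresis raises odds
  res <- residuals(f)
  expect_length(res, nrow(f$model$cells))
  expect_lt(mean(abs(res)), 3)
  sim <- simulate(f, nsim = 2, seed = 4)
  expect_true(all(sim$sim_1 <= sim$n))
  expect_identical(sim, simulate(f, nsim = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(f))
  grDevices::dev.off()
})

test_that("individual-effect summaries expose the requested mass", {
  f <- small_fit("full")
  s95 <- individual_effect_summaries(f, "r1", mass = 0.95)
  s80 <- individual_effect_summaries(f, "r1", mass = 0.80)
  expect_equal(nrow(s95), 8)
  expect_true(all(s80$hdci_high - s80$hdci_low <
                    s95$hdci_high - s95$hdci_low))
  truth <- small_cohort()$truth
  expect_gt(cor(s95$mean, truth$hysteresis[match(s95$participant,
                                                 truth$participant)]), 0.5)
})
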