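test_that("trial tables round-trip through CSV unchanged", {
  d <- design_spec(n_participants = 3, n_blocks = 2, trials_per_block = 14)
  st <- simulate_study(d, population_params(), sessions = 1:2, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(st$trials, path)
  back <- read_trials(path)
  expect_equal(back, st$trials)
})

test_that("schema violations are rejected with row and field", {
  rows <- make_trial_rows(2)
  bad <- rows
  bad$task[2] <- "orientation"
  bad$l1_response[2] <- NA
  bad$base_orientation[2] <- 30L
  # aspect ratio still set on the orientation-task row
  expect_error(write_trials(bad, tempfile()), "row 2.*aspect_ratio")
  bad2 <- rows
  bad2$task[1] <- "mystery"
  expect_error(write_trials(bad2, tempfile()), "unknown task")
  bad3 <- rows
  bad3$l2_response[2] <- "deg45"
  expect_error(write_trials(bad3, tempfile()), "row 2.*l2_response")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant,session,task", path)
  expect_error(read_trials(path), "missing columns")
})

test_that("participant exclusions follow the strict 40% diagonal rule", {
  mk <- function(id, n_trials, n_diag) {
    rows <- make_trial_rows(n_trials, participant = id)
    rows$l1_response <- c(rep("diag1", n_diag),
                          rep("deg0", n_trials - n_diag))
    rows
  }
  trials <- rbind(mk("A", 630, 259),  # 41.1% diagonal
                  mk("B", 630, 252),  # exactly 40.0%
                  mk("C", 629, 0))    # incomplete
  ex <- apply_participant_exclusions(trials, sessions_required = 1L,
                                     complete_n = 630L)
  ex <- ex[order(ex$participant), ]
  expect_equal(ex$excluded, c(TRUE, FALSE, TRUE))
  expect_equal(ex$reason, c("diagonal_rate_exceeded", "none",
                            "incomplete_session"))
  expect_equal(ex$diagonal_rate[1:2], c(259 / 630, 0.40))
  # a participant with zero main-task trials is incomplete
  ori <- make_trial_rows(5, participant = "D", task = "orientation")
  ex2 <- apply_participant_exclusions(rbind(trials, ori), 1L, 630L)
  expect_equal(ex2$reason[ex2$participant == "D"], "incomplete_session")
})

test_that("raising the diagonal threshold never excludes more people", {
  d <- design_spec(n_participants = 10, n_blocks = 1, trials_per_block = 70)
  st <- simulate_study(d, population_params(lapse_rate = 0.3), sessions = 1,
                       tasks = "main", seed = 77)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    sum(apply_participant_exclusions(st$trials, 1L, complete_n = 70L,
                                     diagonal_threshold = th)$excluded),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("binary-trial reduction drops exactly the non-dominant responses", {
  rows <- make_trial_rows(10, aspect_ratio = 1.1)
  rows$l1_response[c(2, 5)] <- c("diag1", "diag2")
  rows$l2_response[8] <- "deg90"
  rows$l2_response[c(1, 3)] <- c("deg60", "deg120")
  bt <- to_binary_trials(rows)
  expect_equal(nrow(bt), 7)
  expect_equal(bt$centered_ar, rep(0.1, 7), tolerance = 1e-12)
  expect_equal(bt$r1, rep(1L, 7))
  expect_equal(sum(bt$y2 == 0), 2)
  # aspect ratio 1.0 maps to centered 0.0
  rows2 <- make_trial_rows(2, aspect_ratio = 1.0)
  expect_equal(to_binary_trials(rows2)$centered_ar, c(0, 0))
  # filtering is idempotent: kept rows survive a reapplication untouched
  kept <- rows[rows$l1_response %in% c("deg0", "deg90") &
                 rows$l2_response %in% c("deg0", "deg60", "deg120"), ]
  expect_equal(to_binary_trials(kept), bt)
})

test_that("empirical logits use the boundary continuity correction only", {
  bt <- data.frame(
    participant = "P1", session = 1L, task = "main",
    centered_ar = rep(c(0, 0.1, 0.2), times = c(10, 10, 10)),
    r1 = 1L,
    y2 = c(rep(1, 5), rep(0, 5),   # 5/10 -> logit 0
           rep(1, 10),             # 10/10 -> boundary
           rep(1, 3), rep(0, 7)))  # 3/10
  lg <- empirical_logits(bt, by = "centered_ar")
  expect_equal(lg$logit[lg$centered_ar == 0], 0)
  expect_equal(lg$logit[lg$centered_ar == 0.1], log(10.5 / 0.5))
  expect_equal(lg$logit[lg$centered_ar == 0.2], log(0.3 / 0.7))
  expect_equal(lg$n, c(10, 10, 10))
})

test_that("response-bias summary reports proportions and hand asymmetry", {
  rows <- make_trial_rows(630)
  rows$l1_response <- c(rep("diag1", 63), rep("deg0", 567))
  rows$response_hand <- "L"
  rb <- response_bias_summary(rows)
  expect_equal(rb$p_diagonal_l1, 0.1)
  expect_equal(rb$left_right_asymmetry, 0.5)
  rows$response_hand <- NA_character_
  rb2 <- response_bias_summary(rows)
  expect_true(is.na(rb2$left_right_asymmetry))
  expect_equal(rb2$p_diagonal_l1, 0.1)
  # a lapse-free simulated observer never reports 90 degrees for L2
  d <- design_spec(n_participants = 2, n_blocks = 1, trials_per_block = 70)
  st <- simulate_study(d, population_params(lapse_rate = 0), sessions = 1,
                       tasks = "main", seed = 5)
  expect_equal(response_bias_summary(st$trials)$p_deg90_l2, c(0, 0))
})
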