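# Shared simulated cohorts and fits, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# lapse-free single-session main-task cohort, 8 observers x 210 trials
small_cohort <- function() fixture("small_cohort", {
  d <- design_spec(n_participants = 8, n_blocks = 3, trials_per_block = 70)
  st <- simulate_study(d, population_params(lapse_rate = 0), sessions = 1,
                       tasks = "main", seed = 7001)
  bt <- to_binary_trials(st$trials)
  list(binary = bt[bt$task == "main", ], truth = st$effects)
})

small_sampler <- function(seed = 11L) sampler_config(chains = 2L,
                                                     iterations = 800L,
                                                     warmup = 600L,
                                                     seed = seed)

small_fit <- function(model = "full") {
  fixture(paste0("fit_", model),
          fit_percept_model(small_cohort()$binary, model,
                            sampler = small_sampler()))
}

# hand-built trial rows in the schema, all fields valid unless overridden
make_trial_rows <- function(n, participant = "P1", session = 1L,
                            task = "main", l1 = "deg0", l2 = "deg0",
                            aspect_ratio = 1.1, hand = "L") {
  data.frame(participant = participant, session = session, task = task,
             block = 1L, trial = seq_len(n),
             aspect_ratio = if (task == "main") aspect_ratio else NA_real_,
             base_orientation = if (task == "orientation") 30L else 10L,
             l1_response = if (task == "orientation") NA_character_ else l1,
             l2_response = l2, response_hand = hand,
             stringsAsFactors = FALSE)
}

# axial distance between two orientations in degrees
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
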