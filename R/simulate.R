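#' Experimental design specification
#'
#' The replica design: each participant completes, per session, nine main-task
#' blocks of 70 trials (10 per aspect ratio), one 90-trial control block in
#' session 1, and four orientation-bias blocks of 60 trials (each absolute
#' orientation 1-60 degrees once per block).
#'
#' @param n_participants number of simulated observers (default 75).
#' @param n_blocks main-task blocks per session (default 9).
#' @param trials_per_block main-task trials per block (default 70); must be
#'   divisible by the number of aspect ratios.
#' @param aspect_ratios ordered vector of design aspect ratios.
#' @param control_trials control-task trials (default 90, one block).
#' @param orientation_blocks,orientation_trials_per_block orientation-task
#'   layout (default 4 x 60).
#' @param orientation_range inclusive degree range of absolute orientations
#'   (default `c(1, 60)`); its width must equal `orientation_trials_per_block`.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(n_participants = 75L, n_blocks = 9L,
                        trials_per_block = 70L,
                        aspect_ratios = design_aspect_ratios(),
                        control_trials = 90L,
                        orientation_blocks = 4L,
                        orientation_trials_per_block = 60L,
                        orientation_range = c(1L, 60L)) {
  if (trials_per_block %% length(aspect_ratios) != 0)
    stop("trials_per_block must be divisible by the number of aspect ratios")
  if (diff(orientation_range) + 1L != orientation_trials_per_block)
    stop("orientation_range width must equal orientation_trials_per_block")
  structure(list(n_participants = as.integer(n_participants),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 aspect_ratios = aspect_ratios,
                 control_trials = as.integer(control_trials),
                 orientation_blocks = as.integer(orientation_blocks),
                 orientation_trials_per_block = as.integer(orientation_trials_per_block),
                 orientation_range = as.integer(orientation_range)),
            class = "design_spec")
}

#' Population parameters of the synthetic observer
#'
#' Generative counterpart of the hierarchical model: population means and
#' spreads (logit units) of the individual intercepts and slopes, their
#' correlations, and the nuisance processes (lapses, orientation bias,
#' response hand).
#'
#' Default effect sizes sit at the centre of the effects reported for this
#' paradigm: hysteresis 2.3, adaptation 2.0, hysteresis-adaptation
#' correlation 0.7, strongly negative proximity slope. The default lapse
#' rate 0.15 makes the expected share of main-task trials dropped in
#' preprocessing (diagonal first responses plus 90-degree second responses)
#' about 19 percent.
#'
#' @param mu_intercept,mu_hysteresis,mu_adaptation population means of the
#'   second-lattice model terms (logit units).
#' @param mu_proximity,mu_intercept_l1 population means of the first-lattice
#'   model terms.
#' @param sd_intercept,sd_hysteresis,sd_adaptation,sd_proximity,sd_intercept_l1
#'   between-participant SDs.
#' @param rho_hyst_adapt within-session correlation between individual
#'   hysteresis and adaptation effects.
#' @param rho_session named vector of cross-session correlations per effect
#'   (nonnegative; effects `intercept_l1`, `proximity`, `intercept`,
#'   `hysteresis`, `adaptation`).
#' @param lapse_rate probability of a non-dominant (diagonal / 90-degree)
#'   response on any report.
#' @param control_carryover multiplier on the hysteresis slope in the
#'   control task (random first lattice), emulating a residual decisional
#'   carry-over (default 0.4).
#' @param bias_concentration,bias_direction axial von-Mises-type orientation
#'   bias: weight of candidate orientation x is proportional to
#'   exp(concentration * cos(2 * (x - direction))); direction in degrees.
#' @param sd_bias_concentration,sd_bias_direction between-participant spread
#'   of the bias parameters (concentration truncated at 0; direction on the
#'   axial circle).
#' @param sd_hand_bias SD of the per-participant left-hand response bias.
#' @return list of class `population_params`.
#' @export
population_params <- function(mu_intercept = -1.0, mu_hysteresis = 2.3,
                              mu_adaptation = 2.0, mu_proximity = -8.0,
                              mu_intercept_l1 = 0.0,
                              sd_intercept = 0.5, sd_hysteresis = 1.0,
                              sd_adaptation = 1.0, sd_proximity = 2.0,
                              sd_intercept_l1 = 0.5,
                              rho_hyst_adapt = 0.7,
                              rho_session = c(intercept_l1 = 0.8,
                                              proximity = 0.9,
                                              intercept = 0.8,
                                              hysteresis = 0.8,
                                              adaptation = 0.95),
                              lapse_rate = 0.15,
                              control_carryover = 0.4,
                              bias_concentration = 0.4,
                              bias_direction = 90,
                              sd_bias_concentration = 0.3,
                              sd_bias_direction = 30,
                              sd_hand_bias = 0.05) {
  stopifnot(abs(rho_hyst_adapt) <= 1, lapse_rate >= 0, lapse_rate <= 1,
            bias_concentration >= 0)
  rho_session <- rho_session[c("intercept_l1", "proximity", "intercept",
                               "hysteresis", "adaptation")]
  if (anyNA(rho_session))
    stop("rho_session must name all effects: intercept_l1, proximity, ",
         "intercept, hysteresis, adaptation")
  if (any(rho_session < 0 | rho_session > 1))
    stop("cross-session correlations must lie in [0, 1] for this generator")
  structure(mget(names(formals())), class = "population_params")
}

.effect_names <- c("intercept_l1", "proximity", "intercept", "hysteresis",
                   "adaptation")

#' Draw per-participant true effects
#'
#' Individual effects are multivariate normal around the population means.
#' Within a session, hysteresis and adaptation deviations correlate exactly
#' `rho_hyst_adapt`; across sessions each effect correlates exactly
#' `rho_session[effect]` with itself. The joint structure comes from a
#' shared plus session-unique factor model whose hysteresis-adaptation
#' coupling is rescaled so the within-session correlation is exact;
#' settings that no such factor model can realize (a large
#' `rho_hyst_adapt` combined with very discrepant session correlations)
#' raise an error.
#'
#' @param pop [population_params()].
#' @param n_participants number of observers.
#' @param sessions sessions to draw (default `1:2`).
#' @param seed integer seed.
#' @return data frame with one row per participant x session: true
#'   `intercept_l1`, `proximity`, `intercept`, `hysteresis`, `adaptation`
#'   (logit units) plus nuisance truths `lapse_rate`, `bias_concentration`,
#'   `bias_direction`, `hand_bias`.
#' @export
draw_participants <- function(pop, n_participants, sessions = 1:2,
                              seed = NULL) {
  with_seed(seed, {
    eff <- .effect_names
    K <- length(eff)
    S <- length(sessions)
    rho <- pop$rho_session
    # joint correlation over (effect, session) coordinates, from a shared +
    # session-unique factor model: deviation_es = sqrt(rho_e) u_e +
    # sqrt(1-rho_e) v_es, with corr(u_h, u_a) = corr(v_hs, v_as) = x chosen
    # so the within-session hysteresis-adaptation correlation is exact
    A <- sqrt(rho[["hysteresis"]] * rho[["adaptation"]])
    B <- sqrt((1 - rho[["hysteresis"]]) * (1 - rho[["adaptation"]]))
    x <- if (pop$rho_hyst_adapt == 0) 0 else pop$rho_hyst_adapt / (A + B)
    if (!is.finite(x) || abs(x) > 1)
      stop("rho_hyst_adapt is too large for the session correlations of ",
           "hysteresis and adaptation; reduce it or align the session ",
           "correlations", call. = FALSE)
    C <- diag(K * S)
    coord <- function(k, si) (si - 1L) * K + k
    hk <- match("hysteresis", eff)
    ak <- match("adaptation", eff)
    for (si in seq_len(S)) for (sj in seq_len(S)) {
      for (k in seq_len(K)) {
        if (si != sj) C[coord(k, si), coord(k, sj)] <- rho[[eff[k]]]
      }
      cross <- if (si == sj) pop$rho_hyst_adapt else A * x
      C[coord(hk, si), coord(ak, sj)] <- cross
      C[coord(ak, sj), coord(hk, si)] <- cross
    }
    ec <- eigen(C, symmetric = TRUE)
    if (min(ec$values) < -1e-8)
      stop("rho_hyst_adapt and rho_session imply a non-positive-",
           "semidefinite joint covariance", call. = FALSE)
    A <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0)), nrow = K * S)
    n <- n_participants
    dev <- matrix(stats::rnorm(n * K * S), n, K * S) %*% t(A)
    mus <- c(intercept_l1 = pop$mu_intercept_l1, proximity = pop$mu_proximity,
             intercept = pop$mu_intercept, hysteresis = pop$mu_hysteresis,
             adaptation = pop$mu_adaptation)
    sds <- c(intercept_l1 = pop$sd_intercept_l1, proximity = pop$sd_proximity,
             intercept = pop$sd_intercept, hysteresis = pop$sd_hysteresis,
             adaptation = pop$sd_adaptation)
    conc <- pmax(0, stats::rnorm(n, pop$bias_concentration,
                                 pop$sd_bias_concentration))
    bdir <- (pop$bias_direction + stats::rnorm(n, 0, pop$sd_bias_direction)) %% 180
    hand <- pmin(0.45, pmax(-0.45, stats::rnorm(n, 0, pop$sd_hand_bias)))
    out <- NULL
    for (si in seq_len(S)) {
      vals <- dev[, coord(seq_len(K), si), drop = FALSE]
      vals <- sweep(sweep(vals, 2, sds[eff], `*`), 2, mus[eff], `+`)
      colnames(vals) <- eff
      out <- rbind(out, data.frame(
        participant = sprintf("P%03d", seq_len(n)), session = sessions[si],
        vals, lapse_rate = pop$lapse_rate, bias_concentration = conc,
        bias_direction = bdir, hand_bias = hand,
        stringsAsFactors = FALSE, row.names = NULL))
    }
    out
  })
}

#' Main-task trial skeleton
#'
#' Per block, each aspect ratio appears `trials_per_block / n_aspect_ratios`
#' times in seeded-shuffled order; the absolute 0-degree orientation of each
#' trial is drawn uniformly over 0-89 degrees.
#'
#' @param spec [design_spec()].
#' @param participants character vector of participant ids.
#' @param session session number.
#' @param seed integer seed.
#' @return trial-schema data frame with empty response columns.
#' @export
make_design <- function(spec, participants = NULL, session = 1L, seed = NULL) {
  if (is.null(participants))
    participants <- sprintf("P%03d", seq_len(spec$n_participants))
  with_seed(seed, {
    per_ar <- spec$trials_per_block %/% length(spec$aspect_ratios)
    out <- vector("list", length(participants) * spec$n_blocks)
    k <- 0
    for (p in participants) {
      for (b in seq_len(spec$n_blocks)) {
        ars <- sample(rep(spec$aspect_ratios, per_ar))
        k <- k + 1
        out[[k]] <- data.frame(
          participant = p, session = session, task = "main", block = b,
          trial = seq_along(ars), aspect_ratio = ars,
          base_orientation = sample(0:89, length(ars), replace = TRUE),
          l1_response = NA_character_, l2_response = NA_character_,
          response_hand = NA_character_, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

# first-lattice response rule (vectorized over trials of one observer)
.sim_l1 <- function(centered_ar, intercept_l1, proximity, lapse_rate,
                    task = "main") {
  n <- length(centered_ar)
  lapse <- stats::runif(n) < lapse_rate
  eta <- intercept_l1 + ifelse(is.na(centered_ar), 0, proximity * centered_ar)
  deg0 <- stats::runif(n) < inv_logit(eta)
  diag_opts <- if (task == "main") c("diag1", "diag2") else c("deg45", "deg135")
  ifelse(lapse, sample(diag_opts, n, replace = TRUE),
         ifelse(deg0, "deg0", "deg90"))
}

# second-lattice response rule; r1 is the 0-degree indicator of the percept
.sim_l2 <- function(centered_ar, r1, intercept, adaptation, hysteresis,
                    lapse_rate) {
  n <- length(r1)
  lapse <- stats::runif(n) < lapse_rate
  eta <- intercept + ifelse(is.na(centered_ar), 0, adaptation * centered_ar) +
    hysteresis * r1
  y2 <- stats::runif(n) < inv_logit(eta)
  alt <- sample(c("deg60", "deg120"), n, replace = TRUE)
  lapse_resp <- sample(c("deg60", "deg120", "deg90"), n, replace = TRUE)
  ifelse(lapse, lapse_resp, ifelse(y2, "deg0", alt))
}

#' Simulate first- and second-lattice responses
#'
#' `simulate_l1()`: with probability `lapse_rate` a uniformly chosen
#' diagonal; otherwise a 0-vs-90-degree Bernoulli report with log-odds
#' `intercept_l1 + proximity * centered_ar`. `simulate_l2()`: with
#' probability `lapse_rate` a uniform draw over 60/120/90 degrees; otherwise
#' a Bernoulli report with log-odds `intercept + adaptation * centered_ar +
#' hysteresis * r1`, 0-degree on success, 60 or 120 with equal probability
#' otherwise.
#'
#' @param centered_ar centered aspect ratio (AR - 1); NA means no stimulus
#'   support (random lattice), contributing 0 to the log-odds.
#' @param r1 indicator, 1 = first lattice perceived at 0 degrees.
#' @param effects one row of [draw_participants()] output (or any list with
#'   the needed fields).
#' @param lapse_rate overrides `effects$lapse_rate` when given.
#' @return character vector of response categories.
#' @export
simulate_l1 <- function(centered_ar, effects, lapse_rate = NULL) {
  .sim_l1(centered_ar, effects$intercept_l1, effects$proximity,
          if (is.null(lapse_rate)) effects$lapse_rate else lapse_rate)
}

#' @rdname simulate_l1
#' @export
simulate_l2 <- function(centered_ar, r1, effects, lapse_rate = NULL) {
  .sim_l2(centered_ar, r1, effects$intercept, effects$adaptation,
          effects$hysteresis,
          if (is.null(lapse_rate)) effects$lapse_rate else lapse_rate)
}

#' Simulate the orientation-bias task
#'
#' Hexagonal lattices at absolute orientations over the design range; the
#' response is drawn over the three dominant candidates (base, base + 60,
#' base + 120 degrees) with axial von-Mises-type weights proportional to
#' exp(concentration * cos(2 * (candidate - bias_direction))); with
#' probability `lapse_rate` the unlikely 90-degree option is reported
#' instead.
#'
#' @param effects one row of [draw_participants()] for this participant and
#'   session.
#' @param spec [design_spec()].
#' @param session session number.
#' @param seed integer seed.
#' @return trial-schema data frame of orientation-task trials.
#' @export
simulate_orientation_task <- function(effects, spec, session = 1L,
                                      seed = NULL) {
  with_seed(seed, {
    oris <- seq(spec$orientation_range[1], spec$orientation_range[2])
    blocks <- lapply(seq_len(spec$orientation_blocks), function(b) {
      base <- sample(oris)
      offs <- c(0, 60, 120)
      resp <- vapply(base, function(th) {
        w <- exp(effects$bias_concentration *
                   cospi(2 * (th + offs - effects$bias_direction) / 180))
        c("deg0", "deg60", "deg120")[sample.int(3, 1, prob = w)]
      }, character(1))
      lapse <- stats::runif(length(base)) < effects$lapse_rate
      resp[lapse] <- "deg90"
      data.frame(participant = effects$participant, session = session,
                 task = "orientation", block = b, trial = seq_along(base),
                 aspect_ratio = NA_real_, base_orientation = base,
                 l1_response = NA_character_, l2_response = resp,
                 response_hand = NA_character_, stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
}

#' Simulate a full study
#'
#' Generates the replica design and responses for every requested task and
#' session: the main task (rectangular first lattice, hexagonal second), the
#' session-1 control task (random first lattice; hysteresis scaled by
#' `pop$control_carryover`, no adaptation term since the first lattice
#' carries no aspect ratio), and the orientation-bias task.
#'
#' @param design [design_spec()].
#' @param pop [population_params()].
#' @param sessions sessions to simulate (default `1:2`).
#' @param tasks subset of `c("main", "control", "orientation")`.
#' @param seed integer seed; fixes the whole study deterministically.
#' @param lapse_override optional named vector (participant id ->
#'   lapse rate) replacing individual lapse rates, e.g. to plant
#'   random-responding observers; a name like `"P003.2"` restricts the
#'   override to session 2.
#' @return list of class `sim_study` with elements `trials` (trial-schema
#'   data frame), `effects` (true per-participant effects), `pop`, `design`,
#'   `seed`.
#' @export
simulate_study <- function(design = design_spec(), pop = population_params(),
                           sessions = 1:2,
                           tasks = c("main", "control", "orientation"),
                           seed = 1L, lapse_override = NULL) {
  effects <- draw_participants(pop, design$n_participants, sessions,
                               seed = child_seed(seed, 1L))
  ids <- unique(effects$participant)
  trials <- vector("list", 0L)
  for (s in sessions) {
    if ("orientation" %in% tasks) {
      for (p in ids) {
        er <- effects[effects$participant == p & effects$session == s, ]
        er$lapse_rate <- .lapse_for(lapse_override, p, s, er$lapse_rate)
        trials[[length(trials) + 1L]] <- simulate_orientation_task(
          er, design, session = s,
          seed = child_seed(seed, 1000L * s + match(p, ids)))
      }
    }
    if ("main" %in% tasks) {
      des <- make_design(design, ids, session = s,
                         seed = child_seed(seed, 500000L + s))
      trials[[length(trials) + 1L]] <- with_seed(
        child_seed(seed, 600000L + s),
        .fill_main(des, effects[effects$session == s, ], lapse_override, s))
    }
    if ("control" %in% tasks && s == 1L) {
      trials[[length(trials) + 1L]] <- with_seed(
        child_seed(seed, 700000L + s),
        .sim_control(design, effects[effects$session == s, ],
                     lapse_override, s, pop$control_carryover))
    }
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  structure(list(trials = trials, effects = effects, pop = pop,
                 design = design, seed = seed), class = "sim_study")
}

.lapse_for <- function(override, p, s, default) {
  if (is.null(override)) return(default)
  key_ps <- paste0(p, ".", s)
  if (key_ps %in% names(override)) return(unname(override[key_ps]))
  if (p %in% names(override)) return(unname(override[p]))
  default
}

.fill_main <- function(des, eff, lapse_override, session) {
  for (p in unique(des$participant)) {
    er <- eff[eff$participant == p, ]
    lr <- .lapse_for(lapse_override, p, session, er$lapse_rate)
    idx <- which(des$participant == p)
    car <- des$aspect_ratio[idx] - 1
    l1 <- .sim_l1(car, er$intercept_l1, er$proximity, lr)
    r1 <- ifelse(l1 == "deg0", 1L, ifelse(l1 == "deg90", 0L, NA_integer_))
    # a diagonal first report gives no dominant percept; the second report
    # is then generated without the hysteresis term
    l2 <- .sim_l2(car, ifelse(is.na(r1), 0L, r1), er$intercept,
                  er$adaptation, ifelse(is.na(r1), 0, er$hysteresis), lr)
    des$l1_response[idx] <- l1
    des$l2_response[idx] <- l2
    p_left <- 0.5 + er$hand_bias
    des$response_hand[idx] <- ifelse(stats::runif(length(idx)) < p_left,
                                     "L", "R")
  }
  des
}

.sim_control <- function(design, eff, lapse_override, session, carryover) {
  out <- vector("list", length(unique(eff$participant)))
  for (k in seq_along(out)) {
    er <- eff[k, ]
    lr <- .lapse_for(lapse_override, er$participant, session, er$lapse_rate)
    n <- design$control_trials
    l1 <- .sim_l1(rep(NA_real_, n), er$intercept_l1, 0, lr, task = "control")
    r1 <- ifelse(l1 == "deg0", 1L, ifelse(l1 == "deg90", 0L, NA_integer_))
    l2 <- .sim_l2(rep(NA_real_, n), ifelse(is.na(r1), 0L, r1), er$intercept,
                  0, ifelse(is.na(r1), 0, er$hysteresis * carryover), lr)
    out[[k]] <- data.frame(
      participant = er$participant, session = session, task = "control",
      block = 1L, trial = seq_len(n), aspect_ratio = NA_real_,
      base_orientation = sample(0:89, n, replace = TRUE),
      l1_response = l1, l2_response = l2,
      response_hand = ifelse(stats::runif(n) < 0.5 + er$hand_bias, "L", "R"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated study to disk
#'
#' Trials go to `<dir>/trials.csv` in the trial schema; the ground truth
#' (population parameters and per-participant true effects) goes to a
#' sidecar `<dir>/truth.yaml` for parameter-recovery tests.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(study$trials, file.path(dir, "trials.csv"))
  truth <- list(
    seed = study$seed,
    population = study$pop[!vapply(study$pop, is.function, TRUE)],
    effects = lapply(seq_len(nrow(study$effects)), function(i)
      as.list(study$effects[i, ]))
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
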