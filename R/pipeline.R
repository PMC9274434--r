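#' Run the full replica analysis pipeline
#'
#' End-to-end orchestration: simulate (or load) a study, apply participant
#' exclusions, preprocess to binary trials, fit the model family, and
#' compute every requested hypothesis test - average hysteresis/adaptation
#' (bridge-sampling BFs and fixed-effect HDCIs), the interaction check,
#' individual-differences and positive-effects comparisons, the
#' hysteresis-adaptation correlation, the control-task hysteresis, the
#' orientation-bias relations, the cross-session stability model families,
#' and the exploratory proximity and response-bias analyses. Every stage is
#' seeded from one top-level seed and timed in the run manifest.
#'
#' @param config nested list (or path to a YAML file) with optional
#'   sections `seed`, `trials_csv`, `design` (arguments of
#'   [design_spec()]), `population` (arguments of [population_params()]),
#'   `sampler` (arguments of [sampler_config()]), `hypotheses` (character
#'   subset of H1-H10, "proximity", "response_bias"; default all),
#'   `prior_draws` (encompassing denominator size), `sessions`.
#' @param out_dir if given, the report (JSON), exclusion and bias tables
#'   and individual-effect summaries (CSV) are written there.
#' @param quiet suppress JAGS output.
#' @return list of class `replica_report`: `report` (named results),
#'   `manifest` (config snapshot, seeds, data fingerprints, timings),
#'   `fits`, `data`.
#' @export
run_replica <- function(config = list(), out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hyps <- if (is.null(config$hypotheses))
    c(paste0("H", 1:10), "proximity", "response_bias") else config$hypotheses
  design <- do.call(design_spec, config$design %||% list())
  pop <- do.call(population_params, config$population %||% list())
  sessions <- config$sessions %||% 1:2
  sargs <- config$sampler %||% list()
  sargs$seed <- sargs$seed %||% child_seed(seed, 11L)
  sampler <- do.call(sampler_config, sargs)
  n_prior <- config$prior_draws %||% 20000L
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("dotlattice")),
                   timings = list())
  t_all <- Sys.time()
  tick <- function(stage, t0)
    manifest$timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))

  # ---- data ------------------------------------------------------------
  t0 <- Sys.time()
  if (!is.null(config$trials_csv)) {
    trials <- read_trials(config$trials_csv)
    truth <- NULL
  } else {
    study <- simulate_study(design, pop, sessions = sessions,
                            seed = child_seed(seed, 1L))
    trials <- study$trials
    truth <- study$effects
  }
  complete_n <- design$n_blocks * design$trials_per_block
  excl_s1 <- apply_participant_exclusions(trials, 1L, complete_n)
  keep_s1 <- excl_s1$participant[!excl_s1$excluded]
  has_s2 <- 2L %in% trials$session
  if (has_s2) {
    excl_joint <- apply_participant_exclusions(trials, 1:2, complete_n)
    keep_joint <- excl_joint$participant[!excl_joint$excluded]
  } else {
    excl_joint <- NULL
    keep_joint <- character(0)
  }
  main_s1 <- to_binary_trials(
    trials[trials$task == "main" & trials$session == 1L &
             trials$participant %in% keep_s1, ])
  manifest$data_fingerprint <- paste(nrow(trials), nrow(main_s1),
                                     sum(main_s1$y2), sep = "|")
  tick("data", t0)

  fits <- new.env(parent = emptyenv())
  get_fit <- function(name, data = main_s1) {
    if (is.null(fits[[name]])) {
      sc <- sampler
      sc$seed <- child_seed(seed, 100L + nchar(name) * 7L +
                              utf8ToInt(substr(name, 1, 1)))
      fits[[name]] <- fit_percept_model(data, model = name, sampler = sc,
                                        quiet = quiet)
    }
    fits[[name]]
  }
  report <- list()
  report$design_counts <- list(
    main_per_session = nrow(trials[trials$task == "main" &
                                     trials$session == 1L, ]),
    control = nrow(trials[trials$task == "control", ]),
    orientation_per_session = nrow(trials[trials$task == "orientation" &
                                            trials$session == 1L, ]))
  report$exclusions <- list(
    n_excluded_s1 = sum(excl_s1$excluded),
    n_kept_s1 = length(keep_s1),
    n_kept_joint = if (has_s2) length(keep_joint) else NA_integer_)

  t0 <- Sys.time()
  if ("H1" %in% hyps) {
    bf <- bf_bridge(get_fit("full"), get_fit("no-hyst"),
                    seed = child_seed(seed, 21L))
    f <- get_fit("full")
    hd <- hdci(f$draws[, sprintf("beta[%d]", match("r1", f$model$fix_names))])
    report$H1 <- list(log_bf_hysteresis = bf$log_bf, mc_error = bf$mc_error,
                      hysteresis_hdci = unname(hd))
  }
  if ("H2" %in% hyps) {
    bf <- bf_bridge(get_fit("full"), get_fit("no-adapt"),
                    seed = child_seed(seed, 22L))
    f <- get_fit("full")
    hd <- hdci(f$draws[, sprintf("beta[%d]", match("ar", f$model$fix_names))])
    report$H2 <- list(log_bf_adaptation = bf$log_bf, mc_error = bf$mc_error,
                      adaptation_hdci = unname(hd))
  }
  if ("H3" %in% hyps) {
    bf <- bf_bridge(get_fit("full"), get_fit("interaction"),
                    seed = child_seed(seed, 23L))
    report$H3 <- list(log_bf_no_interaction = bf$log_bf,
                      mc_error = bf$mc_error)
  }
  if ("H4" %in% hyps) {
    bf_h <- bf_bridge(get_fit("full"), get_fit("common-hyst"),
                      seed = child_seed(seed, 24L))
    bf_a <- bf_bridge(get_fit("full"), get_fit("common-adapt"),
                      seed = child_seed(seed, 25L))
    report$H4 <- list(log_bf_random_hysteresis = bf_h$log_bf,
                      log_bf_random_adaptation = bf_a$log_bf)
  }
  if ("H5" %in% hyps) {
    f <- get_fit("full")
    enc <- function(term, k) encompassing_bf(
      individual_draws(f, term),
      prior_individual_draws(f, term, n_prior,
                             seed = child_seed(seed, 26L + k)), "positive")
    bh <- enc("r1", 0L); ba <- enc("ar", 1L)
    report$H5 <- list(bf_positive_hysteresis = bh$bf,
                      bf_positive_adaptation = ba$bf,
                      bound_hysteresis = bh$bound, bound_adaptation = ba$bound)
  }
  if ("H6" %in% hyps) {
    f <- get_fit("full")
    internal <- .correlation_draws(f)[, "cor_ar_r1"]
    two_stage <- bayes_cor(colMeans(individual_draws(f, "r1")),
                           colMeans(individual_draws(f, "ar")),
                           sampler_config(2L, 2500L, 500L,
                                          child_seed(seed, 28L)))
    report$H6 <- list(
      bf_positive = savage_dickey_onesided(two_stage$r_draws, "positive")$bf,
      cor_mean = two_stage$mean, cor_hdci = unname(two_stage$hdci),
      model_cor_mean = mean(internal),
      model_cor_hdci = unname(hdci(internal)))
  }
  tick("confirmatory_s1", t0)

  if ("H7" %in% hyps) {
    t0 <- Sys.time()
    ctrl <- to_binary_trials(
      trials[trials$task == "control" & trials$participant %in% keep_s1, ])
    if (nrow(ctrl)) {
      sc <- sampler; sc$seed <- child_seed(seed, 31L)
      f1 <- fit_percept_model(ctrl, model = "control-full", sampler = sc,
                              quiet = quiet)
      sc$seed <- child_seed(seed, 32L)
      f0 <- fit_percept_model(ctrl, model = "control-null", sampler = sc,
                              quiet = quiet)
      bf <- bf_bridge(f1, f0, seed = child_seed(seed, 33L))
      hd <- hdci(f1$draws[, sprintf("beta[%d]",
                                    match("r1", f1$model$fix_names))])
      report$H7 <- list(log_bf_control_hysteresis = bf$log_bf,
                        control_hysteresis_hdci = unname(hd))
      fits$control_full <- f1
    }
    tick("control", t0)
  }

  biases <- NULL
  if (any(c("H8", "H10") %in% hyps) &&
      "orientation" %in% trials$task) {
    biases <- bias_per_participant(trials)
  }
  if ("H8" %in% hyps && !is.null(biases)) {
    t0 <- Sys.time()
    f <- get_fit("full")
    b1 <- biases[biases$session == 1L, ]
    rel <- function(term) bias_effect_relation(
      b1, individual_effect_summaries(f, term), "negative",
      sampler_config(2L, 2500L, 500L, child_seed(seed, 41L)))
    rh <- rel("r1"); ra <- rel("ar")
    quad <- function(term) bf_linear_vs_quadratic(
      b1$vector_magnitude[match(f$model$pid_levels, b1$participant)],
      colMeans(individual_draws(f, term)),
      seed = child_seed(seed, 42L))
    report$H8 <- list(
      bf_negative_hysteresis = rh$bf$bf, bf_positive_hysteresis = rh$bf_opposite$bf,
      cor_hysteresis = rh$cor$mean, cor_hysteresis_hdci = unname(rh$cor$hdci),
      bf_negative_adaptation = ra$bf$bf, bf_positive_adaptation = ra$bf_opposite$bf,
      cor_adaptation = ra$cor$mean, cor_adaptation_hdci = unname(ra$cor$hdci),
      log_bf_quadratic_hysteresis = quad("r1")$log_bf,
      log_bf_quadratic_adaptation = quad("ar")$log_bf)
    tick("orientation_bias", t0)
  }

  joint_data <- NULL
  if (has_s2 && any(c("H9", "proximity") %in% hyps) && length(keep_joint)) {
    joint_data <- to_binary_trials(
      trials[trials$task == "main" & trials$participant %in% keep_joint, ])
  }
  if ("H9" %in% hyps && !is.null(joint_data)) {
    t0 <- Sys.time()
    sess_cmp <- function(effect, k) compare_session_models(
      joint_data, effect, sampler = sampler, seed = child_seed(seed, 50L + k),
      quiet = quiet)
    ch <- sess_cmp("hysteresis", 1L)
    ca <- sess_cmp("adaptation", 2L)
    report$H9 <- list(
      hysteresis = list(log_bf_corr_vs_uncorr = ch$bf_corr_vs_uncorr$log_bf,
                        log_bf_corr_vs_full = ch$bf_corr_vs_full$log_bf,
                        rho_mean = ch$rho_mean, rho_hdci = unname(ch$rho_hdci)),
      adaptation = list(log_bf_corr_vs_uncorr = ca$bf_corr_vs_uncorr$log_bf,
                        log_bf_corr_vs_full = ca$bf_corr_vs_full$log_bf,
                        rho_mean = ca$rho_mean, rho_hdci = unname(ca$rho_hdci)))
    tick("sessions", t0)
  }
  if ("H10" %in% hyps && !is.null(biases) && has_s2) {
    b1 <- biases[biases$session == 1L, ]
    b2 <- biases[biases$session == 2L, ]
    mg <- merge(b1[c("participant", "vector_magnitude", "vector_direction")],
                b2[c("participant", "vector_magnitude", "vector_direction")],
                by = "participant", suffixes = c("_s1", "_s2"))
    cr <- bayes_cor(mg$vector_magnitude_s1, mg$vector_magnitude_s2,
                    sampler_config(2L, 2500L, 500L, child_seed(seed, 61L)))
    report$H10 <- list(
      bf_positive = savage_dickey_onesided(cr$r_draws, "positive")$bf,
      cor_mean = cr$mean, cor_hdci = unname(cr$hdci),
      circular_direction_cor = circular_circular_correlation(
        mg$vector_direction_s1, mg$vector_direction_s2, axial = TRUE))
  }

  if ("proximity" %in% hyps) {
    t0 <- Sys.time()
    fl <- get_fit("l1-full")
    flc <- get_fit("l1-common")
    bf <- bf_bridge(fl, flc, seed = child_seed(seed, 71L))
    enc <- encompassing_bf(
      individual_draws(fl, "ar"),
      prior_individual_draws(fl, "ar", n_prior, child_seed(seed, 72L)),
      "negative")
    prox <- list(log_bf_random_proximity = bf$log_bf,
                 bf_negative_proximity = enc$bf,
                 bound_negative = enc$bound)
    if (!is.null(joint_data)) {
      cp <- compare_session_models(joint_data, "proximity",
                                   sampler = sampler,
                                   seed = child_seed(seed, 73L),
                                   quiet = quiet)
      prox$log_bf_corr_vs_uncorr <- cp$bf_corr_vs_uncorr$log_bf
      prox$log_bf_corr_vs_full <- cp$bf_corr_vs_full$log_bf
      prox$rho_mean <- cp$rho_mean
    }
    if (!is.null(fits$full)) {
      pm <- colMeans(individual_draws(fl, "ar"))
      ids <- fl$model$pid_levels
      f <- fits$full
      idx <- match(f$model$pid_levels, ids)
      prox$cor_with_hysteresis <- stats::cor(
        pm[idx], colMeans(individual_draws(f, "r1")), use = "complete.obs")
      prox$cor_with_adaptation <- stats::cor(
        pm[idx], colMeans(individual_draws(f, "ar")), use = "complete.obs")
    }
    report$proximity <- prox
    tick("proximity", t0)
  }

  if ("response_bias" %in% hyps) {
    rb <- response_bias_summary(trials[trials$participant %in% keep_s1, ])
    out <- list(mean_p_diagonal_l1 = mean(rb$p_diagonal_l1),
                mean_p_deg90_l2 = mean(rb$p_deg90_l2))
    if (has_s2) {
      w <- merge(rb[rb$session == 1L, ], rb[rb$session == 2L, ],
                 by = "participant", suffixes = c("_s1", "_s2"))
      out$cor_p_diagonal_sessions <- stats::cor(w$p_diagonal_l1_s1,
                                                w$p_diagonal_l1_s2)
      out$cor_p_deg90_sessions <- stats::cor(w$p_deg90_l2_s1,
                                             w$p_deg90_l2_s2)
    }
    report$response_bias <- out
  }

  manifest$timings$total <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  result <- structure(list(report = report, manifest = manifest,
                           fits = as.list(fits),
                           data = list(trials = trials, main_s1 = main_s1,
                                       exclusions_s1 = excl_s1,
                                       exclusions_joint = excl_joint,
                                       biases = biases, truth = truth)),
                      class = "replica_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(report = report, manifest = manifest),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(excl_s1, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    if (!is.null(biases))
      utils::write.csv(biases, file.path(out_dir, "bias.csv"),
                       row.names = FALSE)
    if (!is.null(fits$full)) {
      ie <- rbind(cbind(effect = "hysteresis",
                        individual_effect_summaries(fits$full, "r1")),
                  cbind(effect = "adaptation",
                        individual_effect_summaries(fits$full, "ar")))
      utils::write.csv(ie, file.path(out_dir, "individual_effects.csv"),
                       row.names = FALSE)
    }
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.replica_report <- function(x, ...) {
  cat("Replica analysis report\n")
  cat("  stages run:", paste(setdiff(names(x$report),
                                     c("design_counts", "exclusions")),
                             collapse = ", "), "\n")
  cat(sprintf("  total runtime: %.1f s\n", x$manifest$timings$total))
  invisible(x)
}

#' Diagnostic and summary figure files
#'
#' Writes the standard plot families as PNG files: mean logit-vs-aspect-
#' ratio curves split by first percept, forest plots of individual effects,
#' the hysteresis-adaptation scatter with HDCI bars, and the orientation-
#' bias polar plot. Panels whose inputs are missing are skipped with a
#' message.
#'
#' @param fit a full-model `percept_fit` (or NULL).
#' @param biases output of [bias_per_participant()] (or NULL).
#' @param out_dir output directory.
#' @return character vector of files written, invisibly.
#' @export
plot_suite <- function(fit = NULL, biases = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, expr) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = 900, height = 700, res = 110)
    ok <- tryCatch({ expr; TRUE },
                   error = function(e) { message("panel skipped: ",
                                                 conditionMessage(e)); FALSE })
    grDevices::dev.off()
    if (ok) written <<- c(written, path) else unlink(path)
  }
  if (!is.null(fit)) {
    emit("logit_by_ar.png", graphics::plot(fit))
    for (tm in intersect(c("r1", "ar"), fit$model$random)) {
      lbl <- if (tm == "r1") "hysteresis" else "adaptation"
      emit(paste0("forest_", lbl, ".png"), {
        s <- individual_effect_summaries(fit, tm)
        s <- s[order(s$mean), ]
        graphics::plot(s$mean, seq_len(nrow(s)), xlim = range(s$hdci_low,
                                                              s$hdci_high),
                       xlab = paste(lbl, "effect (logit)"),
                       ylab = "participant (sorted)", pch = 19,
                       main = paste("Individual", lbl, "effects"))
        graphics::segments(s$hdci_low, seq_len(nrow(s)), s$hdci_high,
                           seq_len(nrow(s)))
        graphics::abline(v = 0)
        graphics::abline(v = mean(s$mean), col = 2)
      })
    }
    if (all(c("r1", "ar") %in% fit$model$random)) {
      emit("scatter_hysteresis_adaptation.png", {
        sh <- individual_effect_summaries(fit, "r1", mass = 0.80)
        sa <- individual_effect_summaries(fit, "ar", mass = 0.80)
        graphics::plot(sh$mean, sa$mean, pch = 19,
                       xlab = "hysteresis (logit)",
                       ylab = "adaptation (logit)",
                       main = "Individual effects, 80% HDCIs")
        graphics::segments(sh$hdci_low, sa$mean, sh$hdci_high, sa$mean,
                           col = "grey60")
        graphics::segments(sh$mean, sa$hdci_low, sh$mean, sa$hdci_high,
                           col = "grey60")
        graphics::abline(h = 0, v = 0)
      })
    }
  } else message("panel skipped: no model fit supplied")
  if (!is.null(biases)) {
    emit("bias_polar.png", {
      b <- biases[stats::complete.cases(biases), ]
      ang <- 2 * b$vector_direction * pi / 180
      graphics::plot(b$vector_magnitude * cos(ang),
                     b$vector_magnitude * sin(ang),
                     xlim = c(-100, 100), ylim = c(-100, 100), pch = 19,
                     xlab = "L cos(2 theta)", ylab = "L sin(2 theta)",
                     main = "Orientation bias (doubled-angle plane)")
      graphics::symbols(0, 0, circles = 100, inches = FALSE, add = TRUE)
      graphics::abline(h = 0, v = 0, lty = 3)
    })
  } else message("panel skipped: no bias table supplied")
  invisible(written)
}
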