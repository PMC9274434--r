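#' Cross-session correlation model comparison
#'
#' Fits the joint two-session model family for one effect: the tested
#' effect's individual deviations are uncorrelated across sessions
#' (rho = 0), freely correlated (rho estimated), or fully correlated
#' (shared deviation, rho = 1 by construction, with free per-session fixed
#' effects and SDs). All other terms keep a free cross-session correlation
#' in every variant, so the models differ only in the tested effect.
#' Bayes factors come from bridge sampling; the cross-session correlation
#' is summarized from the freely-correlated model.
#'
#' @param data binary-trial data frame containing both sessions for every
#'   participant (main task).
#' @param effect `"hysteresis"` (first-percept slope), `"adaptation"`
#'   (aspect-ratio slope of the second-lattice model) or `"proximity"`
#'   (aspect-ratio slope of the first-lattice model).
#' @param sampler [sampler_config()].
#' @param priors [percept_priors()].
#' @param seed seed for the bridge proposals.
#' @param quiet suppress JAGS output.
#' @return list of class `session_comparison`: `bf_corr_vs_uncorr`,
#'   `bf_corr_vs_full` (both `bayes_factor` objects), `rho_mean`,
#'   `rho_hdci`, `fits` (the three `percept_fit`s), `effect`.
#' @export
compare_session_models <- function(data,
                                   effect = c("hysteresis", "adaptation",
                                              "proximity"),
                                   sampler = sampler_config(),
                                   priors = percept_priors(), seed = 1L,
                                   quiet = TRUE) {
  effect <- match.arg(effect)
  if (effect == "proximity") {
    outcome <- "r1"; fixed <- c("intercept", "ar"); term <- "ar"
  } else {
    outcome <- "y2"; fixed <- c("intercept", "ar", "r1")
    term <- if (effect == "hysteresis") "r1" else "ar"
  }
  variant <- function(v) {
    rho <- stats::setNames(rep("free", length(fixed)), fixed)
    rho[term] <- v
    fit_percept_model(data, fixed = fixed, random = fixed,
                      outcome = outcome, sessions = "joint",
                      session_rho = rho, priors = priors, sampler = sampler,
                      quiet = quiet)
  }
  fits <- list(uncorrelated = variant("zero"), correlated = variant("free"),
               fully_correlated = variant("one"))
  fits$uncorrelated$label <- "joint-uncorrelated"
  fits$correlated$label <- "joint-correlated"
  fits$fully_correlated$label <- "joint-fully-correlated"
  bf_cu <- bf_bridge(fits$correlated, fits$uncorrelated, seed = seed)
  bf_cf <- bf_bridge(fits$correlated, fits$fully_correlated,
                     seed = seed + 2L)
  mc <- fits$correlated
  k <- match(term, mc$model$random)
  rho_node <- sprintf("rho[%d]", which(mc$model$rho_terms == k))
  rho_draws <- mc$draws[, rho_node]
  structure(list(effect = effect, term = term,
                 bf_corr_vs_uncorr = bf_cu, bf_corr_vs_full = bf_cf,
                 rho_mean = mean(rho_draws), rho_hdci = hdci(rho_draws),
                 rho_draws = rho_draws, fits = fits),
            class = "session_comparison")
}

#' @export
print.session_comparison <- function(x, ...) {
  cat("Cross-session model comparison for the", x$effect, "effect\n")
  cat(sprintf("  log BF(correlated vs uncorrelated)     = %8.2f\n",
              x$bf_corr_vs_uncorr$log_bf))
  cat(sprintf("  log BF(correlated vs fully correlated) = %8.2f\n",
              x$bf_corr_vs_full$log_bf))
  cat(sprintf("  cross-session correlation: mean %.3f, 95%% HDCI [%.3f, %.3f]\n",
              x$rho_mean, x$rho_hdci[1], x$rho_hdci[2]))
  invisible(x)
}

#' Sequential Bayes-factor stopping rule
#'
#' Data collection starts at `n_min` participants and is evaluated after
#' every `step` additional participants: it stops when every monitored
#' Bayes factor is decisive (at or below `lower`, or at or above `upper`),
#' and unconditionally at `n_max`.
#'
#' @param bf_stream data frame with a column `n` (ordered, starting at
#'   `n_min`, in steps of `step`) and one column per monitored Bayes
#'   factor.
#' @param lower,upper decisiveness thresholds (default 1/6 and 6).
#' @param n_min,n_max,step sampling plan (defaults 30, 75, 5).
#' @return data frame `bf_stream` with a `decision` column
#'   (`"continue"`, `"stop_threshold"`, `"stop_max_n"`); the attribute
#'   `"stop"` holds the first stopping row.
#' @export
sequential_rule <- function(bf_stream, lower = 1 / 6, upper = 6,
                            n_min = 30L, n_max = 75L, step = 5L) {
  stopifnot(is.data.frame(bf_stream), "n" %in% names(bf_stream),
            ncol(bf_stream) >= 2)
  n <- bf_stream$n
  if (is.unsorted(n, strictly = TRUE))
    stop("bf_stream$n must be strictly increasing")
  if (n[1] != n_min || (length(n) > 1 && any(diff(n) != step)))
    stop("n must start at ", n_min, " and increase in steps of ", step)
  bfs <- as.matrix(bf_stream[setdiff(names(bf_stream), "n")])
  decisive <- apply(bfs <= lower | bfs >= upper, 1, all)
  decision <- ifelse(decisive, "stop_threshold",
                     ifelse(n >= n_max, "stop_max_n", "continue"))
  out <- cbind(bf_stream, decision = decision, stringsAsFactors = FALSE)
  stop_idx <- which(decision != "continue")
  attr(out, "stop") <- if (length(stop_idx)) out[min(stop_idx), ] else NULL
  out
}
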