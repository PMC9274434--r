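#' Orientation vector of axial data
#'
#' Axial circular summary of chosen orientations using doubled angles:
#' magnitude L = 100 * sqrt((sum sin 2theta)^2 + (sum cos 2theta)^2) / n
#' (percent, 0-100) and direction = atan2(sum sin 2theta, sum cos 2theta)/2
#' mapped into [0, 180). The quadrant-aware atan2 makes the direction
#' well-defined for all inputs. 90-degree responses are assumed to be
#' excluded beforehand.
#'
#' @param thetas orientations in degrees (any real values; axial, so theta
#'   and theta + 180 are equivalent).
#' @return named numeric vector `c(L, direction)`; L in percent, direction
#'   in degrees.
#' @export
orientation_vector <- function(thetas) {
  if (!length(thetas)) stop("empty orientation vector")
  s <- sum(sinpi(thetas / 90))  # sin(2 theta) in degrees
  c2 <- sum(cospi(thetas / 90))
  L <- 100 * sqrt(s^2 + c2^2) / length(thetas)
  dir <- (atan2(s, c2) / 2 * 180 / pi) %% 180
  c(L = L, direction = dir)
}

#' Per-participant orientation bias
#'
#' Drops 90-degree responses, converts each remaining response to its
#' absolute chosen orientation ((base orientation + 0/60/120) mod 180) and
#' applies [orientation_vector()] per participant and session. Participants
#' whose responses are all 90 degrees get an NA magnitude with
#' `n_trials_used = 0` (bias absent, flagged).
#'
#' @param trials trial table; orientation-task rows are used.
#' @return data frame: `participant`, `session`, `vector_magnitude` (0-100,
#'   percent), `vector_direction` (degrees in [0, 180)), `n_trials_used`.
#' @export
bias_per_participant <- function(trials) {
  validate_trials(trials)
  ori <- trials[trials$task == "orientation", , drop = FALSE]
  if (!nrow(ori)) stop("no orientation-task trials")
  offset <- c(deg0 = 0, deg60 = 60, deg120 = 120)
  key <- unique(ori[, c("participant", "session")])
  out <- key
  out$vector_magnitude <- NA_real_
  out$vector_direction <- NA_real_
  out$n_trials_used <- 0L
  for (r in seq_len(nrow(key))) {
    rows <- ori[ori$participant == key$participant[r] &
                  ori$session == key$session[r], , drop = FALSE]
    rows <- rows[rows$l2_response != "deg90", , drop = FALSE]
    if (!nrow(rows)) next
    thetas <- (rows$base_orientation + offset[rows$l2_response]) %% 180
    v <- orientation_vector(thetas)
    out$vector_magnitude[r] <- v["L"]
    out$vector_direction[r] <- v["direction"]
    out$n_trials_used[r] <- nrow(rows)
  }
  rownames(out) <- NULL
  out
}

#' Circular-circular correlation coefficient
#'
#' Jammalamadaka-SenGupta coefficient
#' sum sin(a - abar) sin(b - bbar) / sqrt(sum sin^2(a - abar) *
#' sum sin^2(b - bbar)), with the circular means abar, bbar. Axial data
#' (orientations mod 180) are doubled before computation.
#'
#' @param dirs_a,dirs_b paired directions in degrees.
#' @param axial double the angles first (default TRUE, for orientation
#'   data).
#' @return correlation coefficient in [-1, 1].
#' @export
circular_circular_correlation <- function(dirs_a, dirs_b, axial = TRUE) {
  keep <- stats::complete.cases(dirs_a, dirs_b)
  a <- dirs_a[keep]; b <- dirs_b[keep]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  mult <- if (axial) 2 else 1
  a <- mult * a * pi / 180
  b <- mult * b * pi / 180
  abar <- atan2(sum(sin(a)), sum(cos(a)))
  bbar <- atan2(sum(sin(b)), sum(cos(b)))
  num <- sum(sin(a - abar) * sin(b - bbar))
  den <- sqrt(sum(sin(a - abar)^2) * sum(sin(b - bbar)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Relation between orientation-bias strength and context effects
#'
#' Tests whether the magnitude of the absolute orientation bias correlates
#' with the size of an estimated context effect (hysteresis or adaptation)
#' across individuals: Bayesian correlation on matched participants plus a
#' one-sided Savage-Dickey Bayes factor in the hypothesized direction (the
#' opposite direction is returned as well).
#'
#' @param biases output of [bias_per_participant()] (one session).
#' @param effect_summaries output of [individual_effect_summaries()].
#' @param direction hypothesized sign of the correlation.
#' @param sampler [sampler_config()] for the correlation model.
#' @return list: `bf` (hypothesized direction), `bf_opposite`, `cor`
#'   (`bayes_cor` object), `n`.
#' @export
bias_effect_relation <- function(biases, effect_summaries,
                                 direction = c("negative", "positive"),
                                 sampler = sampler_config(chains = 2L,
                                                          iterations = 2500L,
                                                          warmup = 500L)) {
  direction <- match.arg(direction)
  mg <- merge(biases[c("participant", "vector_magnitude")],
              effect_summaries[c("participant", "mean")],
              by = "participant")
  mg <- mg[stats::complete.cases(mg), ]
  if (nrow(mg) < 10)
    warning("fewer than 10 matched participants")
  cr <- bayes_cor(mg$vector_magnitude, mg$mean, sampler = sampler)
  opposite <- if (direction == "negative") "positive" else "negative"
  list(bf = savage_dickey_onesided(cr$r_draws, direction),
       bf_opposite = savage_dickey_onesided(cr$r_draws, opposite),
       cor = cr, n = nrow(mg))
}
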