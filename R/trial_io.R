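#' Trial-table schema
#'
#' One row per trial. Columns: `participant` (character), `session` (1 or 2),
#' `task` (`"main"`, `"control"`, `"orientation"`), `block`, `trial`
#' (1-based index within block), `aspect_ratio` (main task only, NA
#' elsewhere), `base_orientation` (integer degrees; 0-89 for main/control,
#' 1-60 for the orientation task), `l1_response`
#' (`deg0`/`deg90`/`diag1`/`diag2` for main, `deg0`/`deg90`/`deg45`/`deg135`
#' for control, NA for orientation), `l2_response`
#' (`deg0`/`deg60`/`deg120`/`deg90`), `response_hand` (`"L"`/`"R"` or NA).
#'
#' @name trial_schema
#' @keywords internal
NULL

.trial_cols <- c("participant", "session", "task", "block", "trial",
                 "aspect_ratio", "base_orientation", "l1_response",
                 "l2_response", "response_hand")

.l1_levels <- list(main = c("deg0", "deg90", "diag1", "diag2"),
                   control = c("deg0", "deg90", "deg45", "deg135"))
.l2_levels <- c("deg0", "deg60", "deg120", "deg90")

#' The seven design aspect ratios
#'
#' Inter-dot distance ratios |a|/|b| used in the main task:
#' 1.3^-1, 1.2^-1, 1.1^-1, 1, 1.1, 1.2, 1.3.
#'
#' @return numeric vector of length 7, increasing.
#' @export
design_aspect_ratios <- function() {
  c(1 / 1.3, 1 / 1.2, 1 / 1.1, 1, 1.1, 1.2, 1.3)
}

validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(.trial_cols, names(trials))
  if (length(missing_cols))
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  bad_task <- which(!trials$task %in% c("main", "control", "orientation"))
  if (length(bad_task))
    stop("row ", bad_task[1], ": unknown task '", trials$task[bad_task[1]], "'")
  check <- function(idx, field) {
    if (length(idx))
      stop("row ", idx[1], ": invalid value in field '", field, "'")
  }
  check(which(!trials$session %in% c(1L, 2L)), "session")
  is_main <- trials$task == "main"
  is_ctrl <- trials$task == "control"
  is_ori <- trials$task == "orientation"
  # aspect ratio present iff main task
  check(which(is_main & is.na(trials$aspect_ratio)), "aspect_ratio")
  check(which(!is_main & !is.na(trials$aspect_ratio)), "aspect_ratio")
  check(which(is_main & trials$aspect_ratio <= 0), "aspect_ratio")
  # first-lattice response absent iff orientation task
  check(which(is_ori & !is.na(trials$l1_response)), "l1_response")
  check(which(is_main & !trials$l1_response %in% .l1_levels$main), "l1_response")
  check(which(is_ctrl & !trials$l1_response %in% .l1_levels$control), "l1_response")
  check(which(!trials$l2_response %in% .l2_levels), "l2_response")
  bo <- trials$base_orientation
  check(which(!is_ori & (is.na(bo) | bo < 0 | bo > 89)), "base_orientation")
  check(which(is_ori & (is.na(bo) | bo < 1 | bo > 60)), "base_orientation")
  check(which(is.na(trials$block) | trials$block < 1), "block")
  check(which(is.na(trials$trial) | trials$trial < 1), "trial")
  check(which(!is.na(trials$response_hand) &
                !trials$response_hand %in% c("L", "R")), "response_hand")
  invisible(trials)
}

#' Read and write trial tables
#'
#' CSV with the documented header (see [trial_schema]); UTF-8; empty string
#' for inapplicable fields. Every row is validated against the schema
#' invariants; a malformed row raises an error naming the row and field.
#'
#' @param path file path.
#' @param trials data frame in the trial schema.
#' @return `read_trials()` returns the validated trial data frame with row
#'   order preserved; `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(.trial_cols, names(raw))
  if (length(missing_cols))
    stop("CSV header is missing columns: ", paste(missing_cols, collapse = ", "))
  blank_to_na <- function(x) { x[x == ""] <- NA; x }
  num <- function(x) suppressWarnings(as.numeric(blank_to_na(x)))
  int <- function(x) suppressWarnings(as.integer(blank_to_na(x)))
  trials <- data.frame(
    participant = raw$participant,
    session = int(raw$session),
    task = raw$task,
    block = int(raw$block),
    trial = int(raw$trial),
    aspect_ratio = num(raw$aspect_ratio),
    base_orientation = int(raw$base_orientation),
    l1_response = blank_to_na(raw$l1_response),
    l2_response = blank_to_na(raw$l2_response),
    response_hand = blank_to_na(raw$response_hand),
    stringsAsFactors = FALSE
  )
  validate_trials(trials)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials[, .trial_cols]
  for (col in .trial_cols) out[[col]][is.na(out[[col]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Participant exclusions
#'
#' A participant is excluded when (a) any required session is incomplete
#' (fewer main-task trials than the designed count) or (b) the proportion of
#' diagonal first-lattice responses in the main task is strictly greater
#' than `diagonal_threshold` in any required session. A participant with no
#' main-task trials in a required session counts as incomplete.
#'
#' @param trials trial table (see [trial_schema]).
#' @param sessions_required integer vector of sessions that must be complete
#'   (default 1).
#' @param complete_n designed number of main-task trials per session
#'   (default 630 = 9 blocks of 70).
#' @param diagonal_threshold exclusion threshold on the diagonal-response
#'   proportion; exceeding it strictly excludes (default 0.40).
#' @return data frame with one row per participant: `participant`,
#'   `excluded` (logical), `reason` (`"incomplete_session"`,
#'   `"diagonal_rate_exceeded"` or `"none"`), `diagonal_rate` (the maximum
#'   across required sessions).
#' @export
apply_participant_exclusions <- function(trials, sessions_required = 1L,
                                         complete_n = 630L,
                                         diagonal_threshold = 0.40) {
  validate_trials(trials)
  ids <- unique(trials$participant)
  main <- trials[trials$task == "main", , drop = FALSE]
  out <- data.frame(participant = ids, excluded = FALSE, reason = "none",
                    diagonal_rate = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_along(ids)) {
    rates <- numeric(0)
    reason <- "none"
    for (s in sessions_required) {
      rows <- main[main$participant == ids[r] & main$session == s, , drop = FALSE]
      if (nrow(rows) < complete_n) { reason <- "incomplete_session"; break }
      rates <- c(rates, mean(rows$l1_response %in% c("diag1", "diag2")))
    }
    if (reason == "none" && length(rates) && max(rates) > diagonal_threshold)
      reason <- "diagonal_rate_exceeded"
    out$reason[r] <- reason
    out$excluded[r] <- reason != "none"
    out$diagonal_rate[r] <- if (length(rates)) max(rates) else NA_real_
  }
  out
}

#' Reduce trials to the binary modelling table
#'
#' Keeps only trials in which the first lattice was reported as 0 or 90
#' degrees and the second lattice as 0, 60 or 120 degrees (the response
#' alternatives with equal likelihood at aspect ratio 1); everything else is
#' dropped, which is the preprocessing contract, not an error. Adds the
#' centered aspect ratio (AR - 1) and the 0-degree indicators for both
#' lattices.
#'
#' @param trials trial table; main- and/or control-task rows.
#' @return data frame with columns `participant`, `session`, `task`,
#'   `centered_ar` (NA for control trials, whose first lattice is random),
#'   `r1` (1 = first lattice perceived at 0 degrees), `y2` (1 = second
#'   lattice perceived at 0 degrees).
#' @export
to_binary_trials <- function(trials) {
  validate_trials(trials)
  keep <- trials$task %in% c("main", "control") &
    trials$l1_response %in% c("deg0", "deg90") &
    trials$l2_response %in% c("deg0", "deg60", "deg120")
  t2 <- trials[keep, , drop = FALSE]
  data.frame(
    participant = t2$participant,
    session = t2$session,
    task = t2$task,
    centered_ar = t2$aspect_ratio - 1,
    r1 = as.integer(t2$l1_response == "deg0"),
    y2 = as.integer(t2$l2_response == "deg0"),
    stringsAsFactors = FALSE
  )
}

#' Empirical logits per design cell
#'
#' Observed proportion and log-odds of the 0-degree second-lattice percept
#' per group. At boundary cells (0 or n successes) a continuity constant
#' c = 0.5 is applied to both counts (p = (y + c) / (n + 2c)); interior
#' cells use the raw proportion.
#'
#' @param binary_trials output of [to_binary_trials()].
#' @param by grouping columns (default `c("centered_ar", "r1")`; add
#'   `"participant"` for per-individual curves).
#' @param outcome outcome column (default `"y2"`).
#' @param c continuity constant for boundary cells (default 0.5).
#' @return data frame of groups with `n`, `successes`, `p` and `logit`;
#'   empty groups are omitted.
#' @export
empirical_logits <- function(binary_trials, by = c("centered_ar", "r1"),
                             outcome = "y2", c = 0.5) {
  stopifnot(all(by %in% names(binary_trials)), outcome %in% names(binary_trials))
  key <- interaction(binary_trials[by], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(binary_trials)), key)
  groups <- binary_trials[vapply(idx, `[`, 1L, 1L), by, drop = FALSE]
  n <- vapply(idx, length, 1L)
  succ <- vapply(idx, function(i) sum(binary_trials[[outcome]][i]), numeric(1))
  p <- ifelse(succ == 0 | succ == n, (succ + c) / (n + 2 * c), succ / n)
  out <- cbind(groups, n = n, successes = succ, p = p, logit = log(p / (1 - p)))
  rownames(out) <- NULL
  out
}

#' Non-dominant response and left-right asymmetry summary
#'
#' Per participant and session: the probability of a diagonal first-lattice
#' response in the main task, the probability of the (unlikely) 90-degree
#' second-lattice response, and the absolute deviation from chance of
#' choosing a left-hand response option for the second lattice.
#'
#' @param trials trial table; main-task rows are used.
#' @return data frame with `participant`, `session`, `p_diagonal_l1`,
#'   `p_deg90_l2`, `left_right_asymmetry` (NA when no hand codes are
#'   recorded).
#' @export
response_bias_summary <- function(trials) {
  validate_trials(trials)
  main <- trials[trials$task == "main", , drop = FALSE]
  if (!nrow(main)) stop("no main-task trials")
  key <- unique(main[, c("participant", "session")])
  out <- key
  out$p_diagonal_l1 <- NA_real_
  out$p_deg90_l2 <- NA_real_
  out$left_right_asymmetry <- NA_real_
  for (r in seq_len(nrow(key))) {
    rows <- main[main$participant == key$participant[r] &
                   main$session == key$session[r], , drop = FALSE]
    out$p_diagonal_l1[r] <- mean(rows$l1_response %in% c("diag1", "diag2"))
    out$p_deg90_l2[r] <- mean(rows$l2_response == "deg90")
    hands <- rows$response_hand[!is.na(rows$response_hand)]
    if (length(hands))
      out$left_right_asymmetry[r] <- abs(mean(hands == "L") - 0.5)
  }
  rownames(out) <- NULL
  out
}
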