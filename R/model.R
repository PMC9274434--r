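#' Prior configuration for the percept models
#'
#' Zero-centered weakly-informative priors: Normal(0, scale_fixed) on fixed
#' effects (truncated at zero when a sign constraint is requested),
#' half-Student-t(df_sd, scale_sd) on random-effect SDs, and independent
#' Uniform(-1, 1) priors on the partial-correlation coordinates of the
#' random-effect correlation matrix (C-vine Cholesky parameterization) and
#' on cross-session correlations.
#'
#' @param scale_fixed SD of the normal prior on fixed effects (logit units).
#' @param scale_sd scale of the half-t prior on random-effect SDs.
#' @param df_sd degrees of freedom of the half-t prior.
#' @return list of class `percept_priors`.
#' @export
percept_priors <- function(scale_fixed = 2.5, scale_sd = 2.5, df_sd = 3) {
  stopifnot(scale_fixed > 0, scale_sd > 0, df_sd > 0)
  structure(list(scale_fixed = scale_fixed, scale_sd = scale_sd,
                 df_sd = df_sd), class = "percept_priors")
}

#' Sampler configuration
#'
#' JAGS settings. The replication-scale configuration of the original
#' analyses corresponds to `sampler_config(chains = 4, iterations = 20000,
#' warmup = 10000)`; the default here is scaled down for desk-scale runs.
#'
#' @param chains number of chains.
#' @param iterations kept iterations per chain (after warmup).
#' @param warmup adaptation plus burn-in iterations per chain.
#' @param seed integer seed; chain c uses `seed + c`.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, iterations = 1500L, warmup = 1000L,
                           seed = 1L) {
  stopifnot(iterations > 0, warmup >= 0, chains >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "sampler_config")
}

.all_terms <- c("intercept", "ar", "r1", "ar_r1")

#' Named model variants
#'
#' Shorthand for the model family used in the comparisons: for the
#' second-lattice percept, `"full"` (fixed and random intercept, aspect
#' ratio, first-lattice percept), `"no-hyst"` / `"no-adapt"` (the predictor
#' removed entirely), `"common-hyst"` / `"common-adapt"` (fixed effect kept,
#' random slope removed: everyone shares one effect), `"interaction"` (adds
#' the aspect-ratio-by-percept interaction), `"positive"` (full model with
#' the population hysteresis and adaptation means constrained positive).
#' For the first-lattice percept (proximity model, outcome `r1`):
#' `"l1-full"`, `"l1-common"`, `"l1-negative"`. For the control task (no
#' aspect ratio): `"control-full"`, `"control-null"`.
#'
#' @param model variant name.
#' @return list with `outcome`, `fixed`, `random`, `constraint`.
#' @export
percept_model_spec <- function(model) {
  specs <- list(
    "full" = list(outcome = "y2", fixed = c("intercept", "ar", "r1"),
                  random = c("intercept", "ar", "r1"), constraint = NULL),
    "no-hyst" = list(outcome = "y2", fixed = c("intercept", "ar"),
                     random = c("intercept", "ar"), constraint = NULL),
    "no-adapt" = list(outcome = "y2", fixed = c("intercept", "r1"),
                      random = c("intercept", "r1"), constraint = NULL),
    "common-hyst" = list(outcome = "y2", fixed = c("intercept", "ar", "r1"),
                         random = c("intercept", "ar"), constraint = NULL),
    "common-adapt" = list(outcome = "y2", fixed = c("intercept", "ar", "r1"),
                          random = c("intercept", "r1"), constraint = NULL),
    "interaction" = list(outcome = "y2",
                         fixed = c("intercept", "ar", "r1", "ar_r1"),
                         random = c("intercept", "ar", "r1", "ar_r1"),
                         constraint = NULL),
    "positive" = list(outcome = "y2", fixed = c("intercept", "ar", "r1"),
                      random = c("intercept", "ar", "r1"),
                      constraint = c(ar = "positive", r1 = "positive")),
    "l1-full" = list(outcome = "r1", fixed = c("intercept", "ar"),
                     random = c("intercept", "ar"), constraint = NULL),
    "l1-common" = list(outcome = "r1", fixed = c("intercept", "ar"),
                       random = "intercept", constraint = NULL),
    "l1-negative" = list(outcome = "r1", fixed = c("intercept", "ar"),
                         random = c("intercept", "ar"),
                         constraint = c(ar = "negative")),
    "control-full" = list(outcome = "y2", fixed = c("intercept", "r1"),
                          random = c("intercept", "r1"), constraint = NULL),
    "control-null" = list(outcome = "y2", fixed = "intercept",
                          random = "intercept", constraint = NULL)
  )
  if (!model %in% names(specs)) stop("unknown model variant: ", model)
  specs[[model]]
}

# collapse binary trials to binomial cells for one outcome
.make_cells <- function(data, outcome, fixed) {
  stopifnot(nrow(data) > 0)
  car <- data$centered_ar
  if ("ar" %in% fixed && anyNA(car))
    stop("model includes the aspect-ratio term but centered_ar has NAs ",
         "(control-task data carry no aspect ratio)")
  if (!"ar" %in% fixed) car <- rep(0, nrow(data))
  r1 <- if (outcome == "r1") rep(0L, nrow(data)) else data$r1
  key <- paste(data$participant, data$session, car, r1, sep = "\r")
  idx <- split(seq_len(nrow(data)), key)
  first <- vapply(idx, `[`, 1L, 1L)
  cells <- data.frame(
    participant = data$participant[first],
    session = data$session[first],
    centered_ar = car[first],
    r1 = r1[first],
    n = vapply(idx, length, 1L),
    y = vapply(idx, function(i) sum(data[[outcome]][i]), numeric(1)),
    stringsAsFactors = FALSE)
  cells <- cells[order(cells$participant, cells$session, cells$centered_ar,
                       cells$r1), ]
  rownames(cells) <- NULL
  cells
}

.term_x <- function(cells, term) {
  switch(term,
         intercept = rep(1, nrow(cells)),
         ar = cells$centered_ar,
         r1 = as.numeric(cells$r1),
         ar_r1 = cells$centered_ar * cells$r1,
         stop("unknown term: ", term))
}

# u-coordinate count for a K-dimensional vine Cholesky
.n_u <- function(K) K * (K - 1L) / 2L

# lower-triangular Cholesky factor rows from vine coordinates; u is a list
# of N-vectors (or scalars); returns L[[k]][[j]] as vectors
.vine_L <- function(u, K) {
  L <- vector("list", K)
  m <- 0L
  for (k in seq_len(K)) {
    L[[k]] <- vector("list", k)
    if (k == 1L) { L[[1]][[1]] <- 1; next }
    rem <- 1
    for (j in seq_len(k - 1L)) {
      m <- m + 1L
      L[[k]][[j]] <- u[[m]] * sqrt(rem)
      rem <- rem * (1 - u[[m]]^2)
    }
    L[[k]][[k]] <- sqrt(rem)
  }
  L
}

# JAGS code lines for b[i, k] under the vine parameterization
.jags_vine_lines <- function(K) {
  lines <- character(0)
  if (K >= 2) {
    m <- 0L
    for (k in 2:K) {
      rem <- "1"
      for (j in seq_len(k - 1L)) {
        m <- m + 1L
        lines <- c(lines, sprintf("  Lr[%d,%d] <- u[%d] * sqrt(%s)",
                                  k, j, m, rem))
        rem <- sprintf("%s * (1 - u[%d]^2)", rem, m)
      }
      lines <- c(lines, sprintf("  Lr[%d,%d] <- sqrt(%s)", k, k, rem))
    }
  }
  lines
}

#' Build a hierarchical percept model
#'
#' Constructs the Bayesian multilevel binomial-logit model of a lattice
#' percept: the Bernoulli trial outcomes are collapsed to binomial counts
#' per (participant, session, centered aspect ratio, first-percept) cell,
#' which leaves every likelihood ratio between model variants unchanged.
#' Individual deviations are parameterized non-centrally
#' (deviation = diag(sigma) L z with standard-normal z and L the Cholesky
#' factor of the random-effect correlation matrix). The returned object
#' carries the JAGS model code and an R-side log joint density on
#' unconstrained parameters (used for bridge sampling) that matches the
#' JAGS model exactly.
#'
#' @param data binary-trial data frame (see [to_binary_trials()]).
#' @param fixed fixed-effect terms, subset of
#'   `c("intercept", "ar", "r1", "ar_r1")`.
#' @param random random (per-participant) terms; must be a subset of
#'   `fixed`.
#' @param outcome `"y2"` (second-lattice percept) or `"r1"` (first-lattice
#'   percept, the proximity model).
#' @param constraint named character vector mapping fixed terms to
#'   `"positive"` or `"negative"`; constrains the population mean only
#'   (truncated-normal prior), individual deviations stay unconstrained.
#' @param sessions `"single"` (all rows one session family) or `"joint"`
#'   (two sessions, per-session fixed effects and SDs, per-term
#'   cross-session correlation of individual deviations).
#' @param session_rho for joint models: named vector/list mapping each
#'   random term to `"free"`, `"zero"` or `"one"` (default all `"free"`).
#' @param priors [percept_priors()].
#' @return object of class `percept_model`.
#' @export
build_percept_model <- function(data, fixed = c("intercept", "ar", "r1"),
                                random = fixed, outcome = "y2",
                                constraint = NULL, sessions = "single",
                                session_rho = NULL,
                                priors = percept_priors()) {
  stopifnot(outcome %in% c("y2", "r1"), sessions %in% c("single", "joint"))
  fixed <- match.arg(fixed, .all_terms, several.ok = TRUE)
  if (length(random)) random <- match.arg(random, .all_terms, several.ok = TRUE)
  if (!all(random %in% fixed))
    stop("random terms must be a subset of fixed terms: ",
         paste(setdiff(random, fixed), collapse = ", "))
  if (!is.null(constraint)) {
    if (!all(names(constraint) %in% fixed))
      stop("sign constraint on a term not in the model: ",
           paste(setdiff(names(constraint), fixed), collapse = ", "))
    stopifnot(all(constraint %in% c("positive", "negative")))
  }
  cells <- .make_cells(data, outcome, fixed)
  pid_levels <- sort(unique(cells$participant))
  I <- length(pid_levels)
  pid <- match(cells$participant, pid_levels)
  if (sessions == "joint") {
    sess_levels <- sort(unique(cells$session))
    if (length(sess_levels) != 2)
      stop("joint models need exactly two sessions; found ",
           length(sess_levels))
    both <- tapply(cells$session, cells$participant,
                   function(s) length(unique(s)))
    if (any(both < 2))
      stop("participant missing a session: ",
           paste(names(both)[both < 2], collapse = ", "))
    sess <- match(cells$session, sess_levels)
    if (is.null(session_rho))
      session_rho <- stats::setNames(rep("free", length(random)), random)
    session_rho <- unlist(session_rho)[random]
    if (anyNA(session_rho) || !all(session_rho %in% c("free", "zero", "one")))
      stop("session_rho must map every random term to free/zero/one")
  } else {
    sess <- rep(1L, nrow(cells))
    session_rho <- NULL
  }
  S <- if (sessions == "joint") 2L else 1L
  K <- length(random)

  # fixed-effect design matrix, one column per (term, session)
  fix_names <- if (S == 2L) as.vector(outer(fixed, 1:2, paste, sep = ".s"))
               else fixed
  X <- matrix(0, nrow(cells), length(fix_names),
              dimnames = list(NULL, fix_names))
  for (f in seq_along(fixed)) {
    x <- .term_x(cells, fixed[f])
    if (S == 2L) {
      X[, f] <- x * (sess == 1L)
      X[, length(fixed) + f] <- x * (sess == 2L)
    } else X[, f] <- x
  }
  fix_constraint <- rep("none", length(fix_names))
  if (!is.null(constraint)) {
    for (t in names(constraint)) {
      hit <- if (S == 2L) paste0(t, ".s", 1:2) else t
      fix_constraint[fix_names %in% hit] <- constraint[[t]]
    }
  }
  # random design columns per (term, session)
  Xr <- lapply(random, function(t) .term_x(cells, t))

  # z layout: single session K columns; joint: per term 2 ("free"/"zero")
  # or 1 ("one") columns
  if (S == 1L) {
    zcols <- as.list(seq_len(K))
  } else {
    zcols <- vector("list", K)
    nz <- 0L
    for (k in seq_len(K)) {
      w <- if (session_rho[k] == "one") 1L else 2L
      zcols[[k]] <- nz + seq_len(w)
      nz <- nz + w
    }
  }
  nzc <- if (K) max(unlist(zcols)) else 0L
  n_sigma <- K * S
  n_u <- if (S == 1L) .n_u(K) else 0L
  rho_terms <- if (S == 2L) which(session_rho == "free") else integer(0)

  obj <- list(fixed = fixed, random = random, outcome = outcome,
              sessions = sessions, session_rho = session_rho,
              constraint = constraint, priors = priors, cells = cells,
              pid = pid, sess = sess, pid_levels = pid_levels, I = I,
              K = K, S = S, X = X, Xr = Xr, fix_names = fix_names,
              fix_constraint = fix_constraint, zcols = zcols, nzc = nzc,
              n_sigma = n_sigma, n_u = n_u, rho_terms = rho_terms,
              data_fingerprint = .data_fingerprint(data))
  obj$jags_code <- .jags_code(obj)
  class(obj) <- "percept_model"
  obj
}

# fingerprint of the trial rows a model was fitted on (model-independent)
.data_fingerprint <- function(data) {
  car <- data$centered_ar
  car[is.na(car)] <- 0
  paste(nrow(data), length(unique(data$participant)),
        sum(data$y2 %||% 0), sum(data$r1), signif(sum(car), 10), sep = "|")
}

# generate the JAGS model string
.jags_code <- function(m) {
  pri <- m$priors
  tau_f <- sprintf("%.10g", 1 / pri$scale_fixed^2)
  tau_s <- sprintf("%.10g", 1 / pri$scale_sd^2)
  eta <- "beta[1] * X[c,1]"
  if (ncol(m$X) > 1)
    for (f in 2:ncol(m$X)) eta <- paste0(eta, sprintf(" + beta[%d] * X[c,%d]", f, f))
  if (m$K) {
    if (m$S == 1L) {
      for (k in seq_len(m$K))
        eta <- paste0(eta, sprintf(" + b[pid[c],%d] * Xr%d[c]", k, k))
    } else {
      for (k in seq_len(m$K))
        eta <- paste0(eta, sprintf(
          " + b1[pid[c],%d] * Xr%d1[c] + b2[pid[c],%d] * Xr%d2[c]",
          k, k, k, k))
    }
  }
  lines <- c("model {",
             "  for (c in 1:C) {",
             paste0("    logit(p[c]) <- ", eta),
             "    y[c] ~ dbin(p[c], n[c])",
             "  }")
  if (m$K) {
    lines <- c(lines, "  for (i in 1:I) {",
               sprintf("    for (j in 1:%d) { z[i,j] ~ dnorm(0, 1) }", m$nzc))
    if (m$S == 1L) {
      for (k in seq_len(m$K)) {
        terms <- sprintf("Lr[%d,%d] * z[i,%d]", k, seq_len(k), seq_len(k))
        lines <- c(lines, sprintf("    b[i,%d] <- sigma[%d] * (%s)", k, k,
                                  paste(terms, collapse = " + ")))
      }
    } else {
      for (k in seq_len(m$K)) {
        zc <- m$zcols[[k]]
        v <- m$session_rho[k]
        lines <- c(lines, sprintf("    b1[i,%d] <- sigma[%d] * z[i,%d]",
                                  k, k, zc[1]))
        b2 <- switch(v,
          free = sprintf(
            "    b2[i,%d] <- sigma[%d] * (rho[%d] * z[i,%d] + sqrt(1 - rho[%d]^2) * z[i,%d])",
            k, m$K + k, which(m$rho_terms == k), zc[1],
            which(m$rho_terms == k), zc[2]),
          zero = sprintf("    b2[i,%d] <- sigma[%d] * z[i,%d]",
                         k, m$K + k, zc[2]),
          one = sprintf("    b2[i,%d] <- sigma[%d] * z[i,%d]",
                        k, m$K + k, zc[1]))
        lines <- c(lines, b2)
      }
    }
    lines <- c(lines, "  }")
    if (m$S == 1L && m$K >= 2) {
      lines <- c(lines, "  Lr[1,1] <- 1", .jags_vine_lines(m$K))
    } else if (m$S == 1L) {
      lines <- c(lines, "  Lr[1,1] <- 1")
    }
    for (s in seq_len(m$n_sigma))
      lines <- c(lines, sprintf("  sigma[%d] ~ dt(0, %s, %d) T(0,)",
                                s, tau_s, pri$df_sd))
    if (m$n_u)
      for (j in seq_len(m$n_u))
        lines <- c(lines, sprintf("  u[%d] ~ dunif(-1, 1)", j))
    if (length(m$rho_terms))
      for (j in seq_along(m$rho_terms))
        lines <- c(lines, sprintf("  rho[%d] ~ dunif(-1, 1)", j))
  }
  for (f in seq_along(m$fix_names)) {
    trunc <- switch(m$fix_constraint[f], none = "", positive = " T(0,)",
                    negative = " T(,0)")
    lines <- c(lines, sprintf("  beta[%d] ~ dnorm(0, %s)%s", f, tau_f, trunc))
  }
  paste(c(lines, "}"), collapse = "\n")
}

# ---- unconstrained parameter layout ------------------------------------

# ordered JAGS node names matching the theta layout
.param_nodes <- function(m) {
  nodes <- sprintf("beta[%d]", seq_along(m$fix_names))
  if (m$K) {
    nodes <- c(nodes, sprintf("sigma[%d]", seq_len(m$n_sigma)))
    if (m$n_u) nodes <- c(nodes, sprintf("u[%d]", seq_len(m$n_u)))
    if (length(m$rho_terms))
      nodes <- c(nodes, sprintf("rho[%d]", seq_along(m$rho_terms)))
    nodes <- c(nodes, as.vector(outer(seq_len(m$I), seq_len(m$nzc),
                                      function(i, j) sprintf("z[%d,%d]", i, j))))
  }
  nodes
}

# forward transform posterior draws (matrix in node order) to unconstrained
.to_unconstrained <- function(m, draws) {
  theta <- draws
  F <- length(m$fix_names)
  for (f in seq_len(F)) {
    if (m$fix_constraint[f] == "positive") theta[, f] <- log(draws[, f])
    if (m$fix_constraint[f] == "negative") theta[, f] <- log(-draws[, f])
  }
  if (m$K) {
    sig <- F + seq_len(m$n_sigma)
    theta[, sig] <- log(draws[, sig, drop = FALSE])
    nuv <- m$n_u + length(m$rho_terms)
    if (nuv) {
      uv <- F + m$n_sigma + seq_len(nuv)
      theta[, uv] <- atanh(draws[, uv, drop = FALSE])
    }
  }
  theta
}

# log joint density (likelihood + priors + Jacobian) on unconstrained theta;
# theta is a matrix with rows = draws; returns a vector
.make_lp <- function(m) {
  F <- length(m$fix_names)
  pri <- m$priors
  X <- m$X
  y <- m$cells$y
  n <- m$cells$n
  pid <- m$pid
  # Bernoulli-trials convention: no binomial coefficient, so the evidence
  # is invariant to how trials are collapsed into cells and model variants
  # with different cell granularities remain comparable
  half_norm_const <- -stats::pnorm(0, lower.tail = TRUE, log.p = TRUE)  # log 2
  sig_idx <- F + seq_len(m$n_sigma)
  u_idx <- if (m$n_u) F + m$n_sigma + seq_len(m$n_u) else integer(0)
  rho_idx <- if (length(m$rho_terms))
    F + m$n_sigma + m$n_u + seq_along(m$rho_terms) else integer(0)
  z_off <- F + m$n_sigma + m$n_u + length(m$rho_terms)
  I <- m$I

  function(theta) {
    if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
    out <- numeric(nrow(theta))
    chunks <- split(seq_len(nrow(theta)),
                    ceiling(seq_len(nrow(theta)) / 400))
    for (ch in chunks) {
      th <- theta[ch, , drop = FALSE]
      N <- nrow(th)
      lp <- numeric(N)
      beta <- th[, seq_len(F), drop = FALSE]
      for (f in seq_len(F)) {
        cns <- m$fix_constraint[f]
        if (cns == "none") {
          lp <- lp + stats::dnorm(beta[, f], 0, pri$scale_fixed, log = TRUE)
        } else {
          val <- exp(th[, f])
          beta[, f] <- if (cns == "positive") val else -val
          lp <- lp + log(2) +
            stats::dnorm(val, 0, pri$scale_fixed, log = TRUE) + th[, f]
        }
      }
      if (m$K) {
        sig <- exp(th[, sig_idx, drop = FALSE])
        lp <- lp + rowSums(log(2) +
                             stats::dt(sig / pri$scale_sd, pri$df_sd,
                                       log = TRUE) - log(pri$scale_sd) +
                             th[, sig_idx, drop = FALSE])
        if (length(u_idx) || length(rho_idx)) {
          uv <- th[, c(u_idx, rho_idx), drop = FALSE]
          x <- tanh(uv)
          lp <- lp + rowSums(-log(2) + log1p(-x^2))
        }
        u <- if (length(u_idx)) tanh(th[, u_idx, drop = FALSE]) else NULL
        rho <- if (length(rho_idx)) tanh(th[, rho_idx, drop = FALSE]) else NULL
        zmat <- th[, z_off + seq_len(I * m$nzc), drop = FALSE]
        lp <- lp + rowSums(stats::dnorm(zmat, log = TRUE))
      }
      eta <- beta %*% t(X)
      if (m$K) {
        zcol <- function(j) zmat[, (j - 1L) * I + seq_len(I), drop = FALSE]
        if (m$S == 1L) {
          ulist <- if (m$n_u) lapply(seq_len(m$n_u), function(j) u[, j])
                   else list()
          L <- .vine_L(ulist, m$K)
          for (k in seq_len(m$K)) {
            acc <- 0
            for (j in seq_len(k)) acc <- acc + L[[k]][[j]] * zcol(j)
            b_k <- sig[, k] * acc
            eta <- eta + b_k[, pid, drop = FALSE] *
              rep(m$Xr[[k]], each = nrow(th))
          }
        } else {
          x1 <- (m$sess == 1L)
          for (k in seq_len(m$K)) {
            zc <- m$zcols[[k]]
            v <- m$session_rho[k]
            b1 <- sig[, k] * zcol(zc[1])
            b2 <- switch(v,
              free = {
                r <- rho[, which(m$rho_terms == k)]
                sig[, m$K + k] * (r * zcol(zc[1]) +
                                    sqrt(1 - r^2) * zcol(zc[2]))
              },
              zero = sig[, m$K + k] * zcol(zc[2]),
              one = sig[, m$K + k] * zcol(zc[1]))
            eta <- eta + b1[, pid, drop = FALSE] *
              rep(m$Xr[[k]] * x1, each = nrow(th)) +
              b2[, pid, drop = FALSE] *
              rep(m$Xr[[k]] * !x1, each = nrow(th))
          }
        }
      }
      # stable binomial log-likelihood: y*eta - n*log(1 + exp(eta))
      softplus <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
      ll <- eta %*% matrix(y) - softplus %*% matrix(n)
      out[ch] <- lp + as.vector(ll)
    }
    out
  }
}
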