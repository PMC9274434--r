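#' Fit a hierarchical percept model
#'
#' Fits the Bayesian multilevel logistic model of lattice percepts with
#' JAGS. Either name a `model` variant (see [percept_model_spec()]) or pass
#' the term sets explicitly. Returns a `percept_fit` object with
#' `print()`, `summary()`, `coef()`, `predict()`, `plot()`, `simulate()`
#' and `residuals()` methods.
#'
#' @param data binary-trial data frame from [to_binary_trials()].
#' @param model variant name (ignored when `fixed` is given).
#' @param fixed,random,outcome,constraint,sessions,session_rho,priors passed
#'   to [build_percept_model()].
#' @param sampler [sampler_config()].
#' @param quiet suppress JAGS progress output.
#' @return object of class `percept_fit`: the built model, the posterior
#'   draws (raw and unconstrained), and convergence diagnostics
#'   (split R-hat and bulk effective sample size per parameter; the fit is
#'   flagged unreliable when any split R-hat exceeds 1.01 or any top-level
#'   bulk ESS falls below 400).
#' @export
fit_percept_model <- function(data, model = "full", fixed = NULL,
                              random = NULL, outcome = NULL,
                              constraint = NULL, sessions = "single",
                              session_rho = NULL, priors = percept_priors(),
                              sampler = sampler_config(), quiet = TRUE) {
  if (is.null(fixed)) {
    sp <- percept_model_spec(model)
    fixed <- sp$fixed
    if (is.null(random)) random <- sp$random
    if (is.null(outcome)) outcome <- sp$outcome
    if (is.null(constraint)) constraint <- sp$constraint
  } else {
    if (is.null(random)) random <- fixed
    if (is.null(outcome)) outcome <- "y2"
    model <- "custom"
  }
  m <- build_percept_model(data, fixed = fixed, random = random,
                           outcome = outcome, constraint = constraint,
                           sessions = sessions, session_rho = session_rho,
                           priors = priors)
  fit_model(m, sampler, label = model, quiet = quiet)
}

#' @rdname fit_percept_model
#' @param m a `percept_model` from [build_percept_model()].
#' @param label model label stored on the fit.
#' @export
fit_model <- function(m, sampler = sampler_config(), label = "custom",
                      quiet = TRUE) {
  stopifnot(inherits(m, "percept_model"))
  t0 <- Sys.time()
  jd <- list(C = nrow(m$cells), y = m$cells$y, n = m$cells$n, X = m$X)
  if (m$K) {
    jd$I <- m$I
    jd$pid <- m$pid
    if (m$S == 1L) {
      for (k in seq_len(m$K)) jd[[sprintf("Xr%d", k)]] <- m$Xr[[k]]
    } else {
      for (k in seq_len(m$K)) {
        jd[[sprintf("Xr%d1", k)]] <- m$Xr[[k]] * (m$sess == 1L)
        jd[[sprintf("Xr%d2", k)]] <- m$Xr[[k]] * (m$sess == 2L)
      }
    }
  }
  beta0 <- ifelse(m$fix_constraint == "positive", 0.5,
                  ifelse(m$fix_constraint == "negative", -0.5, 0))
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    ini <- list(beta = beta0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = sampler$seed + ch)
    if (m$K) {
      ini$z <- matrix(0, m$I, m$nzc)
      ini$sigma <- rep(0.5, m$n_sigma)
      if (m$n_u) ini$u <- rep(0, m$n_u)
      if (length(m$rho_terms)) ini$rho <- rep(0, length(m$rho_terms))
    }
    ini
  })
  n_adapt <- max(100L, m$S * 100L, floor(sampler$warmup / 2))
  jm <- rjags::jags.model(textConnection(m$jags_code), data = jd,
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = n_adapt, quiet = quiet)
  burn <- max(0L, sampler$warmup - n_adapt)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  monitors <- "beta"
  if (m$K) {
    monitors <- c(monitors, "sigma", "z")
    if (m$n_u) monitors <- c(monitors, "u")
    if (length(m$rho_terms)) monitors <- c(monitors, "rho")
  }
  samp <- rjags::coda.samples(jm, monitors, n.iter = sampler$iterations,
                              progress.bar = "none")
  nodes <- .param_nodes(m)
  per_chain <- lapply(samp, function(s) {
    cm <- as.matrix(s)
    cn <- colnames(cm)
    # coda drops the index on length-1 arrays
    for (v in c("beta", "sigma", "u", "rho"))
      cn[cn == v] <- paste0(v, "[1]")
    cn[cn == "z"] <- "z[1,1]"
    colnames(cm) <- cn
    cm[, nodes, drop = FALSE]
  })
  draws <- do.call(rbind, per_chain)
  theta <- .to_unconstrained(m, draws)
  top <- nodes[!startsWith(nodes, "z[")]
  rhat <- vapply(seq_along(nodes), function(j)
    split_rhat(lapply(per_chain, function(pc) pc[, j])), numeric(1))
  names(rhat) <- nodes
  ess <- vapply(top, function(nd)
    sum(vapply(per_chain, function(pc)
      unname(coda::effectiveSize(coda::mcmc(pc[, nd]))), numeric(1))),
    numeric(1))
  diagnostics <- list(
    rhat = rhat, ess = ess,
    max_rhat = max(rhat, na.rm = TRUE), min_ess = min(ess),
    reliable = max(rhat, na.rm = TRUE) <= 1.01 && min(ess) >= 400)
  structure(list(model = m, label = label, draws = draws, theta = theta,
                 chains = sampler$chains, sampler = sampler,
                 diagnostics = diagnostics, lp = .make_lp(m),
                 runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "percept_fit")
}

# posterior draws (rows) of the individual total effect of a term, N x I
#' Posterior draws of individual total effects
#'
#' Individual total effect = population fixed effect + individual deviation.
#' For a common-effects term (no random slope) every participant shares the
#' fixed-effect draws.
#'
#' @param fit `percept_fit`.
#' @param term one of the model's fixed terms.
#' @param session 1 or 2 (joint fits only).
#' @return matrix draws x participants, columns named by participant id.
#' @export
individual_draws <- function(fit, term, session = 1L) {
  m <- fit$model
  if (!term %in% m$fixed) stop("term '", term, "' is not in the model")
  F <- length(m$fix_names)
  fcol <- if (m$S == 2L) paste0(term, ".s", session) else term
  beta <- fit$draws[, sprintf("beta[%d]", match(fcol, m$fix_names))]
  N <- length(beta)
  tot <- matrix(beta, N, m$I)
  colnames(tot) <- m$pid_levels
  k <- match(term, m$random)
  if (is.na(k)) return(tot)
  sig_i <- if (m$S == 2L && session == 2L) m$K + k else k
  sig <- fit$draws[, sprintf("sigma[%d]", sig_i)]
  zc <- function(j) fit$draws[, sprintf("z[%d,%d]", seq_len(m$I), j),
                              drop = FALSE]
  if (m$S == 1L) {
    u <- if (m$n_u) lapply(seq_len(m$n_u), function(j)
      fit$draws[, sprintf("u[%d]", j)]) else list()
    L <- .vine_L(u, m$K)
    acc <- 0
    for (j in seq_len(k)) acc <- acc + L[[k]][[j]] * zc(j)
    tot + sig * acc
  } else {
    cols <- m$zcols[[k]]
    v <- m$session_rho[k]
    dev <- if (session == 1L) zc(cols[1])
    else switch(v,
                free = {
                  r <- fit$draws[, sprintf("rho[%d]", which(m$rho_terms == k))]
                  r * zc(cols[1]) + sqrt(1 - r^2) * zc(cols[2])
                },
                zero = zc(cols[2]),
                one = zc(cols[1]))
    tot + sig * dev
  }
}

#' Summaries of individual effects
#'
#' Posterior mean and highest density continuous interval of each
#' participant's total effect (fixed + individual deviation).
#'
#' @param fit `percept_fit`.
#' @param term model term to summarize.
#' @param mass HDCI mass (default 0.95; 0.80 is used for scatter displays).
#' @param session session for joint fits.
#' @return data frame: `participant`, `mean`, `hdci_low`, `hdci_high`.
#' @export
individual_effect_summaries <- function(fit, term, mass = 0.95,
                                        session = 1L) {
  tot <- individual_draws(fit, term, session)
  hd <- apply(tot, 2, hdci, mass = mass)
  data.frame(participant = colnames(tot), mean = colMeans(tot),
             hdci_low = hd[1, ], hdci_high = hd[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Prior draws of individual total effects
#'
#' Forward simulation from the model's prior: fixed effect from its
#' (possibly truncated) normal prior, SD from the half-t prior, correlation
#' coordinates uniform, individual deviations standard normal. Used as the
#' denominator sample of the encompassing Bayes factor.
#'
#' @param fit `percept_fit` (or `percept_model`).
#' @param term model term.
#' @param ndraws number of prior draws.
#' @param seed integer seed.
#' @param session session for joint models.
#' @return matrix ndraws x participants.
#' @export
prior_individual_draws <- function(fit, term, ndraws = 10000L, seed = 1L,
                                   session = 1L) {
  m <- if (inherits(fit, "percept_fit")) fit$model else fit
  if (!term %in% m$fixed) stop("term '", term, "' is not in the model")
  pri <- m$priors
  with_seed(seed, {
    fcol <- if (m$S == 2L) paste0(term, ".s", session) else term
    cns <- m$fix_constraint[match(fcol, m$fix_names)]
    beta <- stats::rnorm(ndraws, 0, pri$scale_fixed)
    if (cns == "positive") beta <- abs(beta)
    if (cns == "negative") beta <- -abs(beta)
    tot <- matrix(beta, ndraws, m$I)
    colnames(tot) <- m$pid_levels
    k <- match(term, m$random)
    if (is.na(k)) return(tot)
    sig <- pri$scale_sd * abs(stats::rt(ndraws, pri$df_sd))
    # the individual deviation is marginally sigma * standard normal for
    # every parameterization used here (rows of L have unit norm)
    dev <- matrix(stats::rnorm(ndraws * m$I), ndraws, m$I)
    tot + sig * dev
  })
}

#' @export
print.percept_fit <- function(x, ...) {
  m <- x$model
  cat("Hierarchical percept model fit (", x$label, ")\n", sep = "")
  cat("  outcome:", m$outcome, "| sessions:", m$sessions, "\n")
  cat("  fixed terms: ", paste(m$fix_names, collapse = ", "), "\n")
  cat("  random terms:", if (m$K) paste(m$random, collapse = ", ")
      else "(none)", "\n")
  cat("  participants:", m$I, "| cells:", nrow(m$cells),
      "| trials:", sum(m$cells$n), "\n")
  cat(sprintf("  draws: %d chains x %d | max split-Rhat %.3f | min ESS %.0f%s\n",
              x$chains, nrow(x$draws) / x$chains, x$diagnostics$max_rhat,
              x$diagnostics$min_ess,
              if (x$diagnostics$reliable) "" else " [flagged unreliable]"))
  print(stats::coef(x))
  invisible(x)
}

#' @export
coef.percept_fit <- function(object, ...) {
  m <- object$model
  b <- colMeans(object$draws[, sprintf("beta[%d]", seq_along(m$fix_names)),
                             drop = FALSE])
  stats::setNames(b, m$fix_names)
}

#' @export
summary.percept_fit <- function(object, mass = 0.95, ...) {
  m <- object$model
  rows <- function(nodes, names) {
    d <- object$draws[, nodes, drop = FALSE]
    hd <- apply(d, 2, hdci, mass = mass)
    data.frame(parameter = names, mean = colMeans(d),
               sd = apply(d, 2, stats::sd), hdci_low = hd[1, ],
               hdci_high = hd[2, ], row.names = NULL)
  }
  out <- rows(sprintf("beta[%d]", seq_along(m$fix_names)),
              paste0("b_", m$fix_names))
  if (m$K) {
    sig_names <- if (m$S == 2L)
      paste0("sd_", rep(m$random, 2), ".s", rep(1:2, each = m$K))
    else paste0("sd_", m$random)
    out <- rbind(out, rows(sprintf("sigma[%d]", seq_len(m$n_sigma)),
                           sig_names))
    if (m$S == 1L && m$K >= 2) {
      cors <- .correlation_draws(object)
      hd <- apply(cors, 2, hdci, mass = mass)
      out <- rbind(out, data.frame(
        parameter = colnames(cors), mean = colMeans(cors),
        sd = apply(cors, 2, stats::sd), hdci_low = hd[1, ],
        hdci_high = hd[2, ], row.names = NULL))
    }
    if (length(m$rho_terms))
      out <- rbind(out, rows(sprintf("rho[%d]", seq_along(m$rho_terms)),
                             paste0("rho_session_", m$random[m$rho_terms])))
  }
  structure(out, class = c("summary.percept_fit", "data.frame"),
            diagnostics = object$diagnostics)
}

# random-effect correlation draws implied by the vine coordinates
.correlation_draws <- function(fit) {
  m <- fit$model
  stopifnot(m$S == 1L, m$K >= 2)
  u <- lapply(seq_len(m$n_u), function(j) fit$draws[, sprintf("u[%d]", j)])
  L <- .vine_L(u, m$K)
  out <- NULL
  nm <- character(0)
  for (k in 2:m$K) for (l in seq_len(k - 1L)) {
    r <- 0
    for (j in seq_len(min(k, l))) r <- r + L[[k]][[j]] * L[[l]][[j]]
    out <- cbind(out, r)
    nm <- c(nm, paste0("cor_", m$random[l], "_", m$random[k]))
  }
  colnames(out) <- nm
  out
}

#' @export
predict.percept_fit <- function(object, newdata = NULL,
                                type = c("link", "response"),
                                participant = NULL, ...) {
  type <- match.arg(type)
  m <- object$model
  if (is.null(newdata)) newdata <- m$cells
  if (m$S == 2L) stop("predict() supports single-session fits")
  X <- vapply(m$fixed, function(t) .term_x(newdata, t),
              numeric(nrow(newdata)))
  X <- matrix(X, nrow = nrow(newdata))
  beta <- object$draws[, sprintf("beta[%d]", seq_along(m$fix_names)),
                       drop = FALSE]
  eta <- X %*% t(beta)  # cells x draws
  if (!is.null(newdata$participant) || !is.null(participant)) {
    pids <- if (!is.null(participant)) rep(participant, nrow(newdata))
            else newdata$participant
    idx <- match(pids, m$pid_levels)
    if (!anyNA(idx)) {
      for (k in seq_along(m$random)) {
        tot <- individual_draws(object, m$random[k])  # draws x I
        dev <- t(tot[, idx, drop = FALSE]) -
          matrix(beta[, match(m$random[k], m$fix_names)],
                 nrow(newdata), nrow(beta), byrow = TRUE)
        eta <- eta + dev * .term_x(newdata, m$random[k])
      }
    }
  }
  est <- rowMeans(if (type == "response") inv_logit(eta) else eta)
  est
}

#' @export
residuals.percept_fit <- function(object, type = "pearson", ...) {
  m <- object$model
  p <- .posterior_mean_p(object)
  (m$cells$y - m$cells$n * p) / sqrt(m$cells$n * p * (1 - p))
}

.posterior_mean_p <- function(fit) {
  m <- fit$model
  th <- fit$theta
  # posterior-mean probability per cell via the lp machinery is overkill;
  # reuse the draws directly on a cell basis
  beta <- fit$draws[, sprintf("beta[%d]", seq_along(m$fix_names)),
                    drop = FALSE]
  eta <- beta %*% t(m$X)
  if (m$K) {
    for (k in seq_len(m$K)) {
      if (m$S == 1L) {
        tot <- individual_draws(fit, m$random[k])
        dev <- tot - beta[, match(m$random[k], m$fix_names)]
        eta <- eta + dev[, m$pid, drop = FALSE] *
          rep(m$Xr[[k]], each = nrow(beta))
      } else {
        for (s in 1:2) {
          tot <- individual_draws(fit, m$random[k], session = s)
          dev <- tot - beta[, match(paste0(m$random[k], ".s", s),
                                    m$fix_names)]
          eta <- eta + dev[, m$pid, drop = FALSE] *
            rep(m$Xr[[k]] * (m$sess == s), each = nrow(beta))
        }
      }
    }
  }
  colMeans(inv_logit(eta))
}

#' @export
simulate.percept_fit <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$model
  p <- .posterior_mean_p(object)
  with_seed(seed, {
    out <- replicate(nsim, stats::rbinom(length(p), m$cells$n, p))
    colnames(out) <- paste0("sim_", seq_len(nsim))
    cbind(m$cells[c("participant", "session", "centered_ar", "r1", "n")],
          as.data.frame(out))
  })
}

#' @export
plot.percept_fit <- function(x, ...) {
  m <- x$model
  if (!"ar" %in% m$fixed || !"r1" %in% m$fixed) {
    stop("plot() needs a model with aspect-ratio and first-percept terms")
  }
  cells <- m$cells
  # empirical cell logits aggregated over participants
  agg_key <- paste(cells$centered_ar, cells$r1)
  n <- tapply(cells$n, agg_key, sum)
  y <- tapply(cells$y, agg_key, sum)
  ar <- tapply(cells$centered_ar, agg_key, `[`, 1)
  r1 <- tapply(cells$r1, agg_key, `[`, 1)
  p <- ifelse(y == 0 | y == n, (y + 0.5) / (n + 1), y / n)
  lg <- log(p / (1 - p))
  graphics::plot(ar, lg, pch = ifelse(r1 == 1, 19, 1),
                 xlab = "centered aspect ratio",
                 ylab = "logit P(L2 -> 0 deg)",
                 main = "Second-lattice percept by aspect ratio")
  b <- stats::coef(x)
  xs <- seq(min(ar), max(ar), length.out = 50)
  for (r in 0:1) {
    eta <- b["intercept"] + b["ar"] * xs + b["r1"] * r +
      if ("ar_r1" %in% names(b)) b["ar_r1"] * xs * r else 0
    graphics::lines(xs, eta, lty = 2 - r)
  }
  graphics::legend("topleft", legend = c("L1 -> 0 deg", "L1 -> 90 deg"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
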