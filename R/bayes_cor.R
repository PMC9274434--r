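#' Bayesian correlation model
#'
#' Bivariate-normal model with a Uniform(-1, 1) prior on the correlation,
#' fitted with JAGS on standardized data (normal priors on the means,
#' half-t priors on the SDs). Used for the two-stage correlation tests on
#' posterior-mean individual effects and orientation-bias magnitudes; the
#' one-sided Bayes factor then comes from [savage_dickey_onesided()] on the
#' returned draws.
#'
#' @param x,y paired numeric vectors.
#' @param sampler [sampler_config()].
#' @param quiet suppress JAGS output.
#' @return list of class `bayes_cor`: `r_draws`, `mean`, `hdci`, `n`.
#' @export
bayes_cor <- function(x, y, sampler = sampler_config(chains = 2L,
                                                     iterations = 2500L,
                                                     warmup = 500L),
                      quiet = TRUE) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (n < 10) warning("fewer than 10 pairs; correlation weakly identified")
  xs <- as.vector(scale(x)); ys <- as.vector(scale(y))
  code <- "
model {
  for (i in 1:n) { v[i,1:2] ~ dmnorm(mu[1:2], Tau[1:2,1:2]) }
  Sigma[1,1] <- sig[1]^2
  Sigma[2,2] <- sig[2]^2
  Sigma[1,2] <- r * sig[1] * sig[2]
  Sigma[2,1] <- Sigma[1,2]
  Tau[1:2,1:2] <- inverse(Sigma[1:2,1:2])
  mu[1] ~ dnorm(0, 1)
  mu[2] ~ dnorm(0, 1)
  sig[1] ~ dt(0, 1, 3) T(0,)
  sig[2] ~ dt(0, 1, 3) T(0,)
  r ~ dunif(-1, 1)
}"
  inits <- lapply(seq_len(sampler$chains), function(ch)
    list(r = 0, mu = c(0, 0), sig = c(1, 1),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sampler$seed + ch))
  jm <- rjags::jags.model(textConnection(code),
                          data = list(n = n, v = cbind(xs, ys)),
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = max(100L, sampler$warmup %/% 2),
                          quiet = quiet)
  stats::update(jm, max(0L, sampler$warmup - max(100L, sampler$warmup %/% 2)),
         progress.bar = "none")
  samp <- rjags::coda.samples(jm, "r", n.iter = sampler$iterations,
                              progress.bar = "none")
  r_draws <- as.vector(do.call(rbind, lapply(samp, as.matrix)))
  structure(list(r_draws = r_draws, mean = mean(r_draws),
                 hdci = hdci(r_draws), n = n), class = "bayes_cor")
}

#' @export
print.bayes_cor <- function(x, ...) {
  cat(sprintf("Bayesian correlation (n = %d): mean r = %.3f, 95%% HDCI [%.3f, %.3f]\n",
              x$n, x$mean, x$hdci[1], x$hdci[2]))
  invisible(x)
}

# Bayesian linear regression of y on a design matrix (standardized inputs
# expected); returns draws and a log joint density for bridge sampling.
.bayes_lm <- function(X, y, sampler = sampler_config(chains = 2L,
                                                     iterations = 2500L,
                                                     warmup = 500L),
                      quiet = TRUE) {
  P <- ncol(X)
  n <- length(y)
  code <- paste(c(
    "model {",
    "  for (i in 1:n) { y[i] ~ dnorm(inprod(X[i,], coef[1:P]), pow(sig, -2)) }",
    "  for (p in 1:P) { coef[p] ~ dnorm(0, 1) }",
    "  sig ~ dt(0, 1, 3) T(0,)",
    "}"), collapse = "\n")
  inits <- lapply(seq_len(sampler$chains), function(ch)
    list(coef = rep(0, P), sig = 1,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = sampler$seed + ch))
  jm <- rjags::jags.model(textConnection(code),
                          data = list(n = n, P = P, X = X, y = y),
                          inits = inits, n.chains = sampler$chains,
                          n.adapt = 200L, quiet = quiet)
  stats::update(jm, max(0L, sampler$warmup - 200L), progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("coef", "sig"),
                              n.iter = sampler$iterations,
                              progress.bar = "none")
  nodes <- c(sprintf("coef[%d]", seq_len(P)), "sig")
  draws <- do.call(rbind, lapply(samp, function(s) as.matrix(s)[, nodes]))
  theta <- draws
  theta[, P + 1] <- log(draws[, P + 1])
  lp <- function(th) {
    if (is.null(dim(th))) th <- matrix(th, nrow = 1)
    coefs <- th[, seq_len(P), drop = FALSE]
    sig <- exp(th[, P + 1])
    mu <- coefs %*% t(X)  # draws x n
    ll <- vapply(seq_len(nrow(th)), function(i)
      sum(stats::dnorm(y, mu[i, ], sig[i], log = TRUE)), numeric(1))
    pr <- rowSums(stats::dnorm(coefs, log = TRUE)) +
      log(2) + stats::dt(sig, 3, log = TRUE) + th[, P + 1]
    ll + pr
  }
  list(theta = theta, lp = lp)
}

#' Linear versus quadratic relation, by bridge sampling
#'
#' Compares a linear and a quadratic Bayesian regression of `y` on `x`
#' (both standardized, matched unit-normal priors on the coefficients) and
#' returns the Bayes factor of the quadratic model over the linear one.
#'
#' @param x,y paired numeric vectors.
#' @param sampler [sampler_config()].
#' @param seed seed for the bridge proposal draws.
#' @return `bayes_factor` list (log BF of quadratic vs linear).
#' @export
bf_linear_vs_quadratic <- function(x, y,
                                   sampler = sampler_config(chains = 2L,
                                                            iterations = 2500L,
                                                            warmup = 500L),
                                   seed = 1L) {
  keep <- stats::complete.cases(x, y)
  xs <- as.vector(scale(x[keep])); ys <- as.vector(scale(y[keep]))
  X_lin <- cbind(1, xs)
  X_quad <- cbind(1, xs, xs^2)
  fit_lin <- .bayes_lm(X_lin, ys, sampler)
  fit_quad <- .bayes_lm(X_quad, ys, sampler)
  ml_lin <- bridge_log_ml(fit_lin$theta, fit_lin$lp, seed = seed)
  ml_quad <- bridge_log_ml(fit_quad$theta, fit_quad$lp, seed = seed + 1L)
  log_bf <- ml_quad$log_ml - ml_lin$log_ml
  structure(list(log_bf = log_bf, bf = exp(log_bf),
                 favored = if (log_bf >= 0) "quadratic" else "linear",
                 estimator = "bridge",
                 mc_error = sqrt(ml_lin$mc_error^2 + ml_quad$mc_error^2),
                 n_draws_used = ml_lin$n_draws_used + ml_quad$n_draws_used),
            class = "bayes_factor")
}
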