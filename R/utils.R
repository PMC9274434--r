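#' Logit and inverse logit
#'
#' Convenience wrappers around [stats::qlogis()] and [stats::plogis()].
#'
#' @param p probability in (0, 1).
#' @param x real-valued log-odds.
#' @return `logit()` returns log-odds; `inv_logit()` returns probabilities.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Highest density continuous interval from draws
#'
#' Shortest interval containing a given posterior mass, computed by the
#' sliding-window method on sorted draws.
#'
#' @param x numeric vector of draws.
#' @param mass interval mass (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdci <- function(x, mass = 0.95) {
  stopifnot(is.numeric(x), length(x) > 1, mass > 0, mass < 1)
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = xs[1], upper = xs[n]))
  widths <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k])
}

# Split-Rhat (Gelman et al.): each chain split in half, potential scale
# reduction computed across the 2m half-chains.
split_rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  segs <- cbind(chains[1:half, , drop = FALSE],
                chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# run code with a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic child seeds below 2^31 derived from one top-level seed
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  ((as.integer(seed) %% 1000003L) * 1009L + 31L * as.integer(k)) %% 2147480000L
}
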