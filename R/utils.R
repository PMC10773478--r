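# Internal helpers: seeding, numerics, small finite-difference tools.

#' Derive a reproducible substream seed from a master seed and a label
#'
#' Simulation stages (latent draws, vignette assignment, rating noise) and
#' replicate loops each draw from their own substream so that, e.g., changing
#' the UK sample size does not perturb the Indian cohort's draws. The
#' substream seed is a deterministic 31-bit hash of the master seed and a
#' stage label.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  s <- (s + h) %% m
  as.integer(if (s == 0) 1 else s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log(sum(exp(x))) guarded against overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# P(a < Z <= b) for standard normal, stable in both tails; a, b vectorized,
# may be -Inf/Inf.
pnorm_diff <- function(a, b) {
  out <- ifelse(a > 0,
    pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE),
    pnorm(b) - pnorm(a)
  )
  pmax(out, 0)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Central-difference gradient of scalar function f at x (test oracle and
# fallback; the fitting path uses analytic gradients).
fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# Central-difference Jacobian of vector-valued g at x.
fd_jacobian <- function(g, x, eps = 1e-6) {
  g0 <- g(x)
  J <- matrix(0, length(g0), length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- eps
    J[, i] <- (g(x + e) - g(x - e)) / (2 * eps)
  }
  J
}

# Forward-difference variant: half the evaluations, O(eps) accuracy.
fd_jacobian_fwd <- function(g, x, eps = 1e-6) {
  g0 <- g(x)
  J <- matrix(0, length(g0), length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- eps
    J[, i] <- (g(x + e) - g0) / eps
  }
  J
}
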