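# Ordinal-probit probability machinery and per-person marginal likelihoods.
#
# The functions here are the readable reference implementation used in tests
# and for small problems; model fitting calls the compiled core (src/) that
# computes the same quantities plus analytic gradients.

#' Gauss-Hermite quadrature rule for unit-variance normal integrals
#'
#' Nodes and weights rescaled so that `sum(w * f(x))` approximates
#' `E[f(Z)]` for `Z ~ N(0, 1)`: weights sum to 1 and nodes are symmetric
#' about 0. The default 21 nodes per dimension is ample for propensity SDs
#' of order 1-2; convergence is checked against 41 nodes in the test suite.
#'
#' @param Q number of nodes per latent dimension.
#' @return list with `nodes`, `weights`, `Q`.
#' @export
ghq_rule <- function(Q = 21) {
  stopifnot(Q >= 2)
  gh <- pracma::gaussHermite(Q)
  list(nodes = gh$x * sqrt(2), weights = gh$w / sqrt(pi), Q = as.integer(Q))
}

#' Ordered-category probabilities under the probit link
#'
#' `P(rating = k) = Phi(tau[k+1] - m) - Phi(tau[k] - m)` with
#' `tau[0] = -Inf`, `tau[4] = +Inf`.
#'
#' @param m propensity mean.
#' @param tau three strictly increasing thresholds.
#' @return numeric vector of 4 probabilities summing to 1.
#' @export
category_probs <- function(m, tau) {
  stopifnot(length(tau) == 3L, length(m) == 1L)
  if (!(tau[1] < tau[2] && tau[2] < tau[3]))
    stop("thresholds must be strictly increasing")
  cuts <- c(-Inf, tau, Inf)
  pnorm_diff(cuts[1:4] - m, cuts[2:5] - m)
}

#' Propensity mean for a response occasion
#'
#' Self-reports load on both factors (`lambda * theta + gamma * eta`);
#' vignette ratings are anchored at the vignette's severity and load only on
#' response style (`beta + gamma * eta`) — the depression factor does not
#' contribute to vignette ratings.
#'
#' @param params [adjusted_params()].
#' @param item item number.
#' @param source `"SELF"` or `"VIGNETTE"`.
#' @param vignette vignette label, required iff `source = "VIGNETTE"`.
#' @param theta,eta latent factor values.
#' @return scalar propensity mean.
#' @export
propensity_mean <- function(params, item, source, vignette = NULL,
                            theta = 0, eta = 0) {
  stopifnot(inherits(params, "adjusted_params"), source %in% c("SELF", "VIGNETTE"))
  if (source == "SELF") {
    if (!is.null(vignette)) stop("vignette index with SELF source")
    params$lambda[item] * theta + params$gamma[item] * eta
  } else {
    if (is.null(vignette)) stop("VIGNETTE source requires a vignette label")
    v <- match(vignette, vignette_labels(params))
    if (is.na(v)) stop("unknown vignette label")
    unname(params$beta[item, v]) + params$gamma[item] * eta
  }
}

PROB_FLOOR <- 1e-300

# conditional log-likelihood of one person's records at latent values
# (theta, eta); records is a data frame slice of an av_dataset.
conditional_loglik <- function(records, params, country, theta, eta) {
  tau <- params$tau[[country]]
  ll <- 0
  for (r in seq_len(nrow(records))) {
    m <- propensity_mean(params, records$item[r], records$source[r],
                         if (records$source[r] == "VIGNETTE") records$vignette[r],
                         theta = theta, eta = eta)
    p <- category_probs(m, tau[records$item[r], ])[records$rating[r] + 1L]
    ll <- ll + log(max(p, PROB_FLOOR))
  }
  ll
}

#' Marginal log-likelihood of one person under the adjusted model
#'
#' Integrates the conditional likelihood over theta ~ N(mu_country, 1) and
#' eta ~ N(0, 1) with a tensor-product Gauss-Hermite rule. Persons with only
#' vignette records use the exact 1-D reduction over eta (theta does not
#' enter their propensities, so it integrates out analytically).
#'
#' @param records one person's records (a slice of an [av_dataset()]).
#' @param params [adjusted_params()].
#' @param country the person's country (`"IN"` or `"UK"`).
#' @param quad a [ghq_rule()].
#' @return scalar log-likelihood (0 for an empty record set).
#' @export
person_loglik <- function(records, params, country, quad = ghq_rule()) {
  stopifnot(inherits(params, "adjusted_params"), country %in% COUNTRIES)
  if (nrow(records) == 0L) return(0)
  if (length(unique(records$person_id)) > 1L)
    stop("records must belong to a single person")
  mu <- if (country == "UK") params$mu_uk else 0
  z <- quad$nodes; w <- quad$weights
  if (all(records$source == "VIGNETTE")) {
    lls <- vapply(z, function(e) conditional_loglik(records, params, country,
                                                    theta = 0, eta = e),
                  numeric(1))
    return(logsumexp(lls + log(w)))
  }
  lls <- outer(z, z, Vectorize(function(t, e)
    conditional_loglik(records, params, country, theta = mu + t, eta = e)))
  logsumexp(as.vector(lls) + log(as.vector(outer(w, w))))
}

#' Marginal log-likelihood of one person under the naive model
#'
#' One latent dimension (depression only); thresholds shared across
#' countries. Vignette records are rejected: the naive model describes
#' self-reports only.
#'
#' @param records one person's SELF records.
#' @param params [naive_params()].
#' @param country the person's country.
#' @param quad a [ghq_rule()].
#' @return scalar log-likelihood.
#' @export
person_loglik_naive <- function(records, params, country, quad = ghq_rule()) {
  stopifnot(inherits(params, "naive_params"), country %in% COUNTRIES)
  if (nrow(records) == 0L) return(0)
  if (any(records$source == "VIGNETTE"))
    stop("naive model is self-report only; vignette records present")
  mu <- if (country == "UK") params$mu_uk else 0
  z <- quad$nodes; w <- quad$weights
  lls <- vapply(z, function(t) {
    s <- 0
    for (r in seq_len(nrow(records))) {
      m <- params$lambda[records$item[r]] * (mu + t)
      p <- category_probs(m, params$tau[records$item[r], ])[records$rating[r] + 1L]
      s <- s + log(max(p, PROB_FLOOR))
    }
    s
  }, numeric(1))
  logsumexp(lls + log(w))
}

#' Dataset marginal log-likelihood
#'
#' Sum of per-person marginal log-likelihood contributions. A person's
#' cohort determines which blocks they contribute (self, vignette or both);
#' the auxiliary-sample factorization means vignette-only persons contribute
#' nothing about `mu_uk`. Uses the compiled core; equals the sum of
#' [person_loglik()] (or [person_loglik_naive()]) values to numerical
#' accuracy.
#'
#' @param data an oriented [av_dataset()].
#' @param params [adjusted_params()] or [naive_params()] (for the latter the
#'   dataset must contain only SELF records).
#' @param quad a [ghq_rule()].
#' @return scalar log-likelihood.
#' @export
dataset_loglik <- function(data, params, quad = ghq_rule()) {
  require_oriented(data)
  arr <- prepare_arrays(data, params)
  if (inherits(params, "adjusted_params")) {
    loglik_adjusted(arr, params, quad, want_grad = FALSE)$loglik
  } else {
    if (length(arr$v_person))
      stop("naive model is self-report only; vignette records present")
    loglik_naive(arr, params, quad, want_grad = FALSE)$loglik
  }
}

#' Monte-Carlo integration oracle for the person log-likelihood
#'
#' Averages the conditional likelihood over independent latent draws; used
#' as an independent check of the quadrature in the test suite. Returns the
#' log of the Monte-Carlo mean together with a delta-method standard error
#' on the log scale.
#'
#' @param records one person's records.
#' @param params [adjusted_params()] or [naive_params()].
#' @param country the person's country.
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return list with `loglik` and `se`.
#' @export
mc_loglik_oracle <- function(records, params, country, n_draws = 1e5,
                             seed = 1) {
  stopifnot(n_draws >= 1)
  mu <- if (country == "UK") params$mu_uk else 0
  naive <- inherits(params, "naive_params")
  with_seed(seed, {
    th <- rnorm(n_draws, mu, 1)
    et <- rnorm(n_draws, 0, 1)
    ll <- numeric(n_draws)
    for (r in seq_len(nrow(records))) {
      if (naive) {
        m <- params$lambda[records$item[r]] * th
        tau_r <- params$tau[records$item[r], ]
      } else {
        m <- if (records$source[r] == "SELF")
          params$lambda[records$item[r]] * th + params$gamma[records$item[r]] * et
        else
          params$beta[records$item[r],
                      match(records$vignette[r], vignette_labels(params))] +
            params$gamma[records$item[r]] * et
        tau_r <- params$tau[[country]][records$item[r], ]
      }
      cuts <- c(-Inf, tau_r, Inf)
      p <- pnorm_diff(cuts[records$rating[r] + 1L] - m,
                      cuts[records$rating[r] + 2L] - m)
      ll <- ll + log(pmax(p, PROB_FLOOR))
    }
    lik <- exp(ll - max(ll))
    mean_lik <- mean(lik)
    se_log <- stats::sd(lik) / mean_lik / sqrt(n_draws)
    list(loglik = max(ll) + log(mean_lik), se = se_log)
  })
}
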