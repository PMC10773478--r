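# Shared fixtures: tiny parameter sets and datasets built in code.

# A small two-item, two-vignette adjusted parameter set for fast exact tests.
tiny_params <- function(mu_uk = -0.3) {
  adjusted_params(
    lambda = c(1.0, 0.7),
    gamma = c(0.3, 0.4),
    beta = matrix(c(2.0, 1.0,
                    1.5, 0.5), nrow = 2, byrow = FALSE,
                  dimnames = list(NULL, c("A", "B"))),
    tau = list(IN = rbind(c(0.5, 1.2, 2.0), c(0.2, 1.0, 1.8)),
               UK = rbind(c(0.0, 0.9, 2.2), c(-0.3, 0.8, 2.0))),
    mu_uk = mu_uk
  )
}

tiny_config <- function(n = 60, seed = 1, design = "RANDOM_K", k = 2, ...) {
  sim_config(n_india = n, n_uk_self = n, n_uk_av = ceiling(n / 2),
             params = tiny_params(), design = design, k = k, seed = seed, ...)
}

# quick hand-built dataset: two persons, one per country
hand_dataset <- function(oriented = TRUE) {
  av_dataset(data.frame(
    person_id = c("p1", "p1", "p1", "p2", "p2"),
    country = c("IN", "IN", "IN", "UK", "UK"),
    cohort = c("IN_MAIN", "IN_MAIN", "IN_MAIN", "UK_SELF", "UK_SELF"),
    item = c(1L, 2L, 1L, 1L, 2L),
    source = c("SELF", "SELF", "VIGNETTE", "SELF", "SELF"),
    vignette = c(NA, NA, "A", NA, NA),
    rating = c(0L, 2L, 3L, 1L, 1L),
    stringsAsFactors = FALSE
  ), oriented = oriented)
}

# marginal category probabilities for a self-report item, integrating the
# latent factors by quadrature (independent oracle for simulation tests)
marginal_self_probs <- function(params, item, country, Q = 41) {
  q <- ghq_rule(Q)
  mu <- if (country == "UK") params$mu_uk else 0
  probs <- numeric(4)
  for (a in seq_len(Q)) for (b in seq_len(Q)) {
    m <- params$lambda[item] * (mu + q$nodes[a]) +
      params$gamma[item] * q$nodes[b]
    probs <- probs + q$weights[a] * q$weights[b] *
      category_probs(m, params$tau[[country]][item, ])
  }
  probs
}

marginal_vignette_probs <- function(params, item, vignette, country, Q = 41) {
  q <- ghq_rule(Q)
  v <- match(vignette, colnames(params$beta))
  probs <- numeric(4)
  for (b in seq_len(Q)) {
    m <- params$beta[item, v] + params$gamma[item] * q$nodes[b]
    probs <- probs + q$weights[b] *
      category_probs(m, params$tau[[country]][item, ])
  }
  probs
}

fast_control <- function(...) fit_control(Q = 11, ...)
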