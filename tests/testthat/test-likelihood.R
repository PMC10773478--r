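test_that("category probabilities match the normal CDF and sum to one", {
  expect_equal(category_probs(0, c(0, 1, 2)),
               c(pnorm(0), pnorm(1) - pnorm(0), pnorm(2) - pnorm(1),
                 1 - pnorm(2)), tolerance = 1e-12)
  expect_equal(category_probs(1, c(0, 1, 2)),
               c(pnorm(-1), pnorm(0) - pnorm(-1), pnorm(1) - pnorm(0),
                 1 - pnorm(1)), tolerance = 1e-12)
  expect_equal(category_probs(100, c(0, 1, 2)), c(0, 0, 0, 1),
               tolerance = 1e-12)
  expect_error(category_probs(0, c(1, 0, 2)), "strictly increasing")

  set.seed(1)
  for (i in 1:25) {
    m <- rnorm(1, 0, 3)
    tau <- sort(rnorm(3, 0, 2))
    if (any(diff(tau) == 0)) next
    p <- category_probs(m, tau)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # P(rating >= k) strictly increasing in the propensity mean
  ms <- seq(-3, 3, by = 0.5)
  surv <- t(vapply(ms, function(m) rev(cumsum(rev(category_probs(m, c(0, 1, 2))))),
                   numeric(4)))
  for (k in 2:4) expect_true(all(diff(surv[, k]) > 0))
})

test_that("propensity means follow the two-factor loading structure", {
  p <- adjusted_params(lambda = c(0.9, 0.5), gamma = c(0.014, 0.3),
                       beta = matrix(c(2, 2, 1, 1), 2, 2,
                                     dimnames = list(NULL, c("A", "B"))),
                       tau = list(IN = rbind(c(0, 1, 2), c(0, 1, 2)),
                                  UK = rbind(c(0, 1, 2), c(0, 1, 2))))
  expect_equal(propensity_mean(p, 1, "SELF", theta = 1, eta = 0), 0.9)
  expect_equal(propensity_mean(p, 2, "VIGNETTE", "A", theta = 5, eta = -1),
               2 - 0.3)
  # theta never affects a vignette propensity
  for (th in c(-2, 0, 3))
    expect_equal(propensity_mean(p, 1, "VIGNETTE", "B", theta = th, eta = 0.5),
                 propensity_mean(p, 1, "VIGNETTE", "B", theta = 0, eta = 0.5))
  expect_error(propensity_mean(p, 1, "SELF", vignette = "A"), "vignette index")
  expect_error(propensity_mean(p, 1, "VIGNETTE"), "requires a vignette")
})

test_that("quadrature marginal likelihood agrees with the Monte-Carlo oracle", {
  p <- tiny_params()
  d <- generate_dataset(tiny_config(n = 6, seed = 17))
  persons <- unique(d$person_id)[c(1, 4, 8, 12)]
  for (pid in persons) {
    recs <- d[d$person_id == pid, ]
    ql <- person_loglik(recs, p, recs$country[1])
    mc <- mc_loglik_oracle(recs, p, recs$country[1], n_draws = 2e5, seed = 8)
    expect_lt(abs(ql - mc$loglik), 3 * mc$se)
  }
  # naive model route
  pn <- naive_params(c(0.8, 1.2), rbind(c(0, 1, 2), c(-0.5, 0.5, 1.5)),
                     mu_uk = 0.4)
  recs <- d[d$person_id == persons[1] & d$source == "SELF", ]
  ql <- person_loglik_naive(recs, pn, "IN")
  mc <- mc_loglik_oracle(recs, pn, "IN", n_draws = 2e5, seed = 9)
  expect_lt(abs(ql - mc$loglik), 3 * mc$se)
  expect_identical(mc, mc_loglik_oracle(recs, pn, "IN", n_draws = 2e5, seed = 9))
})

test_that("zero loadings collapse the integral to marginal probabilities", {
  pn <- naive_params(c(0, 0), rbind(c(0, 1, 2), c(-1, 0, 1)))
  recs <- hand_dataset()[hand_dataset()$person_id == "p2", ]
  ll <- person_loglik_naive(recs, pn, "UK")
  direct <- log(category_probs(0, c(0, 1, 2))[2]) +
    log(category_probs(0, c(-1, 0, 1))[2])
  expect_equal(ll, direct, tolerance = 1e-10)
  # independent of quadrature size when the latents drop out
  expect_equal(person_loglik_naive(recs, pn, "UK", ghq_rule(5)), direct,
               tolerance = 1e-10)
  expect_error(person_loglik_naive(hand_dataset()[1:3, ], pn, "IN"),
               "self-report only")
})

test_that("quadrature converges and the 1-D vignette reduction is exact", {
  p <- tiny_params()
  d <- generate_dataset(tiny_config(n = 8, seed = 23))
  pid <- unique(d$person_id[d$cohort == "IN_MAIN"])[2]
  recs <- d[d$person_id == pid, ]
  ll21 <- person_loglik(recs, p, "IN", ghq_rule(21))
  ll41 <- person_loglik(recs, p, "IN", ghq_rule(41))
  expect_lt(abs(ll21 - ll41), 1e-6)

  # vignette-only person: the explicit eta-only rule equals the full 2-D
  # tensor computation used by the dataset path
  pid_av <- unique(d$person_id[d$cohort == "UK_AV"])[1]
  recs_av <- d[d$person_id == pid_av, ]
  ll1d <- person_loglik(recs_av, p, "UK")
  d_single <- av_dataset(as.data.frame(recs_av), oriented = TRUE)
  ll2d <- dataset_loglik(d_single, p)
  expect_equal(ll1d, ll2d, tolerance = 1e-10)

  # empty record set contributes zero
  expect_equal(person_loglik(recs[0, ], p, "IN"), 0)
})

test_that("dataset loglik is additive, order-invariant and matches per-person sums", {
  p <- tiny_params()
  d <- generate_dataset(tiny_config(n = 10, seed = 29))
  persons <- unique(d$person_id)
  ll <- dataset_loglik(d, p)
  ll_ref <- sum(vapply(persons, function(pid) {
    recs <- d[d$person_id == pid, ]
    person_loglik(recs, p, recs$country[1])
  }, numeric(1)))
  expect_equal(ll, ll_ref, tolerance = 1e-9)

  half <- persons[seq_len(length(persons) %/% 2)]
  d1 <- av_dataset(as.data.frame(d[d$person_id %in% half, ]), oriented = TRUE)
  d2 <- av_dataset(as.data.frame(d[!d$person_id %in% half, ]), oriented = TRUE)
  expect_equal(dataset_loglik(d1, p) + dataset_loglik(d2, p), ll,
               tolerance = 1e-9)

  set.seed(3)
  d_perm <- av_dataset(as.data.frame(d)[sample(nrow(d)), ], oriented = TRUE)
  expect_equal(dataset_loglik(d_perm, p), ll, tolerance = 1e-12)
})

test_that("vignette-only persons carry no information about the UK mean", {
  p <- tiny_params()
  d <- generate_dataset(tiny_config(n = 10, seed = 37))
  d_av <- av_dataset(as.data.frame(d[d$cohort == "UK_AV", ]), oriented = TRUE)
  p2 <- p; p2$mu_uk <- 1.7
  expect_equal(dataset_loglik(d_av, p), dataset_loglik(d_av, p2),
               tolerance = 1e-12)
})

test_that("the naive mean enters only through the latent shift", {
  # shifting mu by delta equals shifting each item's thresholds by -lambda*delta
  pn <- naive_params(c(0.8, 1.3), rbind(c(0, 1, 2), c(-0.5, 0.5, 1.5)),
                     mu_uk = 0.3)
  delta <- 0.45
  pn_mu <- pn; pn_mu$mu_uk <- pn$mu_uk + delta
  pn_tau <- pn
  pn_tau$tau <- pn$tau - pn$lambda %o% rep(delta, 3)
  recs <- hand_dataset()[4:5, ]
  expect_equal(person_loglik_naive(recs, pn_mu, "UK"),
               person_loglik_naive(recs, pn_tau, "UK"), tolerance = 1e-9)
})

test_that("quadrature rules are normalized and symmetric", {
  for (Q in c(5, 15, 21, 41)) {
    q <- ghq_rule(Q)
    expect_equal(sum(q$weights), 1, tolerance = 1e-12)
    expect_equal(q$nodes, -rev(q$nodes), tolerance = 1e-12)
    expect_equal(sum(q$weights * q$nodes^2), 1, tolerance = 1e-10)
  }
})
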