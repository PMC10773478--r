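test_that("pack/unpack is a bijection onto ordered-threshold space", {
  set.seed(11)
  for (rep in 1:10) {
    tau_in <- t(apply(matrix(rnorm(6, 0, 2), 2, 3), 1, sort))
    tau_uk <- t(apply(matrix(rnorm(6, 0, 2), 2, 3), 1, sort))
    p <- adjusted_params(rnorm(2), rnorm(2),
                         matrix(rnorm(4), 2, 2,
                                dimnames = list(NULL, c("A", "B"))),
                         tau = list(IN = tau_in, UK = tau_uk),
                         mu_uk = rnorm(1))
    p2 <- unpack_params(pack_params(p), p)
    expect_equal(p2, p, tolerance = 1e-12)
  }
  pn <- load_printed_parameters("naive")
  expect_equal(unpack_params(pack_params(pn), pn), pn,
               tolerance = 1e-12, ignore_attr = TRUE)

  # the documented threshold encoding
  x <- pack_params(naive_params(1, rbind(c(1, 1.5, 2.7))))
  expect_equal(unname(x[2:4]), c(1, log(0.5), log(1.2)), tolerance = 1e-12)

  # any real vector unpacks to strictly ordered thresholds
  tmpl <- tiny_params()
  set.seed(12)
  for (rep in 1:10) {
    x <- rnorm(length(pack_params(tmpl)), 0, 3)
    p <- unpack_params(x, tmpl)
    for (cc in c("IN", "UK"))
      expect_true(all(p$tau[[cc]][, 1] < p$tau[[cc]][, 2] &
                      p$tau[[cc]][, 2] < p$tau[[cc]][, 3]))
  }
  bad <- tiny_params(); bad$mu_uk <- NaN
  expect_error(pack_params(bad), "non-finite")
})

test_that("the compiled score matches a finite-difference gradient", {
  p <- tiny_params()
  d <- generate_dataset(tiny_config(n = 25, seed = 41))
  arr <- avgrm:::prepare_arrays(d, p)
  q <- ghq_rule(9)
  x0 <- pack_params(p)
  f <- function(x) avgrm:::loglik_adjusted(arr, unpack_params(x, p), q,
                                           FALSE)$loglik
  res <- avgrm:::loglik_adjusted(arr, p, q, TRUE)
  ga <- avgrm:::grad_to_unconstrained(res, x0, p)
  gfd <- avgrm:::fd_gradient(f, x0)
  expect_equal(ga, gfd, tolerance = 1e-5, ignore_attr = TRUE)

  pn <- naive_params(c(0.9, 1.1), rbind(c(0, 1, 2), c(-0.5, 0.6, 1.4)), 0.2)
  dn <- av_dataset(as.data.frame(d[d$source == "SELF", ]), oriented = TRUE)
  arrn <- avgrm:::prepare_arrays(dn, pn)
  xn <- pack_params(pn)
  fn <- function(x) avgrm:::loglik_naive(arrn, unpack_params(x, pn), q,
                                         FALSE)$loglik
  resn <- avgrm:::loglik_naive(arrn, pn, q, TRUE)
  gan <- avgrm:::grad_to_unconstrained(resn, xn, pn)
  expect_equal(gan, avgrm:::fd_gradient(fn, xn), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("starting values invert pooled category proportions", {
  # a cell with proportions (.5, .25, .15, .1) has cumulative (.5, .75, .9)
  ratings <- rep(0:3, c(50, 25, 15, 10))
  d <- av_dataset(data.frame(
    person_id = sprintf("p%03d", seq_along(ratings)), country = "IN",
    cohort = "IN_MAIN", item = 1L, source = "SELF", vignette = NA,
    rating = ratings, stringsAsFactors = FALSE), oriented = TRUE)
  s <- starting_values(d, "naive", n_items = 1)
  expect_equal(s$tau[1, ], qnorm(c(0.5, 0.75, 0.9)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(s$lambda, 1)
  expect_equal(s$mu_uk, 0)

  # a degenerate all-zero cell clamps with a warning
  d0 <- av_dataset(data.frame(
    person_id = sprintf("p%03d", 1:20), country = "IN", cohort = "IN_MAIN",
    item = 1L, source = "SELF", vignette = NA, rating = 0L,
    stringsAsFactors = FALSE), oriented = TRUE)
  expect_warning(s0 <- starting_values(d0, "naive", n_items = 1), "clamped")
  expect_equal(s0$tau[1, 1], qnorm(0.999), tolerance = 1e-10)
  expect_true(all(diff(s0$tau[1, ]) > 0))

  # starting loglik is finite on a generated dataset
  dd <- generate_dataset(tiny_config(n = 30, seed = 43))
  st <- starting_values(dd, "adjusted", n_items = 2, vignettes = c("A", "B"))
  expect_true(is.finite(dataset_loglik(dd, st, ghq_rule(11))))
})

test_that("naive fitting recovers generating values on a small world", {
  gen <- adjusted_params(c(1.2, 0.8, 1.0), c(0, 0, 0),
                         matrix(0, 3, 2, dimnames = list(NULL, c("A", "B"))),
                         tau = list(IN = rbind(c(-0.5, 0.5, 1.5), c(0, 1, 2),
                                               c(-0.2, 0.7, 1.8)),
                                    UK = rbind(c(-0.5, 0.5, 1.5), c(0, 1, 2),
                                               c(-0.2, 0.7, 1.8))),
                         mu_uk = 0.5)
  cfg <- sim_config(n_india = 400, n_uk_self = 400, n_uk_av = 0,
                    n_india_av = 0, params = gen, seed = 47)
  d <- generate_dataset(cfg)
  fit <- fit_naive(d, control = fast_control(), n_items = 3)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$start_loglik)
  expect_lt(abs(fit$params$mu_uk - 0.5), 0.25)
  expect_lt(max(abs(fit$params$lambda - gen$lambda)), 0.35)
  # record order and person relabeling do not change the estimates
  perm <- as.data.frame(d)
  set.seed(1); perm <- perm[sample(nrow(perm)), ]
  perm$person_id <- paste0("z", perm$person_id)
  fit2 <- fit_naive(av_dataset(perm, oriented = TRUE),
                    control = fast_control(), n_items = 3)
  expect_equal(fit2$params$mu_uk, fit$params$mu_uk, tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("degenerate designs are rejected with hard errors", {
  d <- generate_dataset(tiny_config(n = 10, seed = 51))
  d_in <- av_dataset(as.data.frame(d[d$country == "IN", ]), oriented = TRUE)
  expect_error(fit_naive(d_in, n_items = 2), "single country")
  d_self <- av_dataset(as.data.frame(d[d$source == "SELF", ]), oriented = TRUE)
  expect_error(fit_adjusted(d_self, n_items = 2, vignettes = c("A", "B")),
               "vignette records")
  expect_error(fit_naive(av_dataset(as.data.frame(d), oriented = FALSE)),
               "not oriented")
})

test_that("adjusted fitting matches a grid search on a two-parameter slice", {
  cfg <- tiny_config(n = 150, seed = 53)
  d <- generate_dataset(cfg)
  fit <- fit_adjusted(d, control = fast_control(), n_items = 2,
                      vignettes = c("A", "B"))
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$start_loglik)

  arr <- avgrm:::prepare_arrays(d, fit$params)
  q <- ghq_rule(11)
  x_hat <- pack_params(fit$params)
  nm <- names(x_hat)
  i_mu <- which(nm == "mu_uk"); i_l1 <- which(nm == "lambda1")
  grid <- seq(-0.2, 0.2, by = 0.04)
  best <- c(0, 0); best_ll <- -Inf
  for (a in grid) for (b in grid) {
    x <- x_hat; x[i_mu] <- x[i_mu] + a; x[i_l1] <- x[i_l1] + b
    ll <- avgrm:::loglik_adjusted(arr, unpack_params(x, fit$params), q,
                                  FALSE)$loglik
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
  }
  # the optimizer's point is the grid optimum to within one grid step
  expect_lte(max(abs(best)), 0.04 + 1e-9)
  expect_lte(best_ll, fit$loglik + 1e-6)
})

test_that("an unrated vignette cell freezes its severity with a warning", {
  d <- generate_dataset(tiny_config(n = 40, seed = 59))
  drop <- !(d$source == "VIGNETTE" & d$vignette == "B" & d$item == 2)
  d2 <- av_dataset(as.data.frame(d[drop, ]), oriented = TRUE)
  expect_warning(
    fit <- fit_adjusted(d2, control = fast_control(), n_items = 2,
                        vignettes = c("A", "B")),
    "never rated")
  st <- starting_values(d2, "adjusted", n_items = 2, vignettes = c("A", "B"))
  expect_equal(fit$params$beta[2, "B"], st$beta[2, "B"])
})
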