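test_that("latent draws have the declared moments and are reproducible", {
  expect_equal(nrow(draw_latents(0, 0, 1)), 0L)
  expect_error(draw_latents(-1, 0, 1), "nonnegative")
  n <- 1e5
  lat <- draw_latents(n, mu = 0, seed = 99)
  bound <- 4 / sqrt(n)
  expect_lt(abs(mean(lat$theta)), bound)
  expect_lt(abs(mean(lat$eta)), bound)
  expect_lt(abs(cor(lat$theta, lat$eta)), bound)
  expect_identical(lat, draw_latents(n, mu = 0, seed = 99))
  lat_uk <- draw_latents(n, mu = 0.47, seed = 7)
  expect_lt(abs(mean(lat_uk$theta) - 0.47), bound)
})

test_that("self-report ratings follow the ordinal probit law", {
  # zero loadings: ratings are iid with probabilities Phi-differences
  p0 <- adjusted_params(lambda = c(0, 0), gamma = c(0, 0),
                        beta = matrix(0, 2, 2, dimnames = list(NULL, c("A", "B"))),
                        tau = list(IN = rbind(c(-1, 0, 1), c(-1, 0, 1)),
                                   UK = rbind(c(-1, 0, 1), c(-1, 0, 1))))
  n <- 2e4
  lat <- draw_latents(n, 0, seed = 2)
  recs <- simulate_self(lat, p0, "IN", seed = 3)
  freq <- tabulate(recs$rating[recs$item == 1] + 1L, 4L) / n
  truth <- c(pnorm(-1), pnorm(0) - pnorm(-1), pnorm(1) - pnorm(0),
             pnorm(1, lower.tail = FALSE))
  expect_lt(max(abs(freq - truth)), 4 * sqrt(max(truth * (1 - truth)) / n))

  # nonzero loadings: frequencies match the latent-integrated marginal law
  p <- tiny_params()
  lat <- draw_latents(n, 0, seed = 5)
  recs <- simulate_self(lat, p, "IN", seed = 6)
  for (j in 1:2) {
    freq <- tabulate(recs$rating[recs$item == j] + 1L, 4L) / n
    truth <- marginal_self_probs(p, j, "IN")
    expect_lt(max(abs(freq - truth)), 4 * sqrt(max(truth * (1 - truth)) / n))
  }

  # threshold beyond support forces the floor category
  p_hi <- tiny_params()
  p_hi$tau$IN <- rbind(c(8, 9, 10), c(8, 9, 10))
  recs <- simulate_self(draw_latents(500, 0, 1), p_hi, "IN", seed = 1)
  expect_true(all(recs$rating == 0L))
})

test_that("vignette ratings ignore the depression factor and see DIF", {
  p <- tiny_params()
  n <- 2e4
  lat <- draw_latents(n, 0, seed = 11)
  pid <- sprintf("x%05d", seq_len(n))
  asg <- data.frame(person_id = pid, item = 1L, vignette = "A",
                    stringsAsFactors = FALSE)
  recs <- simulate_vignette_ratings(lat, p, asg, "IN", pid, "IN_MAIN", seed = 12)
  freq <- tabulate(recs$rating + 1L, 4L) / n
  truth <- marginal_vignette_probs(p, 1, "A", "IN")
  expect_lt(max(abs(freq - truth)), 4 * sqrt(max(truth * (1 - truth)) / n))

  # same latents and severities, different thresholds -> a different law
  # (DIF by construction)
  recs_uk <- simulate_vignette_ratings(lat, p, asg, "UK", pid, "UK_AV", seed = 12)
  truth_uk <- marginal_vignette_probs(p, 1, "A", "UK")
  expect_gt(max(abs(truth_uk - truth)), 0.03)
  freq_uk <- tabulate(recs_uk$rating + 1L, 4L) / n
  expect_lt(max(abs(freq_uk - truth_uk)),
            4 * sqrt(max(truth_uk * (1 - truth_uk)) / n))

  # gamma = 0 decouples ratings from eta
  p0 <- p; p0$gamma <- c(0, 0)
  recs0 <- simulate_vignette_ratings(lat, p0, asg, "IN", pid, "IN_MAIN", seed = 13)
  truth0 <- category_probs(p0$beta[1, "A"], p0$tau$IN[1, ])
  freq0 <- tabulate(recs0$rating + 1L, 4L) / n
  expect_lt(max(abs(freq0 - truth0)), 4 * sqrt(max(truth0 * (1 - truth0)) / n))
  expect_error(simulate_vignette_ratings(lat, p, data.frame(
    person_id = "nope", item = 1L, vignette = "A"), "IN", pid, "IN_MAIN"),
    "unknown persons")
})

test_that("vignette assignment mechanisms have their defining properties", {
  n <- 400
  sr <- matrix(sample(0:3, n * 10, replace = TRUE), n, 10,
               dimnames = list(sprintf("p%04d", 1:n), NULL))
  full <- assign_vignettes("FULL", sr, seed = 1)
  expect_equal(nrow(full), n * 10 * 6)
  expect_true(all(table(full$person_id, full$item) == 6))

  rk <- assign_vignettes("RANDOM_K", sr, k = 2, seed = 2)
  expect_true(all(table(rk$person_id, rk$item) == 2))
  # no duplicates within a cell; uniform marginal frequency ~ k/6
  expect_false(any(duplicated(rk[c("person_id", "item", "vignette")])))
  freq <- table(rk$vignette) / (n * 10)
  expect_lt(max(abs(freq - 2 / 6)), 4 * sqrt((2 / 6) * (4 / 6) / (n * 10)))

  ad <- assign_vignettes("ADAPTIVE", sr, seed = 3)
  amap <- default_adaptive_map()
  for (r in 0:3) {
    cell <- sr[5, ] == r
    if (!any(cell)) next
    j <- which(cell)[1]
    got <- sort(ad$vignette[ad$person_id == rownames(sr)[5] & ad$item == j])
    expect_equal(got, sort(amap[[as.character(r)]]))
  }

  # adaptive with a missing self rating falls back to the random rule
  sr_na <- sr; sr_na[1, 1] <- NA
  ad2 <- assign_vignettes("ADAPTIVE", sr_na, k = 2, seed = 4)
  expect_equal(attr(ad2, "fallbacks"), 1L)
  expect_equal(sum(ad2$person_id == rownames(sr)[1] & ad2$item == 1), 2L)

  expect_error(assign_vignettes("RANDOM_K", sr, k = 7), "between 1 and")
  expect_error(assign_vignettes("ADAPTIVE", NULL), "requires self ratings")
})

test_that("generated datasets have the design's record counts and validate", {
  p <- tiny_params()
  cfg <- sim_config(n_india = 5, n_uk_self = 5, n_uk_av = 5, params = p,
                    design = "FULL", seed = 1, k = 2)
  d <- generate_dataset(cfg)
  J <- 2; V <- 2
  expect_equal(sum(d$cohort == "IN_MAIN" & d$source == "SELF"), 5 * J)
  expect_equal(sum(d$cohort == "IN_MAIN" & d$source == "VIGNETTE"), 5 * J * V)
  expect_equal(sum(d$cohort == "UK_SELF"), 5 * J)
  expect_true(all(d$source[d$cohort == "UK_SELF"] == "SELF"))
  expect_equal(sum(d$cohort == "UK_AV"), 5 * J * V)
  expect_true(all(d$source[d$cohort == "UK_AV"] == "VIGNETTE"))
  expect_equal(nrow(validate_responses(d)), 0L)
  expect_true(isTRUE(attr(d, "oriented")))

  # determinism and substream independence: UK draws unchanged by n_india
  d2 <- generate_dataset(cfg)
  expect_equal(avgrm:::sort_records(d2), avgrm:::sort_records(d))
  cfg3 <- cfg; cfg3$n_india <- 7; cfg3$n_india_av <- 7
  d3 <- generate_dataset(cfg3)
  uk <- function(x) avgrm:::sort_records(av_dataset(
    as.data.frame(x[x$country == "UK", ]), oriented = TRUE))
  expect_equal(uk(d3), uk(d))

  # RANDOM_K k=2: exactly two vignette records per rater x item
  cfg_rk <- tiny_config(n = 20, seed = 9, design = "RANDOM_K", k = 2)
  drk <- generate_dataset(cfg_rk)
  vig <- drk[drk$source == "VIGNETTE", ]
  expect_true(all(table(vig$person_id, vig$item) == 2))

  # nested vignette subsample: only the first n_india_av Indians rate
  cfg_sub <- sim_config(n_india = 10, n_uk_self = 0, n_uk_av = 0,
                        params = p, seed = 3, n_india_av = 4)
  dsub <- generate_dataset(cfg_sub)
  vig <- dsub[dsub$source == "VIGNETTE", ]
  expect_equal(length(unique(vig$person_id)), 4L)
  expect_equal(length(unique(dsub$person_id[dsub$source == "SELF"])), 10L)
})
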