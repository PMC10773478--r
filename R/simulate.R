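# Synthetic-data generator for the three-cohort anchoring-vignette design.
#
# The generator produces data with exactly the statistical structure the
# adjusted model assumes: a latent depression factor theta ~ N(mu_country, 1)
# (India mean 0), an orthogonal response-style factor eta ~ N(0, 1), self
# propensities lambda*theta + gamma*eta, vignette propensities beta + gamma*eta
# (no theta), unit-normal propensity noise, and country-specific thresholds.
# Cohorts: IN_MAIN (self + vignettes), UK_SELF (self only), UK_AV (the
# auxiliary vignette-only calibration sample, drawn from the same UK
# population). Each (cohort, stage) uses its own RNG substream so changing
# one cohort's n leaves the other cohorts' draws untouched.

#' Default adaptive vignette-selection table
#'
#' Severity-matched overlapping pairs: a self rating of 0 triggers the two
#' least severe vignettes \{E, F\}, rating 1 -> \{D, E\}, rating 2 -> \{B, C\},
#' rating 3 -> \{A, B\}. The table is an argument everywhere it is used so
#' recovery results can be shown robust to the rule.
#'
#' @return list of length 4 (ratings 0-3), each a character vector of
#'   vignette labels.
#' @export
default_adaptive_map <- function() {
  list(`0` = c("E", "F"), `1` = c("D", "E"), `2` = c("B", "C"), `3` = c("A", "B"))
}

#' Simulation configuration for the three-cohort design
#'
#' Defaults are the study conditions: 549 Indian mothers with self-reports
#' and vignette ratings, 828 UK mothers with self-reports only, and a
#' 226-person UK auxiliary calibration sample rating vignettes only, two
#' random vignettes per item per rater, generated from the packaged published
#' adjusted-model parameter set.
#'
#' @param n_india persons in IN_MAIN (self + vignettes).
#' @param n_uk_self persons in UK_SELF (self only).
#' @param n_uk_av persons in UK_AV (vignettes only).
#' @param params generating [adjusted_params()].
#' @param design vignette-assignment mechanism: `"FULL"` (all six),
#'   `"RANDOM_K"` (uniform random k-subset per person x item) or
#'   `"ADAPTIVE"` (self-rating-matched pair; see [default_adaptive_map()]).
#' @param k vignettes per item per rater for `RANDOM_K` (study value 2).
#' @param seed master seed.
#' @param n_india_av number of IN_MAIN persons who also rate vignettes
#'   (defaults to all; the study's nested subsample was 247 of 549).
#' @param uk_integrated if `TRUE`, drop the auxiliary sample and give the
#'   UK_SELF persons vignette ratings themselves (the integrated design the
#'   auxiliary sample substitutes for; used in sensitivity experiments).
#' @param adaptive_map adaptive selection table.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_india = 549, n_uk_self = 828, n_uk_av = 226,
                       params = load_printed_parameters("adjusted"),
                       design = c("RANDOM_K", "FULL", "ADAPTIVE"), k = 2,
                       seed = 1, n_india_av = n_india,
                       uk_integrated = FALSE,
                       adaptive_map = default_adaptive_map()) {
  design <- match.arg(design)
  stopifnot(n_india >= 0, n_uk_self >= 0, n_uk_av >= 0,
            n_india_av >= 0, n_india_av <= n_india,
            inherits(params, "adjusted_params"),
            k >= 1, k <= n_vignettes(params))
  structure(list(n_india = n_india, n_uk_self = n_uk_self, n_uk_av = n_uk_av,
                 params = params, design = design, k = k, seed = seed,
                 n_india_av = n_india_av, uk_integrated = isTRUE(uk_integrated),
                 adaptive_map = adaptive_map),
            class = "sim_config")
}

#' Draw latent depression and response-style factors
#'
#' theta ~ N(mu, 1) and eta ~ N(0, 1), independent (the two factors are
#' orthogonal by model assumption).
#'
#' @param n number of persons.
#' @param mu latent depression mean (0 for India, `mu_uk` for the UK).
#' @param seed integer seed.
#' @return data frame with columns `theta`, `eta`.
#' @export
draw_latents <- function(n, mu = 0, seed = 1) {
  if (n < 0) stop("n must be nonnegative")
  with_seed(seed, data.frame(theta = rnorm(n, mu, 1), eta = rnorm(n, 0, 1)))
}

# ratings from propensities: category = number of thresholds exceeded
categorize <- function(propensity, tau_row) {
  as.integer((propensity > tau_row[1]) + (propensity > tau_row[2]) +
             (propensity > tau_row[3]))
}

#' Simulate self-report ratings
#'
#' For person i and item j the propensity is
#' `lambda[j] * theta_i + gamma[j] * eta_i + e`, `e ~ N(0, 1)`, cut by the
#' country's ordered item thresholds into ratings 0-3.
#'
#' @param latents data frame from [draw_latents()].
#' @param params [adjusted_params()] (use `gamma = 0` rows to emulate the
#'   naive generating process).
#' @param country `"IN"` or `"UK"` (selects the threshold set).
#' @param person_ids character ids, one per row of `latents`.
#' @param cohort cohort label for the emitted records.
#' @param seed integer seed for the propensity noise.
#' @return data frame of SELF records.
#' @export
simulate_self <- function(latents, params, country, person_ids = NULL,
                          cohort = NULL, seed = 1) {
  stopifnot(inherits(params, "adjusted_params"), country %in% COUNTRIES)
  n <- nrow(latents)
  J <- n_items(params)
  if (is.null(person_ids)) person_ids <- sprintf("%s%05d", country, seq_len(n))
  if (is.null(cohort)) cohort <- if (country == "IN") "IN_MAIN" else "UK_SELF"
  tau <- params$tau[[country]]
  if (n == 0L) return(empty_records())
  with_seed(seed, {
    out <- vector("list", J)
    for (j in seq_len(J)) {
      m <- params$lambda[j] * latents$theta + params$gamma[j] * latents$eta
      prop <- m + rnorm(n)
      out[[j]] <- data.frame(
        person_id = person_ids, country = country, cohort = cohort,
        item = j, source = "SELF", vignette = NA_character_,
        rating = categorize(prop, tau[j, ]), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

empty_records <- function() {
  data.frame(person_id = character(), country = character(),
             cohort = character(), item = integer(), source = character(),
             vignette = character(), rating = integer(),
             stringsAsFactors = FALSE)
}

#' Assign vignettes to person x item cells
#'
#' `FULL` presents all vignettes; `RANDOM_K` a uniformly random k-subset per
#' person x item; `ADAPTIVE` the severity-matched pair keyed on the person's
#' observed self rating for that item (missingness then depends only on
#' observed data, i.e. is MAR by construction). An adaptive cell with no
#' self rating falls back to the `RANDOM_K` rule (counted in the `fallbacks`
#' attribute).
#'
#' @param design `"FULL"`, `"RANDOM_K"` or `"ADAPTIVE"`.
#' @param self_ratings persons x items integer matrix of self ratings
#'   (`NA` allowed), required for `ADAPTIVE`; row names are person ids.
#' @param k subset size for `RANDOM_K` (and the adaptive fallback).
#' @param seed integer seed.
#' @param person_ids,n_items used when `self_ratings` is absent.
#' @param vignettes available vignette labels.
#' @param adaptive_map rating -> vignette-pair table; see
#'   [default_adaptive_map()].
#' @return data frame with columns `person_id`, `item`, `vignette`.
#' @export
assign_vignettes <- function(design = c("FULL", "RANDOM_K", "ADAPTIVE"),
                             self_ratings = NULL, k = 2, seed = 1,
                             person_ids = rownames(self_ratings),
                             n_items = ncol(self_ratings),
                             vignettes = LETTERS[1:6],
                             adaptive_map = default_adaptive_map()) {
  design <- match.arg(design)
  V <- length(vignettes)
  if (k < 1 || k > V) stop("k must be between 1 and ", V)
  if (design == "ADAPTIVE" && is.null(self_ratings))
    stop("ADAPTIVE assignment requires self ratings")
  if (is.null(person_ids)) stop("person_ids required")
  n <- length(person_ids)
  if (n == 0L)
    return(data.frame(person_id = character(), item = integer(),
                      vignette = character(), stringsAsFactors = FALSE))
  counter <- new.env(parent = emptyenv())
  counter$fallbacks <- 0L
  res <- with_seed(seed, {
    sel <- vector("list", n * n_items)
    idx <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n_items)) {
        idx <- idx + 1L
        sel[[idx]] <- switch(design,
          FULL = vignettes,
          RANDOM_K = sample(vignettes, k),
          ADAPTIVE = {
            r <- self_ratings[i, j]
            if (is.na(r)) {
              counter$fallbacks <- counter$fallbacks + 1L
              sample(vignettes, k)
            } else adaptive_map[[as.character(r)]]
          })
      }
    }
    len <- lengths(sel)
    cell_person <- rep(rep(person_ids, each = n_items), times = len)
    cell_item <- rep(rep(seq_len(n_items), times = n), times = len)
    data.frame(person_id = cell_person, item = cell_item,
               vignette = unlist(sel, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  attr(res, "fallbacks") <- counter$fallbacks
  res
}

#' Simulate vignette ratings
#'
#' Vignette v of item j is rated with propensity
#' `beta[j, v] + gamma[j] * eta_i + e`, `e ~ N(0, 1)` — the depression factor
#' does not contribute — cut by the rater's country thresholds. Rating the
#' same fixed severity through country-specific thresholds is what makes the
#' thresholds (and hence the DIF correction) identifiable.
#'
#' @param latents data frame from [draw_latents()] with row order matching
#'   `person_ids`.
#' @param params [adjusted_params()].
#' @param assignment data frame from [assign_vignettes()].
#' @param country `"IN"` or `"UK"`.
#' @param person_ids ids matching `latents` rows.
#' @param cohort cohort label for the emitted records.
#' @param seed integer seed.
#' @return data frame of VIGNETTE records.
#' @export
simulate_vignette_ratings <- function(latents, params, assignment, country,
                                      person_ids, cohort, seed = 1) {
  stopifnot(inherits(params, "adjusted_params"), country %in% COUNTRIES)
  if (nrow(assignment) == 0L) return(empty_records())
  if (!all(assignment$person_id %in% person_ids))
    stop("assignment refers to unknown persons")
  tau <- params$tau[[country]]
  i <- match(assignment$person_id, person_ids)
  j <- assignment$item
  v <- match(assignment$vignette, vignette_labels(params))
  if (anyNA(v)) stop("assignment refers to unknown vignettes")
  with_seed(seed, {
    m <- params$beta[cbind(j, v)] + params$gamma[j] * latents$eta[i]
    prop <- m + rnorm(nrow(assignment))
    rating <- as.integer((prop > tau[j, 1]) + (prop > tau[j, 2]) +
                         (prop > tau[j, 3]))
    data.frame(person_id = assignment$person_id, country = country,
               cohort = cohort, item = j, source = "VIGNETTE",
               vignette = assignment$vignette, rating = rating,
               stringsAsFactors = FALSE)
  })
}

#' Generate a full three-cohort dataset
#'
#' IN_MAIN persons contribute self-reports and (for the first `n_india_av`
#' of them) vignette ratings; UK_SELF persons self-reports only; UK_AV
#' persons vignette ratings only, with latents drawn from the same
#' N(mu_uk, 1) / N(0, 1) population as UK_SELF. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an oriented [av_dataset()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  J <- n_items(p)
  vl <- vignette_labels(p)
  ss <- function(label) substream_seed(config$seed, label)

  parts <- list()

  # --- India main cohort: self + vignettes -------------------------------
  lat_in <- draw_latents(config$n_india, mu = 0, seed = ss("IN_MAIN/latents"))
  pid_in <- sprintf("IN%05d", seq_len(config$n_india))
  self_in <- simulate_self(lat_in, p, "IN", pid_in, "IN_MAIN",
                           seed = ss("IN_MAIN/self"))
  parts$self_in <- self_in
  if (config$n_india_av > 0 && config$n_india > 0) {
    keep <- seq_len(config$n_india_av)
    sub_self <- self_in[self_in$person_id %in% pid_in[keep], ]
    sr <- matrix(NA_integer_, length(keep), J,
                 dimnames = list(pid_in[keep], NULL))
    sr[cbind(match(sub_self$person_id, pid_in[keep]), sub_self$item)] <-
      sub_self$rating
    asg <- assign_vignettes(config$design, self_ratings = sr, k = config$k,
                            seed = ss("IN_MAIN/assign"),
                            vignettes = vl, adaptive_map = config$adaptive_map)
    parts$vig_in <- simulate_vignette_ratings(
      lat_in[keep, , drop = FALSE], p, asg, "IN", pid_in[keep], "IN_MAIN",
      seed = ss("IN_MAIN/vignette"))
  }

  # --- UK self-report cohort ---------------------------------------------
  lat_uks <- draw_latents(config$n_uk_self, mu = p$mu_uk,
                          seed = ss("UK_SELF/latents"))
  pid_uks <- sprintf("UKS%05d", seq_len(config$n_uk_self))
  parts$self_uk <- simulate_self(lat_uks, p, "UK", pid_uks, "UK_SELF",
                                 seed = ss("UK_SELF/self"))
  if (config$uk_integrated && config$n_uk_self > 0) {
    sr <- matrix(NA_integer_, config$n_uk_self, J,
                 dimnames = list(pid_uks, NULL))
    s <- parts$self_uk
    sr[cbind(match(s$person_id, pid_uks), s$item)] <- s$rating
    asg <- assign_vignettes(config$design, self_ratings = sr, k = config$k,
                            seed = ss("UK_SELF/assign"),
                            vignettes = vl, adaptive_map = config$adaptive_map)
    parts$vig_uks <- simulate_vignette_ratings(
      lat_uks, p, asg, "UK", pid_uks, "UK_SELF", seed = ss("UK_SELF/vignette"))
    # integrated design: the self cohort itself supplies the vignettes
    parts$vig_uks$cohort <- "UK_SELF"
  }

  # --- UK auxiliary vignette-only calibration cohort ---------------------
  if (!config$uk_integrated && config$n_uk_av > 0) {
    lat_ukv <- draw_latents(config$n_uk_av, mu = p$mu_uk,
                            seed = ss("UK_AV/latents"))
    pid_ukv <- sprintf("UKV%05d", seq_len(config$n_uk_av))
    # no self ratings exist; under ADAPTIVE this cohort falls back to the
    # random rule (as in the study, where the calibration sample saw two
    # random vignettes per set)
    des <- if (config$design == "ADAPTIVE") "RANDOM_K" else config$design
    asg <- assign_vignettes(des, k = config$k, seed = ss("UK_AV/assign"),
                            person_ids = pid_ukv, n_items = J,
                            vignettes = vl, adaptive_map = config$adaptive_map)
    parts$vig_ukv <- simulate_vignette_ratings(
      lat_ukv, p, asg, "UK", pid_ukv, "UK_AV", seed = ss("UK_AV/vignette"))
  }

  recs <- do.call(rbind, unname(parts))
  if (is.null(recs)) recs <- empty_records()
  out <- av_dataset(recs, oriented = TRUE)
  # vignette-only UK persons must carry cohort UK_AV; integrated design keeps
  # them in UK_SELF (validate_responses flags the latter combination, which
  # is intentional there)
  attr(out, "config_seed") <- config$seed
  out
}
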