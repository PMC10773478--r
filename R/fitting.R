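# Maximum-likelihood estimation of the naive and vignette-adjusted models.
#
# Thresholds are reparameterized per (country, item) as
# (tau1, log(tau2 - tau1), log(tau3 - tau2)) so any real vector unpacks to a
# strictly ordered triple; loadings and mu_uk are free with a post-fit sign
# normalization (flip the depression factor so lambda[1] > 0, flip the style
# factor so the largest-|gamma| loading is positive). Identification:
# theta has mean 0 / variance 1 in India and variance 1 in the UK; eta has
# mean 0 / variance 1 in both countries; loadings and vignette severities
# are shared across countries.

# ---- data arrays -----------------------------------------------------------

# Convert an av_dataset to the 0-based index arrays the compiled core uses.
# Persons are sorted by id so results are invariant to record order.
prepare_arrays <- function(data, params) {
  stopifnot(inherits(data, "av_dataset"))
  J <- n_items(params)
  if (any(data$item > J))
    stop("dataset contains items beyond the ", J, " parameterized items")
  persons <- sort(unique(data$person_id))
  pidx <- match(data$person_id, persons)
  country <- integer(length(persons))
  country[pidx] <- match(data$country, COUNTRIES) - 1L
  s <- which(data$source == "SELF")
  v <- which(data$source == "VIGNETTE")
  vmatch <- integer(0)
  if (length(v)) {
    if (inherits(params, "adjusted_params")) {
      vmatch <- match(data$vignette[v], vignette_labels(params)) - 1L
      if (anyNA(vmatch)) stop("dataset contains vignettes the parameters lack")
    } else vmatch <- rep(0L, length(v))
  }
  list(persons = persons, p_country = country,
       s_person = pidx[s] - 1L, s_item = data$item[s] - 1L,
       s_rating = data$rating[s],
       v_person = pidx[v] - 1L, v_item = data$item[v] - 1L,
       v_vig = vmatch, v_rating = data$rating[v])
}

# tau list(IN, UK) -> flat vector with layout ((c * J) + j) * 3 + k
flatten_tau <- function(tau) c(t(tau$IN), t(tau$UK))
unflatten_tau <- function(x, J) {
  list(IN = matrix(x[seq_len(3 * J)], J, 3, byrow = TRUE),
       UK = matrix(x[3 * J + seq_len(3 * J)], J, 3, byrow = TRUE))
}

loglik_adjusted <- function(arr, params, quad, want_grad = FALSE) {
  adjusted_loglik_cpp(arr$p_country, arr$s_person, arr$s_item, arr$s_rating,
                      arr$v_person, arr$v_item, arr$v_vig, arr$v_rating,
                      params$lambda, params$gamma, params$beta,
                      flatten_tau(params$tau), params$mu_uk,
                      quad$nodes, quad$weights, want_grad)
}

loglik_naive <- function(arr, params, quad, want_grad = FALSE) {
  naive_loglik_cpp(arr$p_country, arr$s_person, arr$s_item, arr$s_rating,
                   params$lambda, as.vector(t(params$tau)), params$mu_uk,
                   quad$nodes, quad$weights, want_grad)
}

# ---- pack / unpack ---------------------------------------------------------

tau_to_unc <- function(tau_row) c(tau_row[1], log(diff(tau_row)))
tau_from_unc <- function(u) u[1] + c(0, cumsum(exp(u[2:3])))

#' Pack model parameters into an unconstrained vector
#'
#' Bijection between a parameter object and the unconstrained optimizer
#' space: thresholds become `(tau1, log(tau2 - tau1), log(tau3 - tau2))`;
#' everything else is carried through unchanged. [unpack_params()] inverts
#' it; any real vector unpacks to strictly ordered thresholds.
#'
#' @param params [naive_params()] or [adjusted_params()].
#' @return named numeric vector.
#' @export
pack_params <- function(params) {
  if (!all(vapply(params[names(params) != "tau"],
                  function(x) all(is.finite(unlist(x))), logical(1))))
    stop("non-finite parameter values")
  J <- n_items(params)
  if (inherits(params, "naive_params")) {
    tt <- as.vector(apply(params$tau, 1, tau_to_unc)) # 3 per item, item-major
    out <- c(params$lambda, tt, params$mu_uk)
    names(out) <- c(paste0("lambda", seq_len(J)),
                    paste0(rep(c("tau1_", "logd2_", "logd3_"), J),
                           rep(seq_len(J), each = 3)),
                    "mu_uk")
  } else {
    V <- n_vignettes(params)
    tt <- unlist(lapply(COUNTRIES, function(cc)
      as.vector(apply(params$tau[[cc]], 1, tau_to_unc))))
    out <- c(params$lambda, params$gamma, as.vector(params$beta), tt,
             params$mu_uk)
    names(out) <- c(paste0("lambda", seq_len(J)), paste0("gamma", seq_len(J)),
                    paste0("beta", rep(seq_len(J), V), "_",
                           rep(vignette_labels(params), each = J)),
                    paste0(rep(c("tau1_", "logd2_", "logd3_"), J * 2),
                           rep(rep(seq_len(J), each = 3), 2), "_",
                           rep(COUNTRIES, each = 3 * J)),
                    "mu_uk")
  }
  out
}

#' @rdname pack_params
#' @param x unconstrained vector from [pack_params()].
#' @param template a parameter object supplying dimensions and labels.
#' @export
unpack_params <- function(x, template) {
  J <- n_items(template)
  if (inherits(template, "naive_params")) {
    stopifnot(length(x) == J + 3 * J + 1)
    lambda <- unname(x[seq_len(J)])
    tau <- unname(t(vapply(seq_len(J), function(j)
      tau_from_unc(x[J + (j - 1) * 3 + 1:3]), numeric(3))))
    naive_params(lambda, tau, unname(x[length(x)]))
  } else {
    V <- n_vignettes(template)
    stopifnot(length(x) == 2 * J + J * V + 6 * J + 1)
    lambda <- unname(x[seq_len(J)])
    gamma <- unname(x[J + seq_len(J)])
    beta <- matrix(x[2 * J + seq_len(J * V)], J, V,
                   dimnames = list(NULL, vignette_labels(template)))
    off <- 2 * J + J * V
    tau <- lapply(seq_len(2), function(ci) {
      unname(t(vapply(seq_len(J), function(j)
        tau_from_unc(x[off + (ci - 1) * 3 * J + (j - 1) * 3 + 1:3]),
        numeric(3))))
    })
    adjusted_params(lambda, gamma, beta,
                    list(IN = tau[[1]], UK = tau[[2]]), unname(x[length(x)]))
  }
}

# chain rule: natural tau gradient triple -> unconstrained triple
chain_tau_grad <- function(gt_nat, u) {
  d2 <- exp(u[2]); d3 <- exp(u[3])
  c(gt_nat[1] + gt_nat[2] + gt_nat[3],
    (gt_nat[2] + gt_nat[3]) * d2,
    gt_nat[3] * d3)
}

# assemble the unconstrained gradient from the compiled core's natural-scale
# gradients; x is the current unconstrained vector (for the log-increments)
grad_to_unconstrained <- function(res, x, template) {
  J <- n_items(template)
  if (inherits(template, "naive_params")) {
    gt <- numeric(3 * J)
    for (j in seq_len(J)) {
      u <- x[J + (j - 1) * 3 + 1:3]
      gt[(j - 1) * 3 + 1:3] <- chain_tau_grad(res$grad_tau[(j - 1) * 3 + 1:3], u)
    }
    c(res$grad_lambda, gt, res$grad_mu)
  } else {
    V <- n_vignettes(template)
    off <- 2 * J + J * V
    gt <- numeric(6 * J)
    for (ci in 0:1) for (j in seq_len(J)) {
      k <- ci * 3 * J + (j - 1) * 3
      u <- x[off + k + 1:3]
      gt[k + 1:3] <- chain_tau_grad(res$grad_tau[k + 1:3], u)
    }
    c(res$grad_lambda, res$grad_gamma, as.vector(res$grad_beta), gt,
      res$grad_mu)
  }
}

# ---- starting values -------------------------------------------------------

#' Starting values for model fitting
#'
#' Thresholds start at inverse-normal transforms of pooled cumulative
#' category proportions per (country, item) (per item pooled across
#' countries for the naive model), clamped to \[0.001, 0.999\] with a
#' warning when a category is never observed in a cell. Loadings start flat
#' (`lambda = 1`, and `gamma = 0.3` for the adjusted model); vignette
#' severities at the inverse-normal of each vignette's pooled exceedance of
#' the scale midpoint, placed against the starting thresholds; `mu_uk = 0`.
#'
#' @param data an oriented [av_dataset()].
#' @param model `"naive"` or `"adjusted"`.
#' @param n_items,vignettes dimensions of the parameter set to build.
#' @return a parameter object of the requested class.
#' @export
starting_values <- function(data, model = c("adjusted", "naive"),
                            n_items = 10L, vignettes = LETTERS[1:6]) {
  model <- match.arg(model)
  require_oriented(data)
  J <- n_items
  clamped <- FALSE
  cell_tau <- function(ratings) {
    # thresholds from inverse-normal cumulative proportions
    if (!length(ratings)) { clamped <<- TRUE; return(qnorm(c(0.25, 0.5, 0.75))) }
    cum <- cumsum(tabulate(ratings + 1L, 4L))[1:3] / length(ratings)
    p <- clamp(cum, 0.001, 0.999)
    if (any(p != cum)) clamped <<- TRUE
    tt <- qnorm(p)
    # enforce strict ordering when clamping produced ties
    for (k in 2:3) if (tt[k] <= tt[k - 1]) tt[k] <- tt[k - 1] + 1e-3
    tt
  }
  self <- data[data$source == "SELF", ]
  if (model == "naive") {
    tau <- t(vapply(seq_len(J), function(j)
      cell_tau(self$rating[self$item == j]), numeric(3)))
    if (clamped) warning("unobserved categories: clamped threshold starts")
    return(naive_params(lambda = rep(1, J), tau = tau, mu_uk = 0))
  }
  all_resp <- data
  tau <- lapply(COUNTRIES, function(cc) {
    t(vapply(seq_len(J), function(j)
      cell_tau(all_resp$rating[all_resp$country == cc & all_resp$item == j]),
      numeric(3)))
  })
  names(tau) <- COUNTRIES
  vig <- data[data$source == "VIGNETTE", ]
  V <- length(vignettes)
  tau_mid <- (tau$IN[, 2] + tau$UK[, 2]) / 2
  beta <- matrix(0, J, V, dimnames = list(NULL, vignettes))
  for (j in seq_len(J)) for (v in seq_len(V)) {
    r <- vig$rating[vig$item == j & vig$vignette == vignettes[v]]
    p_exceed <- if (length(r)) mean(r >= 2) else 0.5
    beta[j, v] <- tau_mid[j] + qnorm(clamp(p_exceed, 0.001, 0.999))
  }
  if (clamped) warning("unobserved categories: clamped threshold starts")
  adjusted_params(lambda = rep(1, J), gamma = rep(0.3, J), beta = beta,
                  tau = tau, mu_uk = 0)
}

# ---- fitting ---------------------------------------------------------------

#' Fitting options
#'
#' @param Q Gauss-Hermite nodes per latent dimension.
#' @param maxit maximum optimizer iterations.
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param grad_tol gradient infinity-norm below which the fit is declared
#'   converged.
#' @param trace optimizer trace level (0 = silent).
#' @return list of options.
#' @export
fit_control <- function(Q = 21, maxit = 1000, rel_tol = 1e-8,
                        grad_tol = 1e-4, trace = 0) {
  list(Q = Q, maxit = maxit, rel_tol = rel_tol, grad_tol = grad_tol,
       trace = trace)
}

# shared optimizer driver: template gives dims, frozen is a logical mask of
# unconstrained coordinates held at their starting values
run_mle <- function(arr, start, template, control, frozen = NULL) {
  quad <- ghq_rule(control$Q)
  x0 <- pack_params(start)
  if (is.null(frozen)) frozen <- rep(FALSE, length(x0))
  adjusted <- inherits(template, "adjusted_params")
  cache <- new.env(parent = emptyenv())
  cache$x <- NULL
  evaluate <- function(x) {
    if (!is.null(cache$x) && identical(x, cache$x)) return(invisible())
    x_full <- ifelse(frozen, x0, x)
    p <- unpack_params(x_full, template)
    res <- if (adjusted) loglik_adjusted(arr, p, quad, want_grad = TRUE)
           else loglik_naive(arr, p, quad, want_grad = TRUE)
    g <- grad_to_unconstrained(res, x_full, template)
    g[frozen] <- 0
    cache$x <- x
    cache$f <- -res$loglik
    cache$g <- -g
    invisible()
  }
  fn <- function(x) { evaluate(x); cache$f }
  gr <- function(x) { evaluate(x); cache$g }
  opt <- nlminb(x0, fn, gr,
                control = list(iter.max = control$maxit,
                               eval.max = 4 * control$maxit,
                               rel.tol = control$rel_tol,
                               trace = control$trace))
  x_hat <- ifelse(frozen, x0, opt$par)
  g_hat <- gr(opt$par)
  grad_norm <- max(abs(g_hat))
  converged <- opt$convergence == 0 || grad_norm < control$grad_tol
  list(x = x_hat, loglik = -opt$objective, iterations = opt$iterations,
       converged = converged, grad_norm = grad_norm,
       start_loglik = -fn(x0), message = opt$message)
}

# sign normalization: lambda[1] > 0 (flip theta: lambda, mu change sign);
# largest-|gamma| loading > 0 (flip eta: gamma changes sign)
normalize_signs <- function(params) {
  if (params$lambda[1] < 0) {
    params$lambda <- -params$lambda
    params$mu_uk <- -params$mu_uk
  }
  if (!is.null(params$gamma) && length(params$gamma)) {
    k <- which.max(abs(params$gamma))
    if (params$gamma[k] < 0) params$gamma <- -params$gamma
  }
  params
}

new_av_fit <- function(model, params, opt, control, data, n_persons) {
  structure(list(model = model, params = params, loglik = opt$loglik,
                 converged = opt$converged, iterations = opt$iterations,
                 grad_norm = opt$grad_norm, Q = control$Q,
                 start_loglik = opt$start_loglik, control = control,
                 data = data, n_persons = n_persons, se = NULL),
            class = "av_fit")
}

#' Fit the naive one-factor model by marginal maximum likelihood
#'
#' Maximizes the self-report likelihood over the item loadings, shared
#' thresholds and the UK mean, by quasi-Newton iteration with analytic
#' gradients. Vignette records in `data` are ignored (the naive model
#' describes self-reports only). Deterministic given data and starting
#' values.
#'
#' @param data an oriented [av_dataset()] with SELF records from both
#'   countries.
#' @param control a [fit_control()].
#' @param start optional [naive_params()] starting values.
#' @param n_items number of items.
#' @return an `av_fit` object.
#' @export
fit_naive <- function(data, control = fit_control(), start = NULL,
                      n_items = 10L) {
  require_oriented(data)
  self <- data[data$source == "SELF", ]
  if (length(unique(self$country)) < 2L)
    stop("mu_uk is inestimable: self-reports from a single country")
  self_data <- av_dataset(as.data.frame(self), oriented = TRUE)
  if (is.null(start))
    start <- starting_values(self_data, "naive", n_items = n_items)
  arr <- prepare_arrays(self_data, start)
  opt <- run_mle(arr, start, start, control)
  params <- normalize_signs(unpack_params(opt$x, start))
  new_av_fit("naive", params, opt, control, self_data, length(arr$persons))
}

#' Fit the vignette-adjusted two-factor model by marginal maximum likelihood
#'
#' Maximizes the full three-cohort likelihood over the depression and
#' response-style loadings, vignette severities, country-specific thresholds
#' and the UK mean, under the identification constraints (India depression
#' mean 0, both latent variances 1, loadings and severities shared across
#' countries). Integration uses a two-dimensional tensor Gauss-Hermite rule;
#' vignette-only persons' contributions are exact in the depression
#' dimension since their propensities do not involve it. A vignette never
#' rated in either country has its severity frozen at the starting value
#' (with a warning).
#'
#' @param data an oriented [av_dataset()] with SELF and VIGNETTE records
#'   from both countries.
#' @param control a [fit_control()].
#' @param start optional [adjusted_params()] starting values.
#' @param n_items,vignettes dimensions of the parameter set.
#' @return an `av_fit` object.
#' @export
fit_adjusted <- function(data, control = fit_control(), start = NULL,
                         n_items = 10L, vignettes = LETTERS[1:6]) {
  require_oriented(data)
  self <- data[data$source == "SELF", ]
  vig <- data[data$source == "VIGNETTE", ]
  if (length(unique(self$country)) < 2L)
    stop("adjusted model needs self-reports from both countries")
  if (nrow(vig) == 0L)
    stop("adjusted model needs vignette records")
  if (is.null(start))
    start <- starting_values(data, "adjusted", n_items = n_items,
                             vignettes = vignettes)
  J <- n_items(start); V <- n_vignettes(start)
  rated <- matrix(FALSE, J, V)
  rated[cbind(vig$item, match(vig$vignette, vignette_labels(start)))] <- TRUE
  frozen <- rep(FALSE, length(pack_params(start)))
  if (!all(rated)) {
    warning(sum(!rated), " (item, vignette) cell(s) never rated; ",
            "their severities are frozen at starting values")
    beta_idx <- 2 * J + seq_len(J * V)
    frozen[beta_idx[!as.vector(rated)]] <- TRUE
  }
  arr <- prepare_arrays(data, start)
  opt <- run_mle(arr, start, start, control, frozen = frozen)
  params <- normalize_signs(unpack_params(opt$x, start))
  new_av_fit("adjusted", params, opt, control, data, length(arr$persons))
}

#' @export
print.av_fit <- function(x, ...) {
  cat("av_fit:", x$model, "model,", x$n_persons, "persons\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " converged:", x$converged,
      " iterations:", x$iterations,
      " |grad|_inf:", format(x$grad_norm, digits = 3), "\n")
  cat("  mu_uk (UK - India latent depression mean):",
      format(x$params$mu_uk, digits = 4), "\n")
  invisible(x)
}
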