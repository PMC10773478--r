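# Standard errors, Wald intervals, standardized loadings, the country effect
# size d, and the between-country threshold-shift (DIF) table.

#' Standardize raw loadings
#'
#' For the adjusted model the self-report propensity variance is
#' `lambda^2 + gamma^2 + 1`, and both loadings are standardized against that
#' single per-item scale: `lambda* = lambda / sqrt(lambda^2 + gamma^2 + 1)`,
#' `gamma* = gamma / sqrt(lambda^2 + gamma^2 + 1)`. For the naive model
#' `lambda* = lambda / sqrt(lambda^2 + 1)`.
#'
#' @param params a [naive_params()] or [adjusted_params()] object.
#' @return list with `lambda_std` (and `gamma_std` for the adjusted model).
#' @export
standardized_loadings <- function(params) {
  if (inherits(params, "adjusted_params")) {
    s <- sqrt(params$lambda^2 + params$gamma^2 + 1)
    list(lambda_std = params$lambda / s, gamma_std = params$gamma / s)
  } else {
    s <- sqrt(params$lambda^2 + 1)
    list(lambda_std = params$lambda / s)
  }
}

#' Convert standardized loadings back to raw propensity-scale loadings
#'
#' Inverse of [standardized_loadings()]: with
#' `u = 1 - lambda_std^2 (- gamma_std^2)` the raw loadings are the
#' standardized ones divided by `sqrt(u)`. Requires `u > 0` (standardized
#' loadings must leave positive residual variance).
#'
#' @param lambda_std standardized depression loadings.
#' @param gamma_std standardized response-style loadings (omit for the naive
#'   model).
#' @return list with raw `lambda` (and `gamma` when supplied).
#' @export
destandardize_loadings <- function(lambda_std, gamma_std = NULL) {
  lambda_std <- as.numeric(lambda_std)
  u <- 1 - lambda_std^2
  if (!is.null(gamma_std)) {
    gamma_std <- as.numeric(gamma_std)
    stopifnot(length(gamma_std) == length(lambda_std))
    u <- u - gamma_std^2
  }
  if (any(u <= 0))
    stop("standardized loadings imply non-positive residual variance")
  s <- 1 / sqrt(u)
  out <- list(lambda = lambda_std * s)
  if (!is.null(gamma_std)) out$gamma <- gamma_std * s
  out
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the `(1 + level) / 2` normal quantile.
#'
#' @param estimate point estimate.
#' @param se standard error (`>= 0`).
#' @param level confidence level in `[0, 1)`.
#' @return named vector `c(lower, upper)`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (!is.finite(level) || level < 0 || level >= 1) stop("invalid level")
  if (!is.finite(se) || se < 0) stop("se must be nonnegative")
  z <- qnorm((1 + level) / 2)
  c(lower = estimate - z * se, upper = estimate + z * se)
}

#' Standard errors from the observed information matrix
#'
#' Differentiates the analytic score by central finite differences on the
#' unconstrained parameter scale to obtain the observed information, inverts
#' it, and maps to the natural scale by the delta method (numerical Jacobian
#' of the unpacking transform). If the information matrix is not positive
#' definite the standard errors are reported absent with a diagnostic,
#' never fabricated.
#'
#' @param fit an `av_fit` from [fit_naive()] or [fit_adjusted()].
#' @param eps finite-difference step.
#' @param diff `"central"` (default) or `"forward"` differencing of the
#'   score; forward halves the cost at a small accuracy loss, useful inside
#'   simulation loops.
#' @return named numeric vector of natural-scale standard errors (names as
#'   in [pack_params()], with `tau*`/`logd*` positions holding the natural
#'   thresholds' SEs), or `NULL` if the information is not invertible. The
#'   unconstrained-scale covariance is attached as attribute `"vcov_unc"`.
#' @export
standard_errors <- function(fit, eps = 1e-4, diff = c("central", "forward")) {
  diff <- match.arg(diff)
  stopifnot(inherits(fit, "av_fit"))
  if (!fit$converged)
    warning("standard errors at a non-converged solution")
  template <- fit$params
  arr <- prepare_arrays(fit$data, template)
  quad <- ghq_rule(fit$Q)
  adjusted <- fit$model == "adjusted"
  score <- function(x) {
    p <- unpack_params(x, template)
    res <- if (adjusted) loglik_adjusted(arr, p, quad, want_grad = TRUE)
           else loglik_naive(arr, p, quad, want_grad = TRUE)
    grad_to_unconstrained(res, x, template)
  }
  x_hat <- pack_params(fit$params)
  info <- if (diff == "central") -fd_jacobian(score, x_hat, eps = eps)
          else -fd_jacobian_fwd(score, x_hat, eps = eps)
  info <- (info + t(info)) / 2
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("observed information not positive definite; SEs unavailable")
    return(NULL)
  }
  vcov_unc <- solve(info)
  # natural parameter vector as a function of the unconstrained one
  natural <- function(x) {
    p <- unpack_params(x, template)
    if (adjusted) c(p$lambda, p$gamma, as.vector(p$beta), flatten_tau2(p$tau),
                    p$mu_uk)
    else c(p$lambda, as.vector(t(p$tau)), p$mu_uk)
  }
  Jac <- fd_jacobian(natural, x_hat, eps = 1e-6)
  se <- sqrt(pmax(diag(Jac %*% vcov_unc %*% t(Jac)), 0))
  names(se) <- names(x_hat)
  attr(se, "vcov_unc") <- vcov_unc
  se
}

# item-major per country, matching pack order of the tau block
flatten_tau2 <- function(tau) c(as.vector(t(tau$IN)), as.vector(t(tau$UK)))

#' Country effect size from a fitted model
#'
#' The UK-India latent depression mean difference `d = mu_uk` (India
#' reference, unit latent SD) with its Wald interval from the observed
#' information.
#'
#' @param fit an `av_fit`.
#' @param level confidence level.
#' @param se optional precomputed [standard_errors()] result (avoids
#'   recomputation).
#' @return an `effect_size` object: `d`, `se`, `level`, `lower`, `upper`.
#'   When the SE is unavailable the interval is absent and flagged.
#' @export
effect_size <- function(fit, level = 0.95, se = NULL) {
  stopifnot(inherits(fit, "av_fit"))
  d <- fit$params$mu_uk
  if (is.null(se)) se <- standard_errors(fit)
  if (is.null(se) || !"mu_uk" %in% names(se)) {
    warning("no standard error for mu_uk; interval unavailable")
    out <- list(d = d, se = NA_real_, level = level,
                lower = NA_real_, upper = NA_real_)
  } else {
    ci <- wald_ci(d, se[["mu_uk"]], level)
    out <- list(d = d, se = se[["mu_uk"]], level = level,
                lower = ci[["lower"]], upper = ci[["upper"]])
  }
  structure(out, class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("d = %.3f (%.0f%% CI: %.3f, %.3f), SE = %.4f\n",
              x$d, 100 * x$level, x$lower, x$upper, x$se))
  invisible(x)
}

#' Between-country threshold shifts (the DIF table)
#'
#' Signed differences `tau_UK - tau_IN` per item and threshold, summarizing
#' how the two countries cut the same latent propensity into response
#' categories. The attached summary flags the dominant pattern reported for
#' this design: UK thresholds 1 and 2 lower (less severity needed to move
#' off the bottom categories) with threshold 3 similar or higher.
#'
#' @param params [adjusted_params()].
#' @param tol tolerance for calling a shift "similar" (propensity units).
#' @return items x 3 matrix of shifts with attribute `"pattern"` (logical
#'   per item: threshold 1 lower, threshold 2 lower or similar, threshold 3
#'   similar or higher for the UK).
#' @export
threshold_shift <- function(params, tol = 0.35) {
  stopifnot(inherits(params, "adjusted_params"))
  shift <- params$tau$UK - params$tau$IN
  dimnames(shift) <- list(paste0("item", seq_len(nrow(shift))),
                          paste0("tau", 1:3))
  attr(shift, "pattern") <-
    shift[, 1] < 0 & shift[, 2] < tol & shift[, 3] > -tol
  shift
}
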