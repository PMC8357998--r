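# Multi-start maximum-likelihood fitting and delta-method standard errors.

default_fit_control <- function() {
  list(maxit = 500L,          # optimizer iteration cap
       rel_tol = 1e-10,       # relative -2LL convergence tolerance
       grad_tol = 1e-5,       # gradient tolerance (scaled, see below)
       jitter = 0.2)          # multiplicative start jitter
}

# Data-driven starting values: means and variances from first/last-occasion
# sample moments, self-feedback from the log-ratio of successive mean changes.
smart_start <- function(spec, X) {
  p <- spec$n_processes
  Tn <- spec$n_occasions
  ybar <- sapply(0:(Tn - 1L), function(t)
    colMeans(X[, t * p + seq_len(p), drop = FALSE], na.rm = TRUE))
  ybar <- matrix(ybar, nrow = p)   # p x T occasion means
  beta <- numeric(p)
  for (j in seq_len(p)) {
    d <- diff(ybar[j, ])
    r <- d[-1] / d[-length(d)]
    beta[j] <- if (all(is.finite(r)) && all(r > 0))
      max(-1.9, min(0.9, exp(mean(log(r))) - 1)) else -0.3
  }
  mu0 <- ybar[, 1]
  mua <- sapply(seq_len(p), function(j)
    mean(diff(ybar[j, ]) - beta[j] * ybar[j, -Tn]))
  v0 <- pmax(apply(X[, seq_len(p), drop = FALSE], 2, var, na.rm = TRUE),
             0.05)
  slope_var <- pmax(apply((X[, (Tn - 1L) * p + seq_len(p), drop = FALSE] -
                             X[, seq_len(p), drop = FALSE]) / (Tn - 1L),
                          2, var, na.rm = TRUE), 0.05)
  phi <- diag(c(0.7 * v0, 0.5 * slope_var), 2L * p)
  theta <- diag(0.3 * v0, p)
  psi <- if (spec$stochastic) diag(0.2 * v0, p) else NULL
  gamma <- if (p == 2L) c(0, 0) else NULL
  lcs_params(mu0, mua, phi, beta, gamma = gamma, theta = theta, psi = psi)
}

#' Fit a latent change score model by maximum likelihood
#'
#' Minimizes the full-information `-2` log-likelihood over the unconstrained
#' parameter space (see [to_unconstrained()]) with multiple jittered starts,
#' and returns the best converged solution with delta-method standard
#' errors on the natural scale, `-2LL`, AIC and BIC.  The run is
#' deterministic given `seed`.
#'
#' @param panel an `"lcs_panel"` or numeric matrix (columns in time-major
#'   panel order, `NA` for missing).
#' @param spec an [lcs_spec()] describing the model to estimate.
#' @param start optional [lcs_params()] used as the first start; further
#'   starts jitter it.  Default: data-driven moments-based start.
#' @param n_starts number of optimization starts (default 5).
#' @param seed integer seed for the start jitter.
#' @param control list overriding [default_fit_control()] entries
#'   (`maxit`, `rel_tol`, `grad_tol`, `jitter`).
#' @return An object of class `"lcs_fit"`; see [summary.lcs_fit()].
#' @examples
#' fx <- lcs_fixture("fig4_medium_seb", n = 80, seed = 7)
#' fit <- lcs_fit(fx$panel, fx$spec, n_starts = 2)
#' coef(fit)
#' @export
lcs_fit <- function(panel, spec, start = NULL, n_starts = 5L, seed = 1L,
                    control = list()) {
  stopifnot(inherits(spec, "lcs_spec"))
  ctrl <- modifyList(default_fit_control(), control)
  X <- panel_matrix(panel)
  N <- nrow(X)
  k <- count_free_parameters(spec)
  if (N < k)
    warning(sprintf("only %d individuals for %d free parameters", N, k),
            call. = FALSE)
  if (spec$n_occasions == 3L)
    warning("3 occasions is the minimum; dual-change parameters may be ",
            "weakly identified", call. = FALSE)
  if (is.null(start)) start <- smart_start(spec, X)
  v0 <- to_unconstrained(spec, start)
  stats <- suppressWarnings(panel_suffstats(X))  # grouped once, reused per eval
  objective <- function(v) {
    out <- tryCatch(
      suppressWarnings(
        m2ll_from_stats(implied_moments(spec, from_unconstrained(v, spec)),
                        stats)),
      error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    if (s == 1L) v0
    else v0 * (1 + runif(length(v0), -ctrl$jitter, ctrl$jitter)) +
      runif(length(v0), -0.05, 0.05) * (abs(v0) < 1e-8)
  }))
  best <- NULL
  n_used <- 0L
  for (v in starts) {
    n_used <- n_used + 1L
    res <- tryCatch(
      nlminb(v, objective,
             control = list(iter.max = ctrl$maxit, eval.max = 10L * ctrl$maxit,
                            rel.tol = ctrl$rel_tol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best) || best$objective >= 1e10) {
    fit <- empty_fit(spec, start, N, k, n_used)
    return(fit)
  }
  vhat <- best$par
  grad <- num_gradient(function(v) objective(v) / 2, vhat)
  gradient_norm <- max(abs(grad))
  # absolute-plus-relative gradient tolerance on the -2LL/2 surface
  grad_ok <- gradient_norm < ctrl$grad_tol * max(1, abs(best$objective) / 2)
  converged <- best$convergence == 0L && grad_ok &&
    best$iterations < ctrl$maxit
  estimates <- from_unconstrained(vhat, spec)
  minus2ll <- best$objective
  se <- se_cov <- NULL
  se_ok <- FALSE
  if (converged) {
    sed <- delta_method_se(spec, vhat, objective)
    se <- sed$se; se_cov <- sed$vcov; se_ok <- sed$ok
  }
  M <- diag(spec$n_processes) + dynamics_matrix(estimates)
  structure(list(
    spec = spec, estimates = estimates,
    coefficients = params_to_vector(spec, estimates),
    unconstrained = vhat,
    minus2ll = minus2ll, aic = minus2ll + 2 * k,
    bic = minus2ll + k * log(N),
    n = N, k = k, se = se, se_ok = se_ok, vcov = se_cov,
    converged = converged, n_starts_used = n_used,
    gradient_norm = gradient_norm,
    explosive = max(abs(as.complex(eigen(M, only.values = TRUE)$values))) > 1,
    panel = if (inherits(panel, "lcs_panel")) panel else NULL),
    class = "lcs_fit")
}

empty_fit <- function(spec, start, N, k, n_used) {
  structure(list(spec = spec, estimates = start,
                 coefficients = params_to_vector(spec, start),
                 unconstrained = to_unconstrained(spec, start),
                 minus2ll = NA_real_, aic = NA_real_, bic = NA_real_,
                 n = N, k = k, se = NULL, se_ok = FALSE, vcov = NULL,
                 converged = FALSE, n_starts_used = n_used,
                 gradient_norm = NA_real_, explosive = NA, panel = NULL),
            class = "lcs_fit")
}

# Delta-method SEs: numeric Hessian of -2LL/2 in unconstrained coordinates,
# inverted and pushed through the Jacobian of the natural-scale map.
delta_method_se <- function(spec, vhat, objective) {
  H <- tryCatch(optimHess(vhat, function(v) objective(v) / 2),
                error = function(e) NULL)
  fail <- list(se = NULL, vcov = NULL, ok = FALSE)
  if (is.null(H)) return(fail)
  V <- tryCatch(chol2inv(chol(symmetrize(H))), error = function(e) NULL)
  if (is.null(V)) {
    warning("Hessian not positive definite at the optimum; ",
            "standard errors withheld", call. = FALSE)
    return(fail)
  }
  J <- num_jacobian(function(v)
    unname(params_to_vector(spec, from_unconstrained(v, spec))), vhat)
  Vn <- J %*% V %*% t(J)
  se <- sqrt(pmax(diag(Vn), 0))
  nm <- param_names(spec)
  list(se = setNames(se, nm),
       vcov = `dimnames<-`(Vn, list(nm, nm)), ok = TRUE)
}

#' Delta-method standard errors of a fitted model
#'
#' Recomputes the per-parameter standard errors from the numeric Hessian of
#' the negative log-likelihood at the optimum, mapped to the natural scale.
#'
#' @param spec an [lcs_spec()].
#' @param fit an [lcs_fit()] result.
#' @param panel the panel the model was fitted to.
#' @return named numeric vector of standard errors (or `NULL` with a warning
#'   when the Hessian is not positive definite).
#' @export
standard_errors <- function(spec, fit, panel) {
  stopifnot(inherits(fit, "lcs_fit"))
  X <- panel_matrix(panel)
  objective <- function(v)
    suppressWarnings(minus_two_loglik(spec, from_unconstrained(v, spec), X))
  delta_method_se(spec, fit$unconstrained, objective)$se
}

#' @export
print.lcs_fit <- function(x, digits = 4, ...) {
  kind <- if (x$spec$n_processes == 1L) "univariate" else "bivariate"
  if (x$spec$stochastic) kind <- paste("stochastic", kind)
  cat(sprintf("Latent change score fit (%s, %d free parameters)\n",
              kind, x$k))
  cat(sprintf("  N = %d, -2LL = %s, AIC = %s, BIC = %s\n", x$n,
              format(x$minus2ll, digits = 8), format(x$aic, digits = 8),
              format(x$bic, digits = 8)))
  cat(sprintf("  converged: %s (gradient norm %s, %d start(s))\n",
              x$converged, format(x$gradient_norm, digits = 3),
              x$n_starts_used))
  if (isTRUE(x$explosive))
    cat("  note: fitted dynamics are explosive (spectral radius > 1)\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarize a fitted latent change score model
#'
#' @param object an [lcs_fit()] result.
#' @param ... unused.
#' @return A `"summary.lcs_fit"` object with a coefficient table (estimate,
#'   standard error, z, p) and fit statistics.
#' @export
summary.lcs_fit <- function(object, ...) {
  est <- object$coefficients
  if (!is.null(object$se)) {
    z <- est / object$se
    tab <- cbind(Estimate = est, `Std. Error` = object$se, z = z,
                 `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  } else {
    tab <- cbind(Estimate = est)
  }
  structure(list(table = tab, minus2ll = object$minus2ll, aic = object$aic,
                 bic = object$bic, n = object$n, k = object$k,
                 converged = object$converged, spec = object$spec),
            class = "summary.lcs_fit")
}

#' @export
print.summary.lcs_fit <- function(x, digits = 4, ...) {
  cat("Latent change score model fit\n\n")
  printCoefmat(x$table, digits = digits, has.Pvalue = ncol(x$table) == 4)
  cat(sprintf("\n-2LL = %s on %d free parameters (N = %d)\n",
              format(x$minus2ll, digits = 8), x$k, x$n))
  cat(sprintf("AIC = %s, BIC = %s, converged: %s\n",
              format(x$aic, digits = 8), format(x$bic, digits = 8),
              x$converged))
  invisible(x)
}

#' @importFrom stats printCoefmat
#' @export
coef.lcs_fit <- function(object, ...) object$coefficients

#' @export
vcov.lcs_fit <- function(object, ...) object$vcov

#' @export
logLik.lcs_fit <- function(object, ...) {
  structure(-object$minus2ll / 2, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Predicted mean trajectory of a fitted model
#'
#' @param object an [lcs_fit()] result.
#' @param horizon number of changes to project (default: the fitted number
#'   of occasions minus one).
#' @param ... unused.
#' @return An `"lcs_trajectory"` object at the estimated parameters.
#' @export
predict.lcs_fit <- function(object, horizon = object$spec$n_occasions - 1L,
                            ...) {
  mean_trajectory(object$spec, object$estimates, horizon = horizon)
}

#' Simulate panels from a fitted model
#'
#' @param object an [lcs_fit()] result.
#' @param nsim number of panels.
#' @param seed integer seed.
#' @param n individuals per panel (default: fitted sample size).
#' @param ... unused.
#' @return A list of `"lcs_panel"` objects (a single panel if `nsim = 1`).
#' @export
simulate.lcs_fit <- function(object, nsim = 1, seed = 1L, n = object$n,
                             ...) {
  seeds <- derive_seeds(seed, nsim)
  out <- lapply(seq_len(nsim), function(s)
    simulate_panel(object$spec, object$estimates, n = n, seed = seeds[s]))
  if (nsim == 1) out[[1]] else out
}

#' @export
fitted.lcs_fit <- function(object, ...) {
  mu <- implied_moments(object$spec, object$estimates)$mean
  matrix(mu, nrow = object$n, ncol = length(mu), byrow = TRUE,
         dimnames = list(NULL, names(mu)))
}

#' @export
residuals.lcs_fit <- function(object, ...) {
  if (is.null(object$panel))
    stop("fit does not carry its panel; residuals unavailable",
         call. = FALSE)
  object$panel$observed - fitted(object)
}

#' @export
plot.lcs_fit <- function(x, ...) {
  if (is.null(x$panel)) stop("fit does not carry its panel", call. = FALSE)
  p <- x$spec$n_processes
  Tn <- x$spec$n_occasions
  obs_means <- matrix(colMeans(x$panel$observed, na.rm = TRUE),
                      nrow = Tn, byrow = TRUE)
  traj <- predict(x)
  matplot(0:(Tn - 1L), obs_means, pch = 16, col = seq_len(p),
          xlab = "occasion", ylab = "level", ...)
  for (j in seq_len(p))
    lines(traj$times, traj$levels[, j], col = j)
  legend("topleft", legend = paste0(process_names(x$spec),
                                    c(" (observed mean / implied)")),
         col = seq_len(p), lty = 1, pch = 16, bty = "n")
  invisible(x)
}
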