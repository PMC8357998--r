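#' Population parameters of a latent change score model
#'
#' Containers for the population parameters of univariate or bivariate LCS
#' models.  The random-effect vector of an individual is ordered
#' *(initial levels, additive components)*; for a bivariate model that is
#' `(x0, y0, xa, ya)`, and `phi` follows the same ordering.
#'
#' @param mu0 numeric length-`p` vector of initial-level means.
#' @param mua numeric length-`p` vector of additive-component means.
#' @param phi `2p x 2p` symmetric PSD covariance of the random effects.
#' @param beta numeric length-`p` vector of self-feedbacks.
#' @param gamma couplings `c(gamma_x, gamma_y)` (`gamma_x`: level of y ->
#'   change of x; `gamma_y`: level of x -> change of y); bivariate only,
#'   `NULL` otherwise.
#' @param theta `p x p` symmetric PSD measurement-error covariance.
#' @param psi `p x p` symmetric PSD innovation covariance (stochastic models
#'   only), `NULL` otherwise.
#'
#' @return An object of class `"lcs_params"`.
#' @seealso [validate_params()], [lcs_spec()]
#' @examples
#' lcs_params(mu0 = 0, mua = 2, phi = diag(c(10, 0.5)),
#'            beta = -0.4, theta = 0.25)
#' @export
lcs_params <- function(mu0, mua, phi, beta, gamma = NULL, theta, psi = NULL) {
  mu0 <- as.numeric(mu0); mua <- as.numeric(mua); beta <- as.numeric(beta)
  p <- length(mu0)
  if (!p %in% 1:2) stop("'mu0' must have length 1 or 2", call. = FALSE)
  if (length(mua) != p || length(beta) != p)
    stop("'mu0', 'mua' and 'beta' must have a common length", call. = FALSE)
  phi <- as_square_matrix(phi, "phi")
  if (nrow(phi) != 2L * p)
    stop(sprintf("'phi' must be %d x %d", 2 * p, 2 * p), call. = FALSE)
  theta <- as_square_matrix(theta, "theta")
  if (nrow(theta) != p)
    stop(sprintf("'theta' must be %d x %d", p, p), call. = FALSE)
  if (!is.null(gamma)) {
    gamma <- as.numeric(gamma)
    if (p == 1L) stop("'gamma' applies to bivariate models only",
                      call. = FALSE)
    if (length(gamma) != 2L)
      stop("'gamma' must be c(gamma_x, gamma_y)", call. = FALSE)
  }
  if (!is.null(psi)) {
    psi <- as_square_matrix(psi, "psi")
    if (nrow(psi) != p)
      stop(sprintf("'psi' must be %d x %d", p, p), call. = FALSE)
  }
  if (!all(is.finite(c(mu0, mua, beta, phi, theta, gamma, psi))))
    stop("parameters must be finite", call. = FALSE)
  structure(list(mu0 = mu0, mua = mua, phi = symmetrize(phi), beta = beta,
                 gamma = gamma, theta = symmetrize(theta),
                 psi = if (is.null(psi)) NULL else symmetrize(psi)),
            class = "lcs_params")
}

n_proc <- function(params) length(params$mu0)

#' Validate a parameter set against a model specification
#'
#' Checks dimension agreement with the specification, positive
#' semi-definiteness of `phi`, `theta` and `psi` (eigenvalues above
#' `-1e-10`), and the structural pairing rules: `psi` is present exactly for
#' stochastic specifications, `gamma` exactly for bivariate ones.  Validation
#' is idempotent: it returns the parameter set unchanged when all invariants
#' hold.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @return `params`, unchanged, invisibly passed through on success.
#' @export
validate_params <- function(spec, params) {
  stopifnot(inherits(spec, "lcs_spec"), inherits(params, "lcs_params"))
  p <- spec$n_processes
  if (n_proc(params) != p)
    stop(sprintf("parameters are for %d process(es) but spec has %d",
                 n_proc(params), p), call. = FALSE)
  stop_if_not_psd(params$phi, "phi")
  stop_if_not_psd(params$theta, "theta")
  if (spec$stochastic) {
    if (is.null(params$psi))
      stop("stochastic specification requires an innovation covariance 'psi'",
           call. = FALSE)
    stop_if_not_psd(params$psi, "psi")
  } else if (!is.null(params$psi)) {
    stop("'psi' supplied for a deterministic specification", call. = FALSE)
  }
  if (p == 2L) {
    if (is.null(params$gamma))
      stop("bivariate specification requires couplings 'gamma'",
           call. = FALSE)
    fixed <- !spec$free_couplings & params$gamma != 0
    if (any(fixed))
      stop("non-zero coupling supplied where 'free_couplings' fixes it to 0",
           call. = FALSE)
  } else if (!is.null(params$gamma)) {
    stop("'gamma' supplied for a univariate specification", call. = FALSE)
  }
  params
}

# Discrete-time dynamics matrix A: diagonal self-feedbacks, off-diagonal
# couplings.  Row 1 is the change equation of x: dx = xa + beta_x x + gamma_x y.
dynamics_matrix <- function(params) {
  p <- n_proc(params)
  A <- diag(params$beta, p, p)
  if (p == 2L && !is.null(params$gamma)) {
    A[1, 2] <- params$gamma[1]
    A[2, 1] <- params$gamma[2]
  }
  A
}

effect_names <- function(p) {
  pn <- if (p == 1L) "y" else c("x", "y")
  c(paste0(pn, "0"), paste0(pn, "a"))
}

# Names of the free parameters on the natural scale, in canonical order:
# means, vech(phi), dynamics, theta, psi.
param_names <- function(spec) {
  p <- spec$n_processes
  pn <- process_names(spec)
  en <- effect_names(p)
  nm <- c(paste0("mu_", en))
  idx <- which(lower.tri(diag(2 * p), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  nm <- c(nm, sprintf("phi_%s_%s", en[idx[, 1]], en[idx[, 2]]))
  nm <- c(nm, paste0("beta_", pn))
  if (p == 2L) nm <- c(nm, c("gamma_x", "gamma_y")[spec$free_couplings])
  nm <- c(nm, paste0("theta_", pn))
  if (p == 2L && spec$error_covariance) nm <- c(nm, "theta_xy")
  if (spec$stochastic) {
    nm <- c(nm, paste0("psi_", pn))
    if (p == 2L && spec$innovation_covariance) nm <- c(nm, "psi_xy")
  }
  nm
}

# Natural-scale free-parameter vector in the canonical order above.
params_to_vector <- function(spec, params) {
  p <- spec$n_processes
  v <- c(params$mu0, params$mua,
         params$phi[lower.tri(params$phi, diag = TRUE)],
         params$beta)
  if (p == 2L) v <- c(v, params$gamma[spec$free_couplings])
  v <- c(v, diag(params$theta))
  if (p == 2L && spec$error_covariance) v <- c(v, params$theta[1, 2])
  if (spec$stochastic) {
    v <- c(v, diag(params$psi))
    if (p == 2L && spec$innovation_covariance) v <- c(v, params$psi[1, 2])
  }
  setNames(v, param_names(spec))
}

#' @export
print.lcs_params <- function(x, digits = 4, ...) {
  p <- n_proc(x)
  pn <- if (p == 1L) "y" else c("x", "y")
  cat(sprintf("LCS parameters (%d process%s)\n", p, if (p > 1) "es" else ""))
  cat("  mu0:", format(x$mu0, digits = digits),
      " mua:", format(x$mua, digits = digits), "\n")
  cat("  beta:", format(x$beta, digits = digits))
  if (!is.null(x$gamma))
    cat("  gamma:", format(x$gamma, digits = digits))
  cat("\n  phi:\n")
  print(round(x$phi, digits))
  cat("  theta:\n")
  print(round(x$theta, digits))
  if (!is.null(x$psi)) {
    cat("  psi:\n")
    print(round(x$psi, digits))
  }
  invisible(x)
}
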