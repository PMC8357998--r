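# Bijection between the free parameters and an unconstrained optimization
# space: means and dynamics enter as-is; covariance blocks through Cholesky
# factors with logged diagonal, which guarantees positive (semi-)definiteness
# for any input vector.

# vech of the lower triangle of a Cholesky-log factor
chol_to_free <- function(S, jitter = 1e-10) {
  U <- tryCatch(chol(S), error = function(e)
    chol(S + diag(jitter * max(1, max(abs(diag(S)))), nrow(S))))
  L <- t(U)
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

free_to_cov <- function(v, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- v
  diag(L) <- exp(diag(L))
  L %*% t(L)
}

#' Map parameters to and from the unconstrained optimization space
#'
#' `to_unconstrained()` flattens a parameter set into a real vector of
#' length [count_free_parameters()]: means and dynamic coefficients enter
#' untransformed; each covariance block (`phi`, `theta`, `psi`) enters as
#' its Cholesky factor with logged diagonal (single variances as log
#' variance).  `from_unconstrained()` inverts the map, so any real vector
#' yields a valid (PSD) parameter set.  The two are mutually inverse to
#' numerical precision for positive-definite inputs.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param v numeric vector of length [count_free_parameters()].
#' @return `to_unconstrained()`: a numeric vector; `from_unconstrained()`:
#'   an [lcs_params()].
#' @export
to_unconstrained <- function(spec, params) {
  validate_params(spec, params)
  p <- spec$n_processes
  v <- c(params$mu0, params$mua, chol_to_free(params$phi), params$beta)
  if (p == 2L) v <- c(v, params$gamma[spec$free_couplings])
  v <- c(v, theta_block_to_free(params$theta, spec$error_covariance))
  if (spec$stochastic)
    v <- c(v, theta_block_to_free(params$psi, spec$innovation_covariance))
  stopifnot(length(v) == count_free_parameters(spec))
  unname(v)
}

theta_block_to_free <- function(S, with_cov) {
  if (nrow(S) == 1L) return(log(S[1, 1]))
  if (with_cov) chol_to_free(S) else log(diag(S))
}

free_to_theta_block <- function(v, p, with_cov) {
  if (p == 1L) return(matrix(exp(v), 1, 1))
  if (with_cov) free_to_cov(v, 2L) else diag(exp(v), 2L)
}

#' @rdname to_unconstrained
#' @export
from_unconstrained <- function(v, spec) {
  p <- spec$n_processes
  k <- count_free_parameters(spec)
  if (length(v) != k)
    stop(sprintf("expected %d free parameters, got %d", k, length(v)),
         call. = FALSE)
  take <- function(n) {
    out <- v[seq_len(n)]
    v <<- v[-seq_len(n)]
    out
  }
  mu0 <- take(p); mua <- take(p)
  phi <- free_to_cov(take(p * (2L * p + 1L)), 2L * p)
  beta <- take(p)
  gamma <- NULL
  if (p == 2L) {
    gamma <- c(0, 0)
    nfree <- sum(spec$free_couplings)
    if (nfree > 0L) gamma[spec$free_couplings] <- take(nfree)
  }
  theta <- free_to_theta_block(take(theta_block_len(p, spec$error_covariance)),
                               p, spec$error_covariance)
  psi <- NULL
  if (spec$stochastic)
    psi <- free_to_theta_block(
      take(theta_block_len(p, spec$innovation_covariance)),
      p, spec$innovation_covariance)
  lcs_params(mu0, mua, phi, beta, gamma = gamma, theta = theta, psi = psi)
}

theta_block_len <- function(p, with_cov) {
  if (p == 1L) 1L else if (with_cov) 3L else 2L
}
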