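# Model-implied moments of the stacked observed vector, built by explicit
# accumulation algebra from the change recursion.

#' Loading matrix from random effects to latent levels
#'
#' Closed-form accumulation of the change recursion: the latent level at
#' occasion `t` is a linear function of the random effects,
#' `level[t] = M^t %*% level0 + (sum_{k=0}^{t-1} M^k) %*% additive`, with
#' `M = I + A`.  Univariate rows are `((1+beta)^t, ((1+beta)^t - 1)/beta)`
#' with the `beta -> 0` limit `(1, t)`.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @return `(p*T) x 2p` matrix mapping `(initial levels, additive
#'   components)` to the stacked latent levels (time-major row order).
#' @export
loading_matrix <- function(spec, params) {
  validate_params(spec, params)
  p <- spec$n_processes
  Tn <- spec$n_occasions
  M <- diag(p) + dynamics_matrix(params)
  L <- matrix(0, p * Tn, 2L * p)
  Mt <- diag(p)          # M^t
  St <- matrix(0, p, p)  # sum_{k=0}^{t-1} M^k
  for (t in 0:(Tn - 1L)) {
    rows <- t * p + seq_len(p)
    L[rows, seq_len(p)] <- Mt
    L[rows, p + seq_len(p)] <- St
    St <- St + Mt
    Mt <- M %*% Mt
  }
  dimnames(L) <- list(panel_colnames(process_names(spec), 0:(Tn - 1L)),
                      effect_names(p))
  L
}

#' Model-implied mean and covariance of the observed vector
#'
#' The observed vector stacks the `p` processes at `T` occasions
#' (time-major).  Its implied mean is `L %*% c(mu0, mua)` and its covariance
#' `L %*% phi %*% t(L) + Q + R`, where `L` is the [loading_matrix()], `Q`
#' accumulates innovation variance propagated through the dynamics
#' (`Q[t,s] = sum_{k=1}^{min(t,s)} M^{t-k} psi t(M^{s-k})`; zero for
#' deterministic models) and `R` places the measurement-error covariance
#' `theta` on each occasion's block diagonal.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @return An object of class `"lcs_moments"`: list with `mean` (length
#'   `p*T`) and `covariance` (`(p*T) x (p*T)`, symmetric PSD).
#' @export
implied_moments <- function(spec, params) {
  validate_params(spec, params)
  p <- spec$n_processes
  Tn <- spec$n_occasions
  L <- loading_matrix(spec, params)
  mu <- drop(L %*% c(params$mu0, params$mua))
  Sigma <- L %*% params$phi %*% t(L)
  # innovation accumulation: C[t,t] = M C[t-1,t-1] M' + psi,
  # C[t,s] = C[t,t] (M^{s-t})' for s > t
  if (spec$stochastic) {
    M <- diag(p) + dynamics_matrix(params)
    Q <- matrix(0, p * Tn, p * Tn)
    Ctt <- matrix(0, p, p)
    for (t in 1:(Tn - 1L)) {
      Ctt <- M %*% Ctt %*% t(M) + params$psi
      rows <- t * p + seq_len(p)
      Q[rows, rows] <- Ctt
      Cts <- Ctt
      if (t < Tn - 1L) for (s in (t + 1L):(Tn - 1L)) {
        Cts <- Cts %*% t(M)
        cols <- s * p + seq_len(p)
        Q[rows, cols] <- Cts
        Q[cols, rows] <- t(Cts)
      }
    }
    Sigma <- Sigma + Q
  }
  R <- diag(Tn) %x% params$theta
  Sigma <- symmetrize(Sigma + R)
  nm <- rownames(L)
  structure(list(mean = setNames(mu, nm),
                 covariance = `dimnames<-`(Sigma, list(nm, nm)),
                 processes = process_names(spec),
                 occasions = 0:(Tn - 1L)),
            class = "lcs_moments")
}

#' @export
print.lcs_moments <- function(x, digits = 4, ...) {
  cat(sprintf("Model-implied moments of a %d-dimensional observed vector\n",
              length(x$mean)))
  cat("  mean:", format(x$mean, digits = digits), "\n")
  cat("  covariance (leading block):\n")
  k <- min(4, nrow(x$covariance))
  print(round(x$covariance[1:k, 1:k, drop = FALSE], digits))
  invisible(x)
}

#' Monte-Carlo moments of a simulated panel
#'
#' Brute-force empirical counterpart of [implied_moments()]: simulates a
#' panel and returns its sample mean vector and covariance matrix.  Used as
#' an independent oracle for the analytic moments.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param n Monte-Carlo sample size (at least 2).
#' @param seed integer seed.
#' @return list with `mean` and `covariance`.
#' @export
mc_moments <- function(spec, params, n, seed = 1L) {
  stopifnot(n >= 2)
  panel <- simulate_panel(spec, params, n = n, seed = seed)
  list(mean = colMeans(panel$observed), covariance = cov(panel$observed))
}
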