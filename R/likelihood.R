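# Gaussian full-information likelihood (casewise, missing-data tolerant)
# and an independent Kalman-filter route for cross-validation.

#' Log-likelihood of one observed row under implied moments
#'
#' Evaluates the multivariate-normal log density of the observed entries of
#' `row` under the matching marginal (subvector/submatrix) of the implied
#' moments; missing entries are marginalized out, which is the casewise
#' full-information treatment of missing data.
#'
#' @param row numeric vector of length `p*T`, `NA` for missing.
#' @param moments an [implied_moments()] result.
#' @return scalar log-likelihood.
#' @export
row_loglik <- function(row, moments) {
  stopifnot(inherits(moments, "lcs_moments"))
  obs <- !is.na(row)
  m <- sum(obs)
  if (m == 0L) stop("row has no observed entries", call. = FALSE)
  mu <- moments$mean[obs]
  S <- moments$covariance[obs, obs, drop = FALSE]
  U <- safe_chol(S)
  z <- backsolve(U, row[obs] - mu, transpose = TRUE)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

#' Minus two log-likelihood of a panel (full-information route)
#'
#' Sums [row_loglik()] over individuals, grouping rows by missingness
#' pattern so each marginal covariance is factorized once.  Rows with no
#' observed entries are dropped with a warning.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param panel an `"lcs_panel"` or a plain numeric matrix in the panel's
#'   column order.
#' @return scalar `-2 * logLik`.
#' @seealso [kalman_loglik()] for the independent state-space route.
#' @export
minus_two_loglik <- function(spec, params, panel) {
  X <- panel_matrix(panel)
  moments <- implied_moments(spec, params)
  if (ncol(X) != length(moments$mean))
    stop("panel has ", ncol(X), " columns but the model implies ",
         length(moments$mean), call. = FALSE)
  m2ll_from_stats(moments, panel_suffstats(X))
}

# Group rows by missingness pattern and reduce each group to its sufficient
# statistics (count, mean, ML scatter about the group mean); the likelihood
# then costs O(patterns), not O(N), per evaluation.
panel_suffstats <- function(X) {
  all_missing <- rowSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " row(s) with no observed entries dropped",
            call. = FALSE)
    X <- X[!all_missing, , drop = FALSE]
  }
  miss <- is.na(X)
  pat <- apply(miss, 1L, function(z) paste(as.integer(z), collapse = ""))
  lapply(split(seq_len(nrow(X)), pat), function(rows) {
    obs <- !miss[rows[1], ]
    Y <- X[rows, obs, drop = FALSE]
    xbar <- colMeans(Y)
    Yc <- sweep(Y, 2, xbar)
    list(obs = obs, n = length(rows), xbar = xbar,
         scatter = crossprod(Yc) / length(rows))
  })
}

m2ll_from_stats <- function(moments, stats) {
  m2ll <- 0
  for (g in stats) {
    m <- sum(g$obs)
    S <- moments$covariance[g$obs, g$obs, drop = FALSE]
    U <- safe_chol(S)
    Sinv <- chol2inv(U)
    dev <- g$xbar - moments$mean[g$obs]
    m2ll <- m2ll + g$n * (m * log(2 * pi) + 2 * sum(log(diag(U))) +
                            sum(Sinv * g$scatter) +
                            drop(dev %*% Sinv %*% dev))
  }
  m2ll
}

panel_matrix <- function(panel) {
  if (inherits(panel, "lcs_panel")) panel$observed
  else if (is.matrix(panel)) panel
  else stop("'panel' must be an lcs_panel or a numeric matrix",
            call. = FALSE)
}

#' Minus two log-likelihood via the Kalman filter
#'
#' Independent state-space evaluation of the same likelihood: the state is
#' `(latent levels, additive components)` with transition
#' `[[M, I], [0, I]]`, innovations as process noise on the level block, and
#' measurement error as observation noise.  Missing observations are handled
#' by dropping the corresponding observation rows at each step.  Agrees with
#' [minus_two_loglik()] to numerical precision on any valid input.
#'
#' @inheritParams minus_two_loglik
#' @return scalar `-2 * logLik`.
#' @export
kalman_loglik <- function(spec, params, panel) {
  validate_params(spec, params)
  X <- panel_matrix(panel)
  p <- spec$n_processes
  Tn <- spec$n_occasions
  if (ncol(X) != p * Tn)
    stop("panel has ", ncol(X), " columns but the model implies ", p * Tn,
         call. = FALSE)
  all_missing <- rowSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " row(s) with no observed entries dropped",
            call. = FALSE)
    X <- X[!all_missing, , drop = FALSE]
  }
  M <- diag(p) + dynamics_matrix(params)
  d <- 2L * p
  Fm <- rbind(cbind(M, diag(p)), cbind(matrix(0, p, p), diag(p)))
  Qm <- matrix(0, d, d)
  if (spec$stochastic) Qm[seq_len(p), seq_len(p)] <- params$psi
  H <- cbind(diag(p), matrix(0, p, p))
  R <- params$theta
  a0 <- c(params$mu0, params$mua)
  P0 <- params$phi
  ll <- 0
  for (i in seq_len(nrow(X))) {
    a <- a0; P <- P0
    for (t in 0:(Tn - 1L)) {
      if (t > 0L) {             # predict
        a <- drop(Fm %*% a)
        P <- Fm %*% P %*% t(Fm) + Qm
      }
      yt <- X[i, t * p + seq_len(p)]
      obs <- !is.na(yt)
      if (any(obs)) {           # update on the observed components
        Ho <- H[obs, , drop = FALSE]
        v <- yt[obs] - drop(Ho %*% a)
        S <- Ho %*% P %*% t(Ho) + R[obs, obs, drop = FALSE]
        U <- safe_chol(S)
        z <- backsolve(U, v, transpose = TRUE)
        ll <- ll - 0.5 * (sum(obs) * log(2 * pi) +
                            2 * sum(log(diag(U))) + sum(z^2))
        K <- P %*% t(Ho) %*% chol2inv(U)
        a <- a + drop(K %*% v)
        P <- P - K %*% Ho %*% P
        P <- symmetrize(P)
      }
    }
  }
  -2 * ll
}
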