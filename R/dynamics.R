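# Closed-form trajectory algebra: exponential solutions, asymptote
# identities, continuous-/discrete-time conversion, mean recursions and
# fixed points.

#' Exponential trajectory level
#'
#' Evaluates the exponential solution of the continuous-time dual change
#' model,
#' \deqn{y(t) = y_{As} - (y_{As} - y(t_0))\, e^{-r t},}
#' where `asymptote` is the level the trajectory flattens to, `initial` the
#' level at `t = 0`, and `rate` the speed at which the gap to the asymptote
#' shrinks (`rate > 0`, decelerated change) or grows (`rate < 0`, accelerated
#' change).
#'
#' @param asymptote,initial,rate scalars.
#' @param time numeric vector of times.
#' @return numeric vector of levels.
#' @examples
#' exponential_level(5, 0, 4, 0:3)     # decelerated growth toward 5
#' exponential_level(5, 10, -0.4, 1)   # accelerated growth away from 5
#' @export
exponential_level <- function(asymptote, initial, rate, time) {
  asymptote - (asymptote - initial) * exp(-rate * time)
}

#' Continuous-time parameters of a latent change score model
#'
#' The continuous-time (CT) counterpart of the discrete dual change equation
#' is the linear-affine ODE `dy/dt = a + B y`, with drift matrix `B`
#' (univariate: the scalar `-r`) and additive input `a` (univariate:
#' `r * asymptote`).
#'
#' @param drift `p x p` drift matrix (scalar accepted for `p = 1`).
#' @param additive length-`p` additive input.
#' @return An object of class `"lcs_ct"`.
#' @seealso [ct_to_dt()], [dt_to_ct()], [ct_derivative()]
#' @export
ct_params <- function(drift, additive) {
  drift <- as_square_matrix(drift, "drift")
  additive <- as.numeric(additive)
  if (length(additive) != nrow(drift))
    stop("'additive' length must match 'drift' dimension", call. = FALSE)
  if (!all(is.finite(drift)) || !all(is.finite(additive)))
    stop("continuous-time parameters must be finite", call. = FALSE)
  structure(list(drift = drift, additive = additive), class = "lcs_ct")
}

#' @export
print.lcs_ct <- function(x, digits = 6, ...) {
  cat("Continuous-time LCS parameters\n  drift:\n")
  print(round(x$drift, digits))
  cat("  additive:", format(x$additive, digits = digits), "\n")
  invisible(x)
}

#' Instantaneous rate of change of the continuous-time model
#'
#' @param level length-`p` numeric vector of current levels.
#' @param ct an [ct_params()] object.
#' @return `additive + drift %*% level`, as a plain vector.
#' @export
ct_derivative <- function(level, ct) {
  stopifnot(inherits(ct, "lcs_ct"))
  level <- as.numeric(level)
  if (length(level) != nrow(ct$drift))
    stop("'level' length must match the drift dimension", call. = FALSE)
  drop(ct$additive + ct$drift %*% level)
}

#' Additive component / asymptote identity (univariate)
#'
#' In the univariate dual model the additive component and the asymptote are
#' linked by `y_a = y_As * (-beta)`; the two functions are mutual inverses.
#' A zero self-feedback has no finite asymptote (linear regime), so
#' `asymptote_from_additive()` rejects `beta = 0`.
#'
#' @param asymptote,additive,beta scalars (vectorized).
#' @return numeric vector.
#' @examples
#' additive_from_asymptote(5, -0.4)   # 2
#' asymptote_from_additive(2, -0.4)   # 5
#' @export
additive_from_asymptote <- function(asymptote, beta) {
  asymptote * (-beta)
}

#' @rdname additive_from_asymptote
#' @export
asymptote_from_additive <- function(additive, beta) {
  if (any(beta == 0))
    stop("beta = 0 has no finite asymptote (linear regime)", call. = FALSE)
  additive / (-beta)
}

# Principal real logarithm of a 1x1 or 2x2 real matrix, in closed form.
# (Library eigendecomposition-based routines fail on defective 2x2 blocks.)
# Defined iff no eigenvalue lies on the closed negative real axis.
real_logm <- function(M) {
  M <- as_square_matrix(M, "M")
  d <- nrow(M)
  ev <- eigen(M, only.values = TRUE)$values
  evc <- as.complex(ev)
  if (any(abs(Im(evc)) < 1e-12 & Re(evc) <= 0))
    stop("matrix has an eigenvalue on the closed negative real axis; ",
         "no real continuous-time equivalent exists", call. = FALSE)
  if (d == 1L) return(matrix(log(Re(evc[1])), 1, 1))
  if (d != 2L) stop("only 1x1 and 2x2 matrices are supported", call. = FALSE)
  l1 <- evc[1]; l2 <- evc[2]
  scale <- max(1, Mod(l1))
  if (Mod(l1 - l2) < 1e-10 * scale) {
    lam <- Re(l1)  # repeated eigenvalue of a real 2x2 matrix is real
    log(lam) * diag(2) + (M - lam * diag(2)) / lam
  } else {
    # log(M) = a I + b M interpolates the principal log at both eigenvalues
    b <- (log(l1) - log(l2)) / (l1 - l2)
    a <- log(l1) - b * l1
    Re(a * diag(2) + b * M)
  }
}

# Integral of the matrix exponential, Phi = int_0^lag expm(B s) ds, via the
# augmented-matrix identity; valid for singular B.
expm_integral <- function(B, lag) {
  p <- nrow(B)
  aug <- rbind(cbind(B * lag, diag(p)), matrix(0, p, 2 * p))
  E <- as.matrix(Matrix::expm(aug))
  lag * E[seq_len(p), p + seq_len(p), drop = FALSE]
}

#' Convert continuous-time dynamics to their discrete-time equivalents
#'
#' Rescales a continuous-time drift/additive pair to the discrete-time metric
#' of a given occasion spacing: the discrete dynamics matrix is
#' `expm(drift * lag) - I` and the discrete additive input is
#' `int_0^lag expm(drift s) ds %*% additive`.  Iterating the discrete change
#' recursion on the result reproduces the continuous-time solution at
#' multiples of `lag`.
#'
#' @param ct an [ct_params()] object.
#' @param lag positive time lag between occasions.
#' @return list with components `dynamics` (`p x p` matrix, the discrete
#'   self-feedback/coupling block), `additive` (length-`p` vector) and `lag`.
#' @examples
#' ct_to_dt(ct_params(-0.4, 2), lag = 1)  # beta -0.32968, additive 1.6484
#' @export
ct_to_dt <- function(ct, lag = 1) {
  stopifnot(inherits(ct, "lcs_ct"))
  if (!is.numeric(lag) || length(lag) != 1L || !is.finite(lag) || lag <= 0)
    stop("'lag' must be a positive scalar", call. = FALSE)
  p <- nrow(ct$drift)
  M <- as.matrix(Matrix::expm(ct$drift * lag))
  list(dynamics = M - diag(p),
       additive = drop(expm_integral(ct$drift, lag) %*% ct$additive),
       lag = lag)
}

#' Recover continuous-time dynamics from discrete-time parameters
#'
#' Inverse of [ct_to_dt()]: the drift is the principal matrix logarithm of
#' `I + dynamics` divided by the lag, and the continuous additive input
#' solves the matrix-integral relation.  A continuous-time equivalent exists
#' only when `I + dynamics` has no eigenvalue on the closed negative real
#' axis (univariate: `1 + beta > 0`).
#'
#' @param dt_dynamics `p x p` discrete dynamics matrix (scalar `beta`
#'   accepted).
#' @param dt_additive length-`p` discrete additive input.
#' @param lag positive time lag the discrete parameters refer to.
#' @return An [ct_params()] object.
#' @examples
#' dt_to_ct(-0.329680, 1.648400, 1)  # drift -0.4, additive 2
#' @export
dt_to_ct <- function(dt_dynamics, dt_additive, lag = 1) {
  dt_dynamics <- as_square_matrix(dt_dynamics, "dt_dynamics")
  dt_additive <- as.numeric(dt_additive)
  p <- nrow(dt_dynamics)
  if (length(dt_additive) != p)
    stop("'dt_additive' length must match 'dt_dynamics'", call. = FALSE)
  if (!is.numeric(lag) || length(lag) != 1L || lag <= 0)
    stop("'lag' must be a positive scalar", call. = FALSE)
  drift <- real_logm(diag(p) + dt_dynamics) / lag
  Phi <- expm_integral(drift, lag)
  ct_params(drift, solve(Phi, dt_additive))
}

#' Model-implied mean trajectory
#'
#' Iterates the mean change recursion
#' `level[t] = level[t-1] + A %*% level[t-1] + mua` from `level[0] = mu0`,
#' where `A` is the dynamics matrix (diagonal self-feedbacks, off-diagonal
#' couplings).
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param horizon number of changes to iterate (default: to the last
#'   occasion of `spec`).
#' @return An object of class `"lcs_trajectory"`: list with `times`
#'   (`0:horizon`) and `levels` (`(horizon+1) x p` matrix).
#' @examples
#' s <- lcs_spec(1, n_occasions = 4)
#' p <- lcs_params(0, 1, diag(2), -0.5, theta = 1)
#' mean_trajectory(s, p)$levels  # 0, 1, 1.5, 1.75
#' @export
mean_trajectory <- function(spec, params, horizon = spec$n_occasions - 1L) {
  validate_params(spec, params)
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("'horizon' must be at least 1", call. = FALSE)
  p <- spec$n_processes
  M <- diag(p) + dynamics_matrix(params)
  levels <- matrix(NA_real_, horizon + 1L, p,
                   dimnames = list(NULL, process_names(spec)))
  levels[1L, ] <- params$mu0
  for (t in seq_len(horizon))
    levels[t + 1L, ] <- drop(M %*% levels[t, ]) + params$mua
  structure(list(times = 0:horizon, levels = levels),
            class = "lcs_trajectory")
}

#' @export
print.lcs_trajectory <- function(x, ...) {
  cat(sprintf("LCS mean trajectory over occasions 0..%d\n", max(x$times)))
  print(head(cbind(time = x$times, x$levels), 10))
  if (length(x$times) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.lcs_trajectory <- function(x, ..., type = "b") {
  matplot(x$times, x$levels, type = type, pch = 16, lty = 1,
          xlab = "occasion", ylab = "latent level", ...)
  if (ncol(x$levels) > 1)
    legend("topleft", legend = colnames(x$levels), col = seq_len(ncol(x$levels)),
           lty = 1, bty = "n")
  invisible(x)
}

#' Fixed point (asymptote vector) of the mean dynamics
#'
#' Solves `A %*% level + mua = 0` for the equilibrium level of the mean
#' recursion.  In the univariate model this reduces to the asymptote
#' `mua / (-beta)`; in coupled bivariate systems the equilibrium depends on
#' both additive components and all four dynamic parameters, so the
#' univariate identity need not hold process-by-process.
#'
#' @param params an [lcs_params()].
#' @return length-`p` numeric vector.
#' @examples
#' fixed_point(lcs_params(0, 2, diag(2), -0.4, theta = 1))  # 5
#' @export
fixed_point <- function(params) {
  stopifnot(inherits(params, "lcs_params"))
  A <- dynamics_matrix(params)
  if (rcond(A) < 1e-12)
    stop("dynamics matrix is singular: no isolated equilibrium",
         call. = FALSE)
  drop(solve(A, -params$mua))
}
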