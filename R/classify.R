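# Qualitative trajectory-shape classification from the discrete-time
# dynamics.  Univariate shapes follow the sign of the self-feedback and the
# position of the asymptote relative to the initial level; bivariate shapes
# follow the eigenvalues of the one-step transition matrix M = I + A.

univariate_shapes <- c("decelerated_growth", "decelerated_decline",
                       "accelerated_growth", "accelerated_decline",
                       "linear_growth", "linear_decline", "constant")
oscillatory_shapes <- c("oscillatory_damped", "oscillatory_explosive",
                        "oscillatory_sustained")

new_lcs_shape <- function(shape, oscillatory, convergent, eigenvalues,
                          per_process = NULL) {
  structure(list(shape = shape, oscillatory = oscillatory,
                 convergent = convergent, eigenvalues = eigenvalues,
                 per_process = per_process),
            class = "lcs_shape")
}

#' @export
print.lcs_shape <- function(x, ...) {
  cat(sprintf("Trajectory shape: %s (%s, %s)\n", x$shape,
              if (x$oscillatory) "oscillatory" else "non-oscillatory",
              if (x$convergent) "convergent" else "divergent"))
  cat("  eigenvalues of I + A:",
      paste(format(x$eigenvalues, digits = 6), collapse = ", "), "\n")
  if (!is.null(x$per_process))
    cat("  per process:", paste(names(x$per_process), x$per_process,
                                sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Classify the shape of the model-implied trajectories
#'
#' For a univariate dual model the shape is determined by the sign of the
#' self-feedback `beta` and the position of the asymptote
#' `y_As = mu_a / (-beta)` relative to the initial mean `mu_0`:
#' decelerated growth/decline for `beta < 0`, accelerated growth/decline for
#' `beta > 0`, linear growth/decline for `beta = 0` (sign of `mu_a`),
#' `constant` when the additive mean vanishes too, or when the trajectory
#' starts on its asymptote.  Note that the sign of the additive component
#' alone does not determine growth versus decline: what matters is whether
#' the asymptote lies above or below the initial level.
#'
#' For a bivariate model classification works through the eigenvalues of the
#' one-step transition matrix `M = I + A`: a complex pair yields oscillatory
#' trajectories (damped, sustained or explosive by the eigenvalue modulus
#' relative to 1); real eigenvalues yield monotone-type trajectories,
#' convergent when the spectral radius is below 1 and divergent otherwise.
#' When both couplings are zero the processes are dynamically independent
#' and the result carries the two univariate labels in `per_process`.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param tol boundary tolerance for "zero" and "modulus one" decisions
#'   (default `1e-8`).
#' @return An object of class `"lcs_shape"` with fields `shape` (one label),
#'   `oscillatory`, `convergent`, `eigenvalues`, and (decoupled bivariate
#'   models) `per_process`.
#' @examples
#' s <- lcs_spec(1)
#' classify_shape(s, lcs_params(0, 2, diag(2), -0.4, theta = 1))
#' @export
classify_shape <- function(spec, params, tol = 1e-8) {
  validate_params(spec, params)
  if (spec$n_processes == 1L) classify_univariate(params, tol)
  else classify_bivariate(params, tol)
}

classify_univariate <- function(params, tol = 1e-8) {
  beta <- params$beta[1]; mu0 <- params$mu0[1]; mua <- params$mua[1]
  m <- 1 + beta
  convergent <- abs(m) < 1
  if (abs(beta) <= tol) {
    shape <- if (abs(mua) <= tol) "constant"
             else if (mua > 0) "linear_growth" else "linear_decline"
  } else {
    yAs <- mua / (-beta)
    if (abs(yAs - mu0) <= tol) shape <- "constant"
    else if (beta < 0) shape <- if (yAs > mu0) "decelerated_growth"
                                else "decelerated_decline"
    else shape <- if (yAs < mu0) "accelerated_growth"
                  else "accelerated_decline"
  }
  new_lcs_shape(shape, oscillatory = FALSE, convergent = convergent,
                eigenvalues = m)
}

classify_bivariate <- function(params, tol = 1e-8) {
  A <- dynamics_matrix(params)
  M <- diag(2) + A
  ev <- eigen(M, only.values = TRUE)$values
  complex_pair <- is.complex(ev) && max(abs(Im(ev))) > tol
  if (complex_pair) {
    modulus <- Mod(ev[1])
    shape <- if (modulus < 1 - tol) "oscillatory_damped"
             else if (modulus > 1 + tol) "oscillatory_explosive"
             else "oscillatory_sustained"
    return(new_lcs_shape(shape, oscillatory = TRUE,
                         convergent = modulus < 1, eigenvalues = ev))
  }
  ev <- Re(ev)
  convergent <- max(abs(ev)) < 1
  per_process <- NULL
  if (all(abs(params$gamma) <= tol)) {
    # dynamically independent: each process classifies as a univariate model
    per_process <- vapply(1:2, function(j) {
      classify_univariate(lcs_params(params$mu0[j], params$mua[j],
                                     diag(2), params$beta[j],
                                     theta = 1), tol)$shape
    }, character(1))
    names(per_process) <- c("x", "y")
  }
  # coarse monotone-type label: convergent systems behave like decelerated
  # change, divergent like accelerated; growth vs decline from the net mean
  # movement of the trajectory
  traj <- mean_trajectory(lcs_spec(2, n_occasions = 3), params, horizon = 25)
  net <- sum(traj$levels[nrow(traj$levels), ] - traj$levels[1, ])
  if (abs(net) <= tol) shape <- "constant"
  else {
    dir <- if (net > 0) "growth" else "decline"
    shape <- paste0(if (convergent) "decelerated_" else "accelerated_", dir)
  }
  new_lcs_shape(shape, oscillatory = FALSE, convergent = convergent,
                eigenvalues = ev, per_process = per_process)
}
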