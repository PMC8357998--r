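# Panel simulation: random effects, latent trajectories, measurement.

new_lcs_panel <- function(observed, ids, occasions, processes,
                          time_lag = 1, latent = NULL) {
  colnames(observed) <- panel_colnames(processes, occasions)
  structure(list(observed = observed, ids = ids, occasions = occasions,
                 processes = processes, time_lag = time_lag,
                 latent = latent),
            class = "lcs_panel")
}

# time-major column order: x_0, y_0, x_1, y_1, ...
panel_colnames <- function(processes, occasions) {
  as.vector(t(outer(occasions, processes,
                    function(o, v) paste0(v, "_", o))))
}

#' @export
print.lcs_panel <- function(x, ...) {
  cat(sprintf("LCS panel: %d individuals x %d occasions x %d process%s\n",
              nrow(x$observed), length(x$occasions), length(x$processes),
              if (length(x$processes) > 1) "es" else ""))
  cat(sprintf("  missing cells: %d of %d\n", sum(is.na(x$observed)),
              length(x$observed)))
  print(head(x$observed, 4))
  if (nrow(x$observed) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
dim.lcs_panel <- function(x) dim(x$observed)

#' Draw individual random effects (initial levels and additive components)
#'
#' Individuals differ in their initial latent level and in their additive
#' change component; the two follow a multivariate normal distribution with
#' mean `c(mu0, mua)` and covariance `phi` (ordered initial levels first,
#' then additive components).
#'
#' @param params an [lcs_params()].
#' @param n number of individuals.
#' @param seed integer seed; identical seeds give identical draws.
#' @return `n x 2p` matrix with columns named e.g. `y0`, `ya`.
#' @export
draw_between_effects <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "lcs_params"), n >= 1)
  stop_if_not_psd(params$phi, "phi")
  p <- n_proc(params)
  mu <- c(params$mu0, params$mua)
  eff <- with_seed(seed, MASS::mvrnorm(n, mu = mu, Sigma = params$phi))
  if (n == 1L) eff <- matrix(eff, nrow = 1L)
  colnames(eff) <- effect_names(p)
  eff
}

#' Simulate latent trajectories under the change recursion
#'
#' Each individual's latent level is iterated as
#' `level[t] = level[t-1] + A %*% level[t-1] + additive_i + d[i,t]`, starting
#' from the drawn initial level.  For stochastic specifications the
#' innovations `d` are i.i.d. `N(0, psi)` per change (occasions `1..T-1`,
#' with a time-invariant covariance); deterministic specifications set
#' `d = 0`, so each path follows its individual exponential-type curve
#' exactly.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param effects matrix from [draw_between_effects()].
#' @param seed integer seed for the innovation draws (unused when
#'   deterministic).
#' @return `N x T x p` array of latent levels.
#' @export
simulate_latent <- function(spec, params, effects, seed = 1L) {
  validate_params(spec, params)
  p <- spec$n_processes
  Tn <- spec$n_occasions
  if (!is.matrix(effects) || ncol(effects) != 2L * p)
    stop("'effects' must be an N x 2p matrix", call. = FALSE)
  n <- nrow(effects)
  M <- diag(p) + dynamics_matrix(params)
  init <- effects[, seq_len(p), drop = FALSE]
  addc <- effects[, p + seq_len(p), drop = FALSE]
  innov <- NULL
  if (spec$stochastic) {
    stop_if_not_psd(params$psi, "psi")
    d <- with_seed(seed,
                   MASS::mvrnorm(n * (Tn - 1L), mu = rep(0, p),
                                 Sigma = params$psi))
    if (p == 1L) d <- matrix(d, ncol = 1L)
    innov <- array(d, dim = c(n, Tn - 1L, p))
  }
  latent <- array(NA_real_, dim = c(n, Tn, p),
                  dimnames = list(NULL, paste0("t", 0:(Tn - 1L)),
                                  process_names(spec)))
  latent[, 1L, ] <- init
  lev <- init
  for (t in 2:Tn) {
    lev <- lev %*% t(M) + addc
    if (!is.null(innov)) lev <- lev + innov[, t - 1L, , drop = TRUE]
    latent[, t, ] <- lev
  }
  latent
}

#' Add measurement error to latent trajectories
#'
#' Observed scores are the latent levels plus occasion-specific Gaussian
#' measurement error, independent across individuals and occasions (a
#' within-occasion covariance between processes is allowed through
#' off-diagonal `theta`).  Unlike innovations, these errors do not propagate
#' to later occasions.
#'
#' @param latent `N x T x p` array from [simulate_latent()].
#' @param theta `p x p` PSD measurement-error covariance.
#' @param seed integer seed.
#' @param time_lag occasion spacing recorded in the returned panel.
#' @return An `"lcs_panel"` object with the latent array attached.
#' @export
observe <- function(latent, theta, seed = 1L, time_lag = 1) {
  theta <- as_square_matrix(theta, "theta")
  stop_if_not_psd(theta, "theta")
  dm <- dim(latent)
  n <- dm[1]; Tn <- dm[2]; p <- dm[3]
  if (nrow(theta) != p)
    stop("'theta' dimension must match the number of processes",
         call. = FALSE)
  err <- with_seed(seed,
                   MASS::mvrnorm(n * Tn, mu = rep(0, p), Sigma = theta))
  if (p == 1L) err <- matrix(err, ncol = 1L)
  obs <- latent + array(err, dim = dm)
  processes <- if (p == 1L) "y" else c("x", "y")
  wide <- matrix(aperm(obs, c(1, 3, 2)), nrow = n)       # time-major columns
  lat_wide <- matrix(aperm(latent, c(1, 3, 2)), nrow = n)
  colnames(lat_wide) <- panel_colnames(processes, 0:(Tn - 1L))
  new_lcs_panel(wide, ids = seq_len(n), occasions = 0:(Tn - 1L),
                processes = processes, time_lag = time_lag,
                latent = lat_wide)
}

#' Simulate an observed panel under a latent change score model
#'
#' Composes [draw_between_effects()], [simulate_latent()] and [observe()].
#' The master seed spawns three independent substreams (effects,
#' innovations, measurement errors), so changing `theta` never perturbs the
#' latent draws.  Output is a deterministic function of
#' `(spec, params, n, seed)`.
#'
#' @param spec an [lcs_spec()].
#' @param params an [lcs_params()].
#' @param n number of individuals.
#' @param seed integer master seed.
#' @return An `"lcs_panel"` object (observed `N x pT` matrix in time-major
#'   column order, latent values attached).
#' @examples
#' s <- lcs_spec(1, n_occasions = 5)
#' p <- lcs_params(0, 2, diag(c(1, 0.25)), -0.4, theta = 0.25)
#' simulate_panel(s, p, n = 5, seed = 42)
#' @export
simulate_panel <- function(spec, params, n, seed = 1L) {
  validate_params(spec, params)
  seeds <- derive_seeds(seed, 3L)
  eff <- draw_between_effects(params, n, seed = seeds[1])
  latent <- simulate_latent(spec, params, eff, seed = seeds[2])
  observe(latent, params$theta, seed = seeds[3], time_lag = spec$time_lag)
}
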