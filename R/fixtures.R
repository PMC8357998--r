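# Registry of named illustrative scenarios.  Each entry reproduces a
# published illustrative parameter configuration of the LCS family
# (exponential trajectories with asymptote 5; decelerated-growth groups with
# self-feedbacks -0.2/-0.5/-1; additive-variance contrasts with initial-level
# variance 10; six bivariate coupling regimes).  Quantities the sources leave
# unprinted (means, error variances, occasion counts) are fixed here as
# documented registry constants and never vary between calls.

# shared defaults for unprinted quantities
.fx <- list(
  uni_T = 5L,          # occasions for univariate scenarios
  biv_T = 10L,         # occasions for bivariate scenarios
  theta1 = 0.25,       # univariate measurement-error variance
  phi1 = diag(c(1, 0.25)),      # univariate (y0, ya) covariance
  theta2 = diag(0.25, 2),       # bivariate measurement-error covariance
  phi2 = diag(c(1, 1, 0.25, 0.25)),  # bivariate (x0, y0, xa, ya)
  asymptote = 5                 # common asymptote of the exponential sets
)

# univariate scenario from continuous-time rate r, initial level y0,
# asymptote yAs, converted to the discrete metric at lag 1
.uni_from_rate <- function(r, y0, yAs = .fx$asymptote, phi = .fx$phi1) {
  beta <- exp(-r) - 1
  lcs_params(mu0 = y0, mua = additive_from_asymptote(yAs, beta),
             phi = phi, beta = beta, theta = .fx$theta1)
}

.uni_from_beta <- function(beta, y0, yAs = .fx$asymptote, phi = .fx$phi1) {
  lcs_params(mu0 = y0, mua = additive_from_asymptote(yAs, beta),
             phi = phi, beta = beta, theta = .fx$theta1)
}

# fig5-style contrasts: initial-level variance 10, additive variance 0 or 12
.fig5_phi <- function(var_ya) diag(c(10, var_ya))

.table1 <- list(
  A = c(-0.3, -0.3, -0.2, 0.0),
  B = c(-0.3, 0.3, 0.2, 0.0),
  C = c(0.3, -0.7, 0.6, -0.5),
  D = c(0.3, 0.0, 0.2, 0.2),
  E = c(0.9, -0.9, 1.1, -1.1),
  F = c(-0.8, -0.3, -0.8, 0.8)
)

.biv_from_table <- function(col) {
  v <- .table1[[col]]
  lcs_params(mu0 = c(0, 0), mua = c(1, 1), phi = .fx$phi2,
             beta = v[1:2], gamma = v[3:4], theta = .fx$theta2)
}

fixture_registry <- function() {
  uni <- function(params) list(spec = lcs_spec(1, n_occasions = .fx$uni_T),
                               params = params)
  biv <- function(params) list(spec = lcs_spec(2, n_occasions = .fx$biv_T),
                               params = params)
  reg <- list(
    # exponential trajectories: rates {4, -0.4}, initial levels {0, 10},
    # asymptote 5, converted to discrete time at lag 1
    fig2_decelerated_growth  = uni(.uni_from_rate(4, 0)),
    fig2_decelerated_decline = uni(.uni_from_rate(4, 10)),
    fig2_accelerated_growth  = uni(.uni_from_rate(-0.4, 10)),
    fig2_accelerated_decline = uni(.uni_from_rate(-0.4, 0)),
    # socio-economic-background contrast: decelerated growth toward 5 with
    # self-feedbacks -0.2 / -0.5 / -1 ...
    fig4_low_seb    = uni(.uni_from_beta(-0.2, 0)),
    fig4_medium_seb = uni(.uni_from_beta(-0.5, 0)),
    fig4_high_seb   = uni(.uni_from_beta(-1, 0)),
    # ... and accelerated decay with self-feedbacks 0.2 / 0.5 / 1
    fig4_mistakes_low_seb    = uni(.uni_from_beta(0.2, 10, yAs = 12)),
    fig4_mistakes_medium_seb = uni(.uni_from_beta(0.5, 10, yAs = 12)),
    fig4_mistakes_high_seb   = uni(.uni_from_beta(1, 10, yAs = 12)),
    # additive-component variance contrasts: initial-level variance 10,
    # additive variance 0 (A, C) or 12 (B, D); decelerated (A, B) vs
    # accelerated (C, D) change
    fig5_A = uni(.uni_from_beta(-0.4, 0, phi = .fig5_phi(0))),
    fig5_B = uni(.uni_from_beta(-0.4, 0, phi = .fig5_phi(12))),
    fig5_C = uni(.uni_from_beta(0.4, 10, phi = .fig5_phi(0))),
    fig5_D = uni(.uni_from_beta(0.4, 10, phi = .fig5_phi(12)))
  )
  for (col in names(.table1))
    reg[[paste0("table1_", col)]] <- biv(.biv_from_table(col))
  reg
}

#' Named illustrative scenarios with simulated panels
#'
#' `lcs_fixtures()` lists the registered scenario names.  `lcs_fixture()`
#' returns the scenario's specification and population parameters together
#' with a freshly simulated panel.  Scenarios cover the exponential
#' trajectory configurations (`fig2_*`: rates 4 and -0.4, initial levels 0
#' and 10, asymptote 5), the decelerated/accelerated self-feedback contrasts
#' (`fig4_*`: beta = -0.2, -0.5, -1 and 0.2, 0.5, 1), the
#' additive-variance contrasts (`fig5_A`..`fig5_D`: initial-level variance
#' 10, additive variance 0 or 12) and the six bivariate coupling regimes
#' (`table1_A`..`table1_F`).
#'
#' @param name scenario name, one of `lcs_fixtures()`.
#' @param n number of individuals to simulate.
#' @param seed integer seed.
#' @return A list with components `spec`, `params` and `panel`.
#' @examples
#' lcs_fixtures()
#' fx <- lcs_fixture("fig4_low_seb", n = 20, seed = 1)
#' fx$params$beta   # -0.2
#' @export
lcs_fixture <- function(name, n = 200L, seed = 1L) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown fixture '%s'; see lcs_fixtures()", name),
         call. = FALSE)
  fx <- reg[[name]]
  list(spec = fx$spec, params = fx$params,
       panel = simulate_panel(fx$spec, fx$params, n = n, seed = seed))
}

#' @rdname lcs_fixture
#' @export
lcs_fixtures <- function() names(fixture_registry())
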