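# Shared model builders for the test suite.

uni_spec <- function(T = 5L, stochastic = FALSE)
  lcs_spec(1, stochastic = stochastic, n_occasions = T)

biv_spec <- function(T = 5L, stochastic = FALSE, ...)
  lcs_spec(2, stochastic = stochastic, n_occasions = T, ...)

uni_params <- function(mu0 = 0, mua = 2, beta = -0.4,
                       phi = diag(c(1, 0.25)), theta = 0.25, psi = NULL)
  lcs_params(mu0, mua, phi, beta, theta = theta, psi = psi)

biv_params <- function(beta = c(-0.3, -0.4), gamma = c(0.2, -0.1),
                       mu0 = c(0, 1), mua = c(1, 0.5),
                       phi = diag(c(1, 1, 0.3, 0.3)),
                       theta = matrix(c(0.3, 0.05, 0.05, 0.25), 2, 2),
                       psi = NULL)
  lcs_params(mu0, mua, phi, beta, gamma = gamma, theta = theta, psi = psi)

# dynamics of the six illustrative bivariate regimes (beta_x, beta_y,
# gamma_x, gamma_y)
regime_dynamics <- list(
  A = c(-0.3, -0.3, -0.2, 0.0),
  B = c(-0.3, 0.3, 0.2, 0.0),
  C = c(0.3, -0.7, 0.6, -0.5),
  D = c(0.3, 0.0, 0.2, 0.2),
  E = c(0.9, -0.9, 1.1, -1.1),
  F = c(-0.8, -0.3, -0.8, 0.8)
)

biv_from_regime <- function(col) {
  v <- regime_dynamics[[col]]
  biv_params(beta = v[1:2], gamma = v[3:4])
}
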