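test_that("loading matrix accumulates the change recursion in closed form", {
  s <- uni_spec()
  L <- loading_matrix(s, uni_params(beta = -0.5))
  expect_equal(unname(L[1, ]), c(1, 0))               # occasion 0
  expect_equal(unname(L[3, ]), c(0.25, 1.5))          # (1+b)^2, geometric sum
  L0 <- loading_matrix(s, uni_params(beta = 0))
  expect_equal(unname(L0[4, ]), c(1, 3))              # beta -> 0 limit
  # univariate closed form at every occasion
  b <- -0.3
  Lb <- loading_matrix(s, uni_params(beta = b))
  expect_equal(unname(Lb), cbind((1 + b)^(0:4), ((1 + b)^(0:4) - 1) / b))
  # bivariate: blocks are powers of M and partial geometric sums
  par <- biv_params()
  Lb2 <- loading_matrix(biv_spec(T = 4), par)
  M <- diag(2) + rbind(c(par$beta[1], par$gamma[1]),
                       c(par$gamma[2], par$beta[2]))
  expect_equal(unname(Lb2[5:6, 1:2]), M %*% M)
  expect_equal(unname(Lb2[5:6, 3:4]), diag(2) + M)
})

test_that("implied moments are consistent with the mean recursion and simple cases", {
  s <- uni_spec()
  par <- uni_params(beta = -0.4)
  mom <- implied_moments(s, par)
  expect_equal(unname(mom$mean), mean_trajectory(s, par)$levels[, 1])
  expect_equal(mom$covariance, t(mom$covariance))
  # no random effects, deterministic: covariance is sigma_e^2 I
  par0 <- uni_params(phi = matrix(0, 2, 2), theta = 0.25)
  expect_equal(unname(implied_moments(s, par0)$covariance),
               diag(0.25, 5))
})

test_that("implied moments agree with Monte-Carlo moments", {
  cases <- list(
    list(spec = uni_spec(), par = uni_params(beta = -0.4,
                                             phi = matrix(c(2, 0.3, 0.3, 0.5),
                                                          2, 2))),
    list(spec = uni_spec(stochastic = TRUE),
         par = uni_params(beta = -0.5, psi = 1)),
    list(spec = biv_spec(T = 4, stochastic = TRUE),
         par = biv_params(psi = matrix(c(0.4, 0.1, 0.1, 0.3), 2, 2))))
  n <- 60000
  for (case in cases) {
    im <- implied_moments(case$spec, case$par)
    mc <- mc_moments(case$spec, case$par, n = n, seed = 21)
    sd_mean <- sqrt(diag(im$covariance) / n)
    expect_true(all(abs(mc$mean - im$mean) < 4 * sd_mean))
    D <- diag(im$covariance)
    se_cov <- sqrt((outer(D, D) + im$covariance^2) / n)
    expect_true(all(abs(mc$covariance - im$covariance) < 4 * se_cov))
  }
})

test_that("mc_moments is exact for degenerate panels and seed-stable", {
  s <- uni_spec()
  par0 <- uni_params(phi = matrix(0, 2, 2), theta = 0)
  mc <- mc_moments(s, par0, n = 20, seed = 1)
  expect_equal(unname(mc$mean), mean_trajectory(s, par0)$levels[, 1])
  expect_equal(unname(mc$covariance), matrix(0, 5, 5))
  expect_identical(mc_moments(s, uni_params(), 30, seed = 2),
                   mc_moments(s, uni_params(), 30, seed = 2))
})

test_that("row log-likelihood marginalizes missing entries correctly", {
  s <- uni_spec()
  par <- uni_params(beta = -0.4)
  mom <- implied_moments(s, par)
  # identity covariance, row at the mean: -(m/2) log(2 pi)
  mom_id <- mom
  mom_id$covariance <- diag(5)
  expect_equal(row_loglik(mom_id$mean, mom_id), -2.5 * log(2 * pi))
  # a row with entries 2 and 4 missing equals the 3-entry marginal density
  row <- c(0.3, NA, 1.1, NA, 2.0)
  keep <- c(1, 3, 5)
  mom3 <- mom
  mom3$mean <- mom$mean[keep]
  mom3$covariance <- mom$covariance[keep, keep]
  expect_equal(row_loglik(row, mom), row_loglik(row[keep], mom3))
  expect_error(row_loglik(rep(NA_real_, 5), mom), "no observed")
})

test_that("complete-row log-likelihood matches an independent MVN density", {
  skip_if_not_installed("mclust")
  s <- biv_spec(T = 4)
  par <- biv_params()
  mom <- implied_moments(s, par)
  set.seed(31)
  for (i in 1:5) {
    row <- drop(MASS::mvrnorm(1, mom$mean, mom$covariance))
    expect_equal(row_loglik(row, mom),
                 log(mclust::dmvnorm(matrix(row, 1), mom$mean,
                                     mom$covariance)),
                 tolerance = 1e-10)
  }
})

test_that("panel -2LL is additive and permutation-invariant over rows", {
  s <- uni_spec()
  par <- uni_params()
  pan <- simulate_panel(s, par, n = 8, seed = 41)
  X <- pan$observed
  mom <- implied_moments(s, par)
  by_rows <- -2 * sum(vapply(seq_len(8), function(i)
    row_loglik(X[i, ], mom), numeric(1)))
  expect_equal(minus_two_loglik(s, par, X), by_rows)
  expect_equal(minus_two_loglik(s, par, X[sample(8), ]),
               minus_two_loglik(s, par, X))
  expect_warning(m2 <- minus_two_loglik(s, par, rbind(X, NA)), "dropped")
  expect_equal(m2, by_rows)
})

test_that("FIML and Kalman likelihood routes agree", {
  # stochastic univariate
  s <- uni_spec(stochastic = TRUE)
  par <- uni_params(beta = -0.5, psi = 1)
  pan <- simulate_panel(s, par, n = 10, seed = 51)
  expect_equal(kalman_loglik(s, par, pan), minus_two_loglik(s, par, pan),
               tolerance = 1e-6)
  # deterministic bivariate with scattered missingness
  s2 <- biv_spec(T = 4)
  par2 <- biv_params()
  X <- simulate_panel(s2, par2, n = 15, seed = 52)$observed
  set.seed(53)
  X[sample(length(X), 20)] <- NA
  expect_equal(kalman_loglik(s2, par2, X), minus_two_loglik(s2, par2, X),
               tolerance = 1e-6)
  # stochastic bivariate with within-occasion covariances
  s3 <- biv_spec(T = 5, stochastic = TRUE)
  par3 <- biv_params(psi = matrix(c(0.4, 0.1, 0.1, 0.3), 2, 2))
  X3 <- simulate_panel(s3, par3, n = 12, seed = 54)$observed
  X3[2, 1:4] <- NA
  expect_equal(kalman_loglik(s3, par3, X3), minus_two_loglik(s3, par3, X3),
               tolerance = 1e-6)
})

test_that("implied latent variance shrinks or diverges with the sign of beta", {
  sT <- uni_spec(T = 15L)
  shrink <- uni_params(beta = -0.4, phi = diag(c(10, 0)), theta = 0.25)
  v <- diag(implied_moments(sT, shrink)$covariance) - 0.25
  expect_true(all(diff(v) < 0))
  expect_lt(v[15], 1e-3)
  grow <- uni_params(beta = 0.4, phi = diag(c(10, 0)), theta = 0.25)
  vg <- diag(implied_moments(sT, grow)$covariance) - 0.25
  expect_true(all(diff(vg) > 0))
  expect_gt(vg[15], 1e3)
})

test_that("the likelihood is largest near the generating parameters", {
  s <- uni_spec()
  par <- uni_params(beta = -0.4)
  pan <- simulate_panel(s, par, n = 2000, seed = 61)
  at_truth <- minus_two_loglik(s, par, pan)
  for (f in c(0.8, 1.2)) {
    perturbed <- par
    perturbed$beta <- par$beta * f
    expect_gt(minus_two_loglik(s, perturbed, pan), at_truth)
  }
})
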