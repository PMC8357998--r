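test_that("exponential_level evaluates the closed-form trajectory", {
  # intercept property: level at t = 0 is the initial level
  for (ini in c(-3, 0, 10))
    expect_equal(exponential_level(5, ini, 1.7, 0), ini)
  # frozen values computed from y_As - (y_As - y0) exp(-r t)
  expect_equal(exponential_level(5, 0, 4, 1), 4.908422, tolerance = 1e-6)
  expect_equal(exponential_level(5, 10, -0.4, 1), 12.459124,
               tolerance = 1e-6)
  expect_equal(exponential_level(5, 0, 4, c(0, 1)),
               c(0, 5 - 5 * exp(-4)))
})

test_that("ct_derivative returns additive + drift * level", {
  ct <- ct_params(-0.4, 2)
  expect_equal(ct_derivative(0, ct), 2)
  expect_equal(ct_derivative(10, ct), -2)
  # equilibrium: derivative vanishes at the fixed point -drift^{-1} additive
  expect_equal(ct_derivative(5, ct), 0)
  ct2 <- ct_params(matrix(c(-0.3, 0.1, 0.2, -0.5), 2, 2), c(1, 0.5))
  fp <- drop(solve(-ct2$drift, ct2$additive))
  expect_equal(ct_derivative(fp, ct2), c(0, 0))
})

test_that("additive component and asymptote are mutual inverses", {
  expect_equal(additive_from_asymptote(5, -0.4), 2)
  expect_equal(asymptote_from_additive(2, -0.4), 5)
  for (yAs in c(-4, 0.5, 12)) for (beta in c(-1.2, -0.4, 0.7))
    expect_equal(asymptote_from_additive(additive_from_asymptote(yAs, beta),
                                         beta), yAs)
  expect_error(asymptote_from_additive(2, 0), "linear")
})

test_that("ct_to_dt matches scalar formulas and preserves the fixed point", {
  dt <- ct_to_dt(ct_params(-0.4, 2), lag = 1)
  expect_equal(dt$dynamics[1, 1], -0.329680, tolerance = 1e-6)
  expect_equal(dt$additive, 1.648400, tolerance = 1e-6)
  expect_equal(dt$additive / -dt$dynamics[1, 1], 5, tolerance = 1e-10)
  # zero drift: linear regime, additive scales with the lag
  dt0 <- ct_to_dt(ct_params(0, 2), lag = 2.5)
  expect_equal(dt0$dynamics[1, 1], 0)
  expect_equal(dt0$additive, 5)
  # diagonal 2x2 drift decouples into the scalar formulas
  dt2 <- ct_to_dt(ct_params(diag(c(-0.4, -0.9)), c(2, 1)), lag = 1)
  expect_equal(diag(dt2$dynamics), expm1(c(-0.4, -0.9)), tolerance = 1e-12)
  expect_equal(dt2$dynamics[1, 2], 0)
  expect_equal(dt2$additive,
               c(expm1(-0.4) / -0.4 * 2, expm1(-0.9) / -0.9 * 1),
               tolerance = 1e-12)
})

test_that("dt_to_ct inverts ct_to_dt and rejects impossible dynamics", {
  ct <- dt_to_ct(-0.329680, 1.648400, lag = 1)
  expect_equal(ct$drift[1, 1], -0.4, tolerance = 1e-5)
  expect_equal(ct$additive, 2, tolerance = 1e-5)
  ct0 <- dt_to_ct(0, 3, lag = 1)
  expect_equal(ct0$drift[1, 1], 0)
  expect_equal(ct0$additive, 3)
  expect_error(dt_to_ct(-1, 1, lag = 1), "negative real axis")
  expect_error(dt_to_ct(-1.5, 1, lag = 1), "negative real axis")
})

test_that("DT-CT round trip is the identity over random stable systems", {
  set.seed(41)
  for (rep in 1:25) {
    p <- sample(1:2, 1)
    repeat {   # draw a drift with eigenvalues off the closed negative axis
      B <- matrix(rnorm(p * p, sd = 0.5), p, p)
      M <- as.matrix(Matrix::expm(B))
      ev <- as.complex(eigen(M, only.values = TRUE)$values)
      if (all(abs(Im(ev)) > 1e-8 | Re(ev) > 1e-6)) break
    }
    a <- rnorm(p)
    lag <- runif(1, 0.3, 2)
    dt <- ct_to_dt(ct_params(B, a), lag)
    ct <- dt_to_ct(dt$dynamics, dt$additive, lag)
    expect_equal(ct$drift, B, tolerance = 1e-10)
    expect_equal(ct$additive, a, tolerance = 1e-10)
  }
})

test_that("DT recursion on converted parameters reproduces the CT solution", {
  set.seed(42)
  for (rep in 1:20) {
    r <- runif(1, 0.05, 1.5)           # stable decelerated configurations
    yAs <- runif(1, -5, 10)
    y0 <- runif(1, -5, 10)
    lag <- sample(c(0.5, 1, 2), 1)
    dt <- ct_to_dt(ct_params(-r, r * yAs), lag)
    spec <- lcs_spec(1, n_occasions = 8, time_lag = lag)
    par <- lcs_params(y0, dt$additive, diag(2), dt$dynamics[1, 1],
                      theta = 1)
    tr <- mean_trajectory(spec, par, horizon = 7)
    expect_equal(tr$levels[, 1],
                 exponential_level(yAs, y0, r, lag * (0:7)),
                 tolerance = 1e-10)
  }
})

test_that("mean_trajectory follows the change recursion", {
  tr <- mean_trajectory(uni_spec(T = 4), uni_params(mu0 = 0, mua = 1,
                                                    beta = -0.5))
  expect_equal(tr$levels[, 1], c(0, 1, 1.5, 1.75))
  expect_equal(tr$times, 0:3)
  # beta = 0: additive component acts as a linear slope
  tr0 <- mean_trajectory(uni_spec(), uni_params(mu0 = 2, mua = 0.5,
                                                beta = 0))
  expect_equal(tr0$levels[, 1], 2 + 0.5 * (0:4))
  # beta = -1 annihilates history: the asymptote is reached in one step
  tr1 <- mean_trajectory(uni_spec(), uni_params(mu0 = 9, mua = 5,
                                                beta = -1))
  expect_equal(tr1$levels[-1, 1], rep(5, 4))
})

test_that("fixed_point solves the equilibrium and detects degeneracy", {
  expect_equal(fixed_point(uni_params(mua = 2, beta = -0.4)), 5)
  parC <- biv_from_regime("C")
  parC$mua <- c(1, 1)
  fp <- fixed_point(parC)
  expect_equal(fp, c(14.4444, -8.8889), tolerance = 1e-4)
  expect_error(fixed_point(uni_params(beta = 0)), "singular")
  # trajectories started at the fixed point stay there
  par <- biv_from_regime("A")
  par$mu0 <- fixed_point(par)
  tr <- mean_trajectory(biv_spec(), par, horizon = 6)
  for (t in 1:7) expect_equal(tr$levels[t, ], par$mu0,
                              ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("univariate shapes follow beta and the asymptote position", {
  s <- uni_spec()
  cls <- function(mu0, mua, beta)
    classify_shape(s, uni_params(mu0 = mu0, mua = mua, beta = beta))$shape
  expect_identical(cls(0, 2, -0.4), "decelerated_growth")
  expect_identical(cls(10, 2, -0.4), "decelerated_decline")
  expect_identical(cls(10, 2, 0.4), "accelerated_growth")   # y_As = -5 < 10
  expect_identical(cls(-10, 2, 0.4), "accelerated_decline")
  expect_identical(cls(0, 2, 0), "linear_growth")
  expect_identical(cls(0, -2, 0), "linear_decline")
  expect_identical(cls(0, 0, 0), "constant")
  expect_identical(cls(5, 2, -0.4), "constant")   # starts on the asymptote
})

test_that("growth vs decline depends on the asymptote side, not the sign of mua", {
  s <- uni_spec()
  # same additive component and self-feedback; initial level straddles y_As = 5
  below <- classify_shape(s, uni_params(mu0 = 0, mua = 2, beta = -0.4))
  above <- classify_shape(s, uni_params(mu0 = 10, mua = 2, beta = -0.4))
  expect_identical(below$shape, "decelerated_growth")
  expect_identical(above$shape, "decelerated_decline")
})

test_that("bivariate classification follows the eigenvalues of I + A", {
  s <- biv_spec()
  for (col in names(regime_dynamics)) {
    par <- biv_from_regime(col)
    sh <- classify_shape(s, par)
    # independent oracle: eigenvalues straight from base eigen()
    ev <- eigen(diag(2) + rbind(c(par$beta[1], par$gamma[1]),
                                c(par$gamma[2], par$beta[2])),
                only.values = TRUE)$values
    osc <- is.complex(ev)
    expect_identical(sh$oscillatory, osc, info = col)
    expect_identical(sh$convergent, max(Mod(as.complex(ev))) < 1,
                     info = col)
    if (osc) {
      expect_identical(sh$shape,
                       if (Mod(ev[1]) < 1) "oscillatory_damped"
                       else "oscillatory_explosive", info = col)
    }
  }
  # frozen regime facts: E explosive with modulus sqrt(1.40), F damped with
  # modulus sqrt(0.78); A convergent with eigenvalues (0.7, 0.7); D divergent
  # with eigenvalues (1.4, 0.9)
  shE <- classify_shape(s, biv_from_regime("E"))
  expect_identical(shE$shape, "oscillatory_explosive")
  expect_equal(Mod(shE$eigenvalues[1]), sqrt(1.40), tolerance = 1e-10)
  shF <- classify_shape(s, biv_from_regime("F"))
  expect_identical(shF$shape, "oscillatory_damped")
  expect_equal(Mod(shF$eigenvalues[1]), sqrt(0.78), tolerance = 1e-10)
  shA <- classify_shape(s, biv_from_regime("A"))
  expect_false(shA$oscillatory)
  expect_true(shA$convergent)
  expect_equal(sort(shA$eigenvalues), c(0.7, 0.7))
  shD <- classify_shape(s, biv_from_regime("D"))
  expect_false(shD$oscillatory)
  expect_false(shD$convergent)
  expect_equal(sort(shD$eigenvalues), c(0.9, 1.4), tolerance = 1e-12)
})

test_that("decoupled bivariate systems agree with univariate classification", {
  par <- biv_params(beta = c(-0.4, 0.3), gamma = c(0, 0),
                    mu0 = c(0, 10), mua = c(2, 2))
  sh <- classify_shape(biv_spec(), par)
  expect_false(sh$oscillatory)
  expect_identical(unname(sh$per_process["x"]),
                   classify_shape(uni_spec(),
                                  uni_params(0, 2, -0.4))$shape)
  expect_identical(unname(sh$per_process["y"]),
                   classify_shape(uni_spec(),
                                  uni_params(10, 2, 0.3))$shape)
})
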