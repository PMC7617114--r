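cov0 <- c(0, 0, 0)

test_that("hurdle log-density matches hand-computed values", {
  par <- hrqol_params()  # all coefficients 0, shape 1
  # logit p = 0 => p = 0.5; point mass at 0
  expect_equal(hrqol_logdensity(par, 0, cov0, 0.3, 1, 0), log(0.5))
  # continuous part: Exponential(1) at 1 contributes -1
  expect_equal(hrqol_logdensity(par, 0, cov0, 0, 2, 1), log(0.5) - 1)
  expect_error(hrqol_logdensity(par, 0, cov0, 0.3, 1, -0.1), ">= 0")
  expect_error(hrqol_params(shape_q = 0), "shape_q")
  # covariates shift the linear predictors as specified
  par2 <- hrqol_params(gamma0 = rep(0.5, 6), omega = c(1, 0.2, 0.3, 0.4),
                       alpha0 = rep(-1, 6), beta = c(0.5, 0.1, 0.2, 0.3),
                       shape_q = 2)
  covs <- c(1.5, -2, 1)
  etap <- 0.5 + 1 * 0.4 + 0.2 * 1.5 + 0.3 * (-2) + 0.4 * 1
  etam <- -1 + 0.7 + 0.5 * 0.4 + 0.1 * 1.5 + 0.2 * (-2) + 0.3 * 1
  manual <- log(1 - plogis(etap)) +
    dgamma(0.6, shape = 2, rate = 2 / exp(etam), log = TRUE)
  expect_equal(hrqol_logdensity(par2, 0.7, covs, 0.4, 3, 0.6), manual)
})

test_that("gamma and normal variants implement the alternative families", {
  par <- hrqol_params(shape_q = 1)
  # full health enters the gamma variant as the positivity shift 1e-4
  expect_equal(hrqol_logdensity_gamma_variant(par, 0, cov0, 0.3, 1, 1e-4),
               dgamma(1e-4, 1, 1, log = TRUE))
  expect_error(hrqol_logdensity_gamma_variant(par, 0, cov0, 0.3, 1, 0),
               "positive")
  expect_equal(hrqol_logdensity_normal_variant(par, 0, cov0, 0, 1, 0),
               -0.5 * log(2 * pi))
})

test_that("QALY aggregation applies the trapezoid weights", {
  expect_equal(qaly_from_decrements(rep(0, 6)), 4.875)
  expect_equal(qaly_from_decrements(rep(1, 6)), 0)
  expect_equal(qaly_from_decrements(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)), 3.15)
  expect_error(qaly_from_decrements(rep(0, 5)), "6")
  # affine and decreasing in every coordinate with the stated weights
  set.seed(1)
  w <- c(0.5, 0.875, 1, 1, 1, 0.5)
  for (r in 1:5) {
    q <- runif(6)
    expect_equal(qaly_from_decrements(q), 4.875 - sum(w * q))
  }
})

test_that("prediction modes agree in expectation", {
  par_sure <- hrqol_params(gamma0 = rep(30, 6))   # hurdle certain
  expect_equal(predict_hrqol(par_sure, cov0, 0.3, 1)$pred_q, 0, tolerance = 1e-10)
  par_never <- hrqol_params(gamma0 = rep(-30, 6), alpha0 = rep(log(0.4), 6))
  expect_equal(predict_hrqol(par_never, cov0, 0.3, 1)$pred_q, 0.4, tolerance = 1e-8)
  par <- hrqol_params(alpha0 = rep(log(0.4), 6))  # p = 0.5, mu = 0.4
  expect_equal(predict_hrqol(par, cov0, 0.3, 2)$pred_q, 0.2)
  set.seed(7)
  draws <- replicate(1e5, predict_hrqol(par, cov0, 0.3, 2, mode = "stochastic")$pred_q)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.2), 3 * se)
})

test_that("cost log-density and its truncation match closed forms", {
  par <- cost_params(shape_c = 1)  # Exponential(1) when zeta = 0
  expect_equal(cost_logdensity(par, cov0, 4, 3, 1), -1)
  # xi = 0 decouples the QALY residual
  expect_equal(cost_logdensity(par, cov0, 10, 3, 1),
               cost_logdensity(par, cov0, -5, 3, 1))
  expect_error(cost_logdensity(par, cov0, 4, 3, 0), "> 0")
  expect_error(cost_params(shape_c = -1), "shape_c")
  # exponential memorylessness: log[ f(3) / P(X > 2) ] = -(3 - 2)
  expect_equal(truncated_cost_logdensity(par, cov0, 0, 0, 3, lower = 2), -1)
  expect_equal(truncated_cost_logdensity(par, cov0, 0, 0, 1.5, lower = 0),
               cost_logdensity(par, cov0, 0, 0, 1.5))
  expect_identical(truncated_cost_logdensity(par, cov0, 0, 0, 2, lower = 2), -Inf)
})

test_that("marginal cost mean exponentiates the covariate-only predictor", {
  expect_equal(marginal_cost_mean(cost_params(), cov0), 1)
  expect_equal(marginal_cost_mean(cost_params(zeta = c(log(1000), 0, 0, 0)), cov0), 1000)
  par <- cost_params(zeta = c(7, 0, 0.01, 0))
  expect_equal(marginal_cost_mean(par, c(0, 60, 0)), exp(7.6))
})

test_that("baseline imputation density is a gamma truncated at 1.2", {
  par <- baseline_imp_params(1, 1)
  expect_identical(baseline_imp_logdensity(par, 1.3), -Inf)
  expect_equal(baseline_imp_logdensity(par, 0.5),
               log(exp(-0.5) / (1 - exp(-1.2))))
  set.seed(3)
  draws <- rtruncgamma(1e5, 1.4, 4.5, upper = 1.2)
  expect_true(all(draws <= 1.2 & draws > 0))
})

test_that("hurdle density integrates to one over random parameter draws", {
  set.seed(11)
  for (r in 1:20) {
    par <- hrqol_params(gamma0 = rnorm(6, 0, 1.5), omega = rnorm(4, 0, 0.5),
                        alpha0 = rnorm(6, -1, 0.5), beta = rnorm(4, 0, 0.5),
                        shape_q = runif(1, 0.5, 5), theta_sd = 1)
    covs <- rnorm(3, 0, 0.5)
    bq <- runif(1, 0, 1)
    t <- sample(1:6, 1)
    th <- rnorm(1, 0, 0.3)
    p0 <- exp(hrqol_logdensity(par, th, covs, bq, t, 0))
    cont <- integrate(function(x) {
      vapply(x, function(xx) exp(hrqol_logdensity(par, th, covs, bq, t, xx)),
             numeric(1))
    }, 0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(p0 + cont - 1), 1e-6)
  }
})

test_that("truncated densities renormalize to one", {
  par <- cost_params(zeta = c(log(2000), 0, 0, 0), xi = 0.1, shape_c = 2.5)
  v <- integrate(function(x) {
    vapply(x, function(xx)
      exp(truncated_cost_logdensity(par, c(0.5, -1, 1), 3, 3.4, xx, lower = 800)),
      numeric(1))
  }, 800, Inf, rel.tol = 1e-9)$value
  expect_lt(abs(v - 1), 1e-6)
  bp <- baseline_imp_params(1.4, 4.5)
  vb <- integrate(function(x) {
    vapply(x, function(xx) exp(baseline_imp_logdensity(bp, xx)), numeric(1))
  }, 0, 1.2, rel.tol = 1e-9)$value
  expect_lt(abs(vb - 1), 1e-6)
})
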