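#' HRQoL analysis-model parameter block (one per treatment arm)
#'
#' Houses every parameter of the hurdle-gamma utility model: `gamma0` are the
#' six hurdle time intercepts (logit scale), `omega` the four hurdle
#' coefficients on (baseline decrement, BMI, age, sex), `alpha0` the six
#' gamma-part time intercepts (log scale), `beta` the matching gamma-part
#' coefficients, `shape_q` the gamma shape, and (`theta_mu`, `theta_sd`) the
#' random-intercept law.  `theta_mu` defaults to 0: it is absorbed into
#' `alpha0` for identifiability.  The normal variant adds `sd_q`, the
#' residual standard deviation.
#'
#' @param gamma0,alpha0 numeric length-6 time intercepts.
#' @param omega,beta numeric length-4 coefficients (bq, bmi, age, sex).
#' @param shape_q positive gamma shape.
#' @param theta_mu,theta_sd random-intercept mean (fixed 0 by default) and sd.
#' @param sd_q residual sd for the normal variant (optional).
#' @return list of class `hrqol_params`.
#' @export
hrqol_params <- function(gamma0 = rep(0, 6), omega = rep(0, 4),
                         alpha0 = rep(0, 6), beta = rep(0, 4),
                         shape_q = 1, theta_mu = 0, theta_sd = 1, sd_q = 1) {
  stopifnot(length(gamma0) == 6L, length(alpha0) == 6L,
            length(omega) == 4L, length(beta) == 4L)
  if (!is.finite(shape_q) || shape_q <= 0) stop("shape_q must be > 0")
  if (!is.finite(theta_sd) || theta_sd <= 0) stop("theta_sd must be > 0")
  if (!is.finite(sd_q) || sd_q <= 0) stop("sd_q must be > 0")
  structure(list(gamma0 = gamma0, omega = omega, alpha0 = alpha0, beta = beta,
                 shape_q = shape_q, theta_mu = theta_mu, theta_sd = theta_sd,
                 sd_q = sd_q), class = "hrqol_params")
}

#' Conditional cost-model parameter block (one per treatment arm)
#'
#' @param zeta numeric length-4 log-scale coefficients (intercept, BMI, age,
#'   sex).
#' @param xi coupling coefficient on the QALY residual `Q_i - mu.Q_i`.
#' @param shape_c positive gamma shape.
#' @return list of class `cost_params`.
#' @export
cost_params <- function(zeta = rep(0, 4), xi = 0, shape_c = 1) {
  stopifnot(length(zeta) == 4L)
  if (!is.finite(shape_c) || shape_c <= 0) stop("shape_c must be > 0")
  structure(list(zeta = zeta, xi = xi, shape_c = shape_c),
            class = "cost_params")
}

#' Baseline HRQoL imputation parameters
#'
#' Gamma distribution for the baseline decrement, truncated above at 1.2 (the
#' largest viable EQ-5D decrement); the bound is fixed.
#'
#' @param shape_bq,rate_bq positive gamma shape and rate.
#' @return list of class `baseline_imp_params` (with `upper_bound = 1.2`).
#' @export
baseline_imp_params <- function(shape_bq = 1, rate_bq = 1) {
  if (!is.finite(shape_bq) || shape_bq <= 0) stop("shape_bq must be > 0")
  if (!is.finite(rate_bq) || rate_bq <= 0) stop("rate_bq must be > 0")
  structure(list(shape_bq = shape_bq, rate_bq = rate_bq, upper_bound = 1.2),
            class = "baseline_imp_params")
}

hrqol_linpreds <- function(params, theta_i, covariates, bq_i, t) {
  stopifnot(length(covariates) == 3L)
  eta_p <- params$gamma0[t] + params$omega[1] * bq_i +
    params$omega[2] * covariates[1] + params$omega[3] * covariates[2] +
    params$omega[4] * covariates[3]
  eta_mu <- params$alpha0[t] + theta_i + params$beta[1] * bq_i +
    params$beta[2] * covariates[1] + params$beta[3] * covariates[2] +
    params$beta[4] * covariates[3]
  list(p = stats::plogis(eta_p), mu = exp(eta_mu))
}

#' Hurdle-gamma log-density of an HRQoL decrement
#'
#' The decrement is 0 (full health) with probability `p_it` and otherwise
#' gamma with mean `mu.q_it` and shape `shape_q`, where
#' `logit(p_it) = gamma0_t + omega' (bq, bmi, age, sex)` and
#' `log(mu.q_it) = alpha0_t + theta_i + beta' (bq, bmi, age, sex)`.
#'
#' @param params an [hrqol_params()] block.
#' @param theta_i patient random intercept.
#' @param covariates numeric length-3 `(bmi, age, sex)` (centred as used in
#'   the linear predictors).
#' @param bq_i baseline HRQoL decrement.
#' @param t timepoint 1..6.
#' @param q_it observed decrement, `>= 0`.
#' @return log-density (scalar).
#' @export
hrqol_logdensity <- function(params, theta_i, covariates, bq_i, t, q_it) {
  if (!is.finite(q_it) || q_it < 0) stop("q_it must be a finite decrement >= 0")
  lp <- hrqol_linpreds(params, theta_i, covariates, bq_i, t)
  if (q_it == 0) {
    log(lp$p)
  } else {
    log1p(-lp$p) + stats::dgamma(q_it, shape = params$shape_q,
                                 rate = params$shape_q / lp$mu, log = TRUE)
  }
}

#' Plain-gamma variant of the HRQoL log-density
#'
#' Alternative to the hurdle for the family comparison.  The input must be
#' the positivity-shifted decrement `1 - HRQoL + eps` with `eps = 1e-4`, so
#' full health maps to `eps`, not 0.
#'
#' @inheritParams hrqol_logdensity
#' @param q_shifted positive shifted decrement.
#' @return log-density (scalar).
#' @export
hrqol_logdensity_gamma_variant <- function(params, theta_i, covariates, bq_i,
                                           t, q_shifted) {
  if (!is.finite(q_shifted) || q_shifted <= 0) {
    stop("gamma variant requires a strictly positive shifted decrement (1 - HRQoL + 1e-4)")
  }
  lp <- hrqol_linpreds(params, theta_i, covariates, bq_i, t)
  stats::dgamma(q_shifted, shape = params$shape_q,
                rate = params$shape_q / lp$mu, log = TRUE)
}

#' Normal variant of the HRQoL log-density
#'
#' Same linear predictor on the identity scale, residual sd `params$sd_q`.
#'
#' @inheritParams hrqol_logdensity
#' @return log-density (scalar).
#' @export
hrqol_logdensity_normal_variant <- function(params, theta_i, covariates, bq_i,
                                            t, q_it) {
  stopifnot(length(covariates) == 3L)
  mu <- params$alpha0[t] + theta_i + params$beta[1] * bq_i +
    params$beta[2] * covariates[1] + params$beta[3] * covariates[2] +
    params$beta[4] * covariates[3]
  stats::dnorm(q_it, mean = mu, sd = params$sd_q, log = TRUE)
}

#' QALYs from six HRQoL decrements by the area-under-the-curve method
#'
#' `Q = 0.5(1-q1) + 0.875(1-q2) + sum_{t=3..5}(1-q_t) + 0.5(1-q6)` over the
#' 3-month and yearly follow-ups, a linear-interpolation trapezoid with
#' weights (0.5, 0.875, 1, 1, 1, 0.5).
#'
#' @param q numeric length-6 decrements (finite).
#' @return five-year QALYs (scalar).
#' @export
qaly_from_decrements <- function(q) {
  if (length(q) != 6L || any(!is.finite(q))) {
    stop("q must be 6 finite decrements (3 months, years 1-5)")
  }
  w <- qaly_weights()
  sum(w * (1 - q))
}

qaly_weights <- function() c(0.5, 0.875, 1, 1, 1, 0.5)

#' Predicted HRQoL decrement at one timepoint
#'
#' Expectation mode returns `(1 - p_it) * mu.q_it`; stochastic mode draws the
#' hurdle indicator `pred.h ~ Bernoulli(p_it)` and returns
#' `(1 - pred.h) * mu.q_it`.
#'
#' @inheritParams hrqol_logdensity
#' @param mode `"expectation"` or `"stochastic"`.
#' @return list with `p`, `mu_q`, `pred_q`, and (stochastic mode) `pred_h`.
#' @export
predict_hrqol <- function(params, covariates, bq_i, t, theta_i = 0,
                          mode = c("expectation", "stochastic")) {
  mode <- match.arg(mode)
  lp <- hrqol_linpreds(params, theta_i, covariates, bq_i, t)
  if (mode == "expectation") {
    list(p = lp$p, mu_q = lp$mu, pred_q = (1 - lp$p) * lp$mu)
  } else {
    h <- stats::rbinom(1L, 1L, lp$p)
    list(p = lp$p, mu_q = lp$mu, pred_h = h, pred_q = (1 - h) * lp$mu)
  }
}

cost_mean_conditional <- function(params, covariates, Q_i, mu_Q_i) {
  exp(params$zeta[1] + params$zeta[2] * covariates[1] +
        params$zeta[3] * covariates[2] + params$zeta[4] * covariates[3] +
        params$xi * (Q_i - mu_Q_i))
}

#' Conditional gamma log-density of a 5-year total cost
#'
#' `c_i ~ Gamma(shape_c, shape_c / v.c_i)` with
#' `log(v.c_i) = zeta' (1, bmi, age, sex) + xi (Q_i - mu.Q_i)`: the cost mean
#' is shifted by the patient's QALY residual, inducing cost--outcome
#' correlation.
#'
#' @param params a [cost_params()] block.
#' @param covariates numeric length-3 `(bmi, age, sex)`.
#' @param Q_i realized 5-year QALYs; `mu_Q_i` their model-predicted mean.
#' @param mu_Q_i see `Q_i`.
#' @param c_i observed total cost, `> 0`.
#' @return log-density (scalar).
#' @export
cost_logdensity <- function(params, covariates, Q_i, mu_Q_i, c_i) {
  if (!is.finite(c_i) || c_i <= 0) stop("c_i must be > 0")
  v <- cost_mean_conditional(params, covariates, Q_i, mu_Q_i)
  stats::dgamma(c_i, shape = params$shape_c, rate = params$shape_c / v, log = TRUE)
}

#' Lower-truncated cost log-density for partially observed totals
#'
#' The gamma density renormalized to `(lower, Inf)`, where `lower` is the sum
#' of the patient's observed annual costs.  Returns `-Inf` at or below the
#' bound.
#'
#' @inheritParams cost_logdensity
#' @param lower truncation bound in GBP, `>= 0`.
#' @return log-density (scalar).
#' @export
truncated_cost_logdensity <- function(params, covariates, Q_i, mu_Q_i, c_i, lower) {
  if (!is.finite(lower) || lower < 0) stop("lower must be >= 0")
  if (!is.finite(c_i) || c_i <= lower) return(-Inf)
  v <- cost_mean_conditional(params, covariates, Q_i, mu_Q_i)
  rate <- params$shape_c / v
  log_tail <- stats::pgamma(lower, shape = params$shape_c, rate = rate,
                            lower.tail = FALSE, log.p = TRUE)
  stats::dgamma(c_i, shape = params$shape_c, rate = rate, log = TRUE) - log_tail
}

#' Marginal (recycled-prediction) cost mean
#'
#' `mu.c_i = exp(zeta' (1, bmi, age, sex))`: the conditional cost mean with
#' the QALY residual integrated out.
#'
#' @inheritParams cost_logdensity
#' @return expected cost in GBP (scalar).
#' @export
marginal_cost_mean <- function(params, covariates) {
  exp(params$zeta[1] + params$zeta[2] * covariates[1] +
        params$zeta[3] * covariates[2] + params$zeta[4] * covariates[3])
}

#' Upper-truncated gamma log-density for the baseline decrement
#'
#' `Gamma(shape_bq, rate_bq)` renormalized to `(0, 1.2]`; `-Inf` outside.
#'
#' @param params a [baseline_imp_params()] block.
#' @param bq baseline decrement.
#' @return log-density (scalar).
#' @export
baseline_imp_logdensity <- function(params, bq) {
  ub <- params$upper_bound
  if (!is.finite(bq) || bq <= 0 || bq > ub) return(-Inf)
  lz <- stats::pgamma(ub, shape = params$shape_bq, rate = params$rate_bq, log.p = TRUE)
  stats::dgamma(bq, shape = params$shape_bq, rate = params$rate_bq, log = TRUE) - lz
}

#' Sample from a doubly truncated gamma distribution
#'
#' Inverse-CDF sampler used for the baseline-decrement imputation bound
#' (upper 1.2) and for lower-bounded cost imputation.
#'
#' @param n number of draws.
#' @param shape,rate gamma parameters.
#' @param lower,upper truncation bounds.
#' @return numeric vector of draws strictly inside `(lower, upper)`.
#' @export
rtruncgamma <- function(n, shape, rate, lower = 0, upper = Inf) {
  plo <- stats::pgamma(lower, shape, rate)
  phi <- stats::pgamma(upper, shape, rate)
  if (phi - plo <= 0) stop("empty truncation region")
  u <- stats::runif(n, plo, phi)
  out <- stats::qgamma(pmin(pmax(u, .Machine$double.eps), 1 - 1e-16), shape, rate)
  pmin(pmax(out, lower + .Machine$double.xmin), upper)
}
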