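flat_hrqol <- function(alpha0_val, theta_sd = 1e-9) {
  hrqol_params(alpha0 = rep(log(alpha0_val), 6), theta_sd = theta_sd)
}

test_that("recycled predictions reproduce closed forms without crossover", {
  ds <- cea_dataset(toy_patients(4), matrix(0.2, 4, 6), matrix(100, 4, 5))
  # p = 0.5 both arms; gamma-part means 0.2 (MM) vs 0.1 (LS); costs 1000 vs 3000
  fit <- mock_fit(ds, flat_hrqol(0.2), flat_hrqol(0.1),
                  cost_params(zeta = c(log(1000), 0, 0, 0)),
                  cost_params(zeta = c(log(3000), 0, 0, 0)))
  pred <- recycled_predictions(fit)
  expect_equal(pred$delta_c, rep(3000 - 1000, 3))
  expect_equal(pred$delta_q, rep(4.875 * 0.5 * (0.2 - 0.1), 3), tolerance = 1e-6)
  expect_equal(pred$cost_arm[, 1], rep(1000, 3))
  # the year rows decompose the 5-year total exactly
  expect_equal(rowSums(pred$year_arm[, 2, ]), pred$total_arm[, 2])
})

test_that("crossover patients are predicted under treatment received", {
  # every patient crosses over: assignment cannot change any prediction
  ds_all <- cea_dataset(toy_patients(4, arm = c("LS", "LS", "MM", "MM"),
                                     recv = c("MM", "MM", "LS", "LS")),
                        matrix(0.2, 4, 6), matrix(100, 4, 5))
  fit <- mock_fit(ds_all, flat_hrqol(0.2), flat_hrqol(0.1),
                  cost_params(zeta = c(log(1000), 0, 0, 0)),
                  cost_params(zeta = c(log(3000), 0, 0, 0)))
  pred <- recycled_predictions(fit)
  expect_equal(pred$delta_q, rep(0, 3))
  expect_equal(pred$delta_c, rep(0, 3))

  # 2 LS-randomized patients, 1 crossover: increment halves
  ds_half <- cea_dataset(toy_patients(2, arm = c("LS", "LS"),
                                      recv = c("LS", "MM")),
                         matrix(0.2, 2, 6), matrix(100, 2, 5))
  fit2 <- mock_fit(ds_half, flat_hrqol(0.2), flat_hrqol(0.1),
                   cost_params(zeta = c(log(1000), 0, 0, 0)),
                   cost_params(zeta = c(log(3000), 0, 0, 0)))
  pred2 <- recycled_predictions(fit2)
  expect_equal(pred2$delta_c, rep(2000 / 2, 3))
})

test_that("identical arm parameters give zero increments in every draw", {
  ds <- cea_dataset(toy_patients(6), matrix(0.3, 6, 6), matrix(150, 6, 5))
  par <- hrqol_params(gamma0 = rnorm(6), omega = rnorm(4, 0, 0.2),
                      alpha0 = rnorm(6, -1), beta = rnorm(4, 0, 0.2),
                      shape_q = 2, theta_sd = 0.4)
  cpar <- cost_params(zeta = c(7.2, 0.01, 0.005, 0.1), xi = -0.5, shape_c = 2)
  fit <- mock_fit(ds, par, par, cpar, cpar)
  pred <- recycled_predictions(fit)
  expect_equal(pred$delta_q, rep(0, 3))
  expect_equal(pred$delta_c, rep(0, 3))
})

test_that("INB is the draw-wise identity with tie-split probability", {
  inb <- incremental_net_benefit(0.22, 1830, wtp = 20000)
  expect_equal(inb$mean, 2570)
  set.seed(2)
  dq <- rnorm(500, 0.2, 0.05)
  dc <- rnorm(500, 1800, 300)
  inb2 <- incremental_net_benefit(dq, dc, wtp = 15000)
  expect_equal(inb2$draws, 15000 * dq - dc)
  expect_equal(incremental_net_benefit(rep(0, 10), rep(0, 10))$p_positive, 0.5)
  expect_equal(incremental_net_benefit(dq, dc, wtp = 0)$draws, -dc)
  expect_error(incremental_net_benefit(dq, dc[-1]), "equal length")
})

test_that("the acceptability curve steps and saturates correctly", {
  dom <- ceac(rep(0.1, 50), rep(-500, 50))
  expect_true(all(dom$probability == 1))
  step <- ceac(rep(0.1, 40), rep(1000, 40), wtp_grid = c(9000, 10000, 11000))
  expect_equal(step$probability, c(0, 0.5, 1))
  one <- ceac(rnorm(100, 0.2, 0.1), rnorm(100, 1000, 100), wtp_grid = 20000)
  expect_equal(nrow(one), 1L)
  expect_error(ceac(1:3, 1:3, wtp_grid = c(-1, 0)), ">= 0")
  # monotone when every QALY draw is non-negative
  cc <- ceac(abs(rnorm(200, 0.1, 0.1)), rnorm(200, 500, 800))
  expect_true(all(diff(cc$probability) >= 0))
})

test_that("the per-year QALY table summarizes and tie-splits", {
  S <- 200
  set.seed(8)
  year_arm <- array(NA_real_, c(S, 2, 5))
  for (y in 1:5) {
    year_arm[, 1, y] <- rnorm(S, 0.7, 0.02)
    year_arm[, 2, y] <- year_arm[, 1, y]     # identical arms
  }
  pred <- structure(list(delta_q = rep(0, S), delta_c = rep(0, S),
                         year_arm = year_arm,
                         total_arm = cbind(rowSums(year_arm[, 1, ]),
                                           rowSums(year_arm[, 2, ])),
                         cost_arm = cbind(rep(1000, S), rep(3000, S)),
                         scenario = "MAR"), class = "cea_pred")
  tab <- annual_qaly_table(pred)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$difference, rep(0, 6))
  expect_equal(tab$prob_favors_LS, rep(0.5, 6))
  # stochastically larger LS
  year_arm[, 2, ] <- year_arm[, 2, ] + 0.03
  pred$year_arm <- year_arm
  pred$total_arm <- cbind(rowSums(year_arm[, 1, ]), rowSums(year_arm[, 2, ]))
  tab2 <- annual_qaly_table(pred)
  expect_true(all(tab2$prob_favors_LS > 0.5))
  expect_equal(tab2$mean_LS[6], sum(tab2$mean_LS[1:5]))
})

test_that("scenario comparison table round-trips and rejects duplicates", {
  ds <- cea_dataset(toy_patients(4), matrix(0.2, 4, 6), matrix(100, 4, 5))
  fit <- mock_fit(ds, flat_hrqol(0.2), flat_hrqol(0.1),
                  cost_params(zeta = c(log(1000), 0, 0, 0)),
                  cost_params(zeta = c(log(3000), 0, 0, 0)))
  pred <- recycled_predictions(fit)
  r1 <- cea_result(pred, wtp = 20000, scenario = "MAR")
  tab1 <- scenario_compare(list(r1))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$inb, 20000 * mean(pred$delta_q) - 2000)
  expect_error(scenario_compare(list(r1, r1)), "duplicated")
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab1, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$qaly_diff, tab1$qaly_diff)
  expect_equal(back$scenario, tab1$scenario)
})

test_that("imputation summaries exist only for missing cells", {
  q <- matrix(0.2, 3, 6)
  q[2, 4] <- NA
  ds <- cea_dataset(toy_patients(3), q, matrix(100, 3, 5))
  fit <- mock_fit(ds, flat_hrqol(0.2), flat_hrqol(0.2),
                  cost_params(), cost_params())
  fit$draws$hmis <- matrix(c(1, 0, 0), 3, 1)
  fit$draws$qpos <- matrix(0.4, 3, 1)
  out <- imputation_density_summary(fit, "T002", 4)
  expect_equal(out$zero_mass_prob, 1 / 3)
  expect_equal(out$mean, mean(c(0, 0.4, 0.4)))
  expect_equal(out$scenario, "MAR")
  expect_error(imputation_density_summary(fit, "T001", 1), "observed")
  expect_error(imputation_density_summary(fit, "Z999", 4), "unknown patient")
  # hurdle certain for the missing cell -> zero-mass probability one
  fit$draws$hmis <- matrix(1, 3, 1)
  expect_equal(imputation_density_summary(fit, "T002", 4)$zero_mass_prob, 1)
})
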