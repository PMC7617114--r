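# one small fit with every kind of missing quantity, shared across tests
small_sim <- generate_dataset(default_reflux_like_config(n_patients = 60, seed = 8))
small_fit <- fit_quick(small_sim$dataset, "MAR", include_missingness_model = FALSE,
                       seed = 4, mcmc = list(chains = 2L, adapt = 150L,
                                             burnin = 100L, iter = 250L))

test_that("model assembly creates exactly the latent structure the data need", {
  ds <- complete_dataset(20, seed = 5)
  spec <- joint_model_spec(scenario = build_scenario("MAR"),
                           include_missingness_model = FALSE)
  m <- build_joint_model(ds, spec)
  expect_equal(m$n_latent_q, 0L)
  expect_equal(m$n_partial_costs, 0L)
  expect_equal(m$n_missing_bq, 0L)
  expect_false(grepl("hmis", m$model_string))

  # one deleted annual cost -> one truncated latent total with the right bound
  ds2 <- ds
  ds2$annual_cost[3, 2] <- NA
  ds2 <- cea_dataset(ds2$patients, ds2$q, ds2$annual_cost)
  m2 <- build_joint_model(ds2, spec)
  expect_equal(m2$n_partial_costs, 1L)
  expect_equal(m2$partial_cost_bounds,
               sum(ds2$annual_cost[3, ], na.rm = TRUE))
  expect_true(grepl("T\\(clb\\[i\\],\\)", m2$model_string))

  # CCA forces the complete-case subset
  mcca <- build_joint_model(small_sim$dataset,
                            joint_model_spec(scenario = build_scenario("CCA")))
  expect_lt(mcca$ds$n, small_sim$dataset$n)
  expect_equal(sum(is.na(mcca$ds$q)), 0L)
  expect_error(joint_model_spec(scenario = build_scenario("CCA"),
                                include_missingness_model = TRUE),
               "complete-case")
})

test_that("latent decrements enter the missingness likelihood only through selection", {
  ds <- ds_from_patterns(list(c(1, 2, 4, 5, 6), 1:6))
  ind <- classify_missingness(ds)
  fill <- function(v) {
    q <- ds$q
    q[is.na(q)] <- v
    q
  }
  # lambda = 0 and no previous.q coefficient: the latent value is ignorable
  mar <- missingness_params(kappa0 = matrix(-1, 6, 2))
  pb <- list(MM = mar, LS = mar)
  expect_equal(missingness_loglik(pb, ds, ind, fill(0.1)),
               missingness_loglik(pb, ds, ind, fill(0.9)))
  # a nonzero selection coefficient makes it informative
  mnar <- missingness_params(kappa0 = matrix(-1, 6, 2), lambda = c(0.69, 0.69))
  pb2 <- list(MM = mnar, LS = mnar)
  expect_false(isTRUE(all.equal(missingness_loglik(pb2, ds, ind, fill(0.1)),
                                missingness_loglik(pb2, ds, ind, fill(0.9)))))
})

test_that("sampling is deterministic given the seed", {
  ds <- complete_dataset(16, seed = 12)
  mc <- list(chains = 1L, adapt = 100L, burnin = 50L, iter = 120L)
  f1 <- fit_quick(ds, "MAR", include_missingness_model = FALSE, seed = 33, mcmc = mc)
  f2 <- fit_quick(ds, "MAR", include_missingness_model = FALSE, seed = 33, mcmc = mc)
  expect_identical(f1$draws$alpha0, f2$draws$alpha0)
  expect_identical(f1$draws$shape.c, f2$draws$shape.c)
  f3 <- fit_quick(ds, "MAR", include_missingness_model = FALSE, seed = 34, mcmc = mc)
  expect_false(identical(f1$draws$alpha0, f3$draws$alpha0))
})

test_that("imputations respect their truncation bounds in every retained draw", {
  ds <- small_sim$dataset
  part <- which(ds$total_cost_status == "partial")
  # strictly above the bound up to double precision: when the bound falls in
  # the far upper tail of the conditional gamma, the inverse-CDF draw can
  # land on the bound itself
  cimp <- imputed_cost(small_fit)
  for (i in part) expect_true(all(cimp[, i] >= ds$cost_lower[i]))
  expect_gt(max(cimp[, part[1]]) , ds$cost_lower[part[1]])
  bimp <- imputed_bq(small_fit)
  expect_true(all(bimp <= 1.2 + 1e-9))
  qimp <- imputed_q(small_fit)
  expect_true(all(qimp >= 0))
  # observed cells are constant across draws
  oc <- which(!is.na(ds$q), arr.ind = TRUE)[1, ]
  expect_true(all(qimp[, oc[1], oc[2]] == ds$q[oc[1], oc[2]]))
})

test_that("convergence report flags and serializes", {
  expect_warning(convergence_report(fit_quick(complete_dataset(16, seed = 12),
                                              "MAR", include_missingness_model = FALSE,
                                              seed = 1,
                                              mcmc = list(chains = 1L, adapt = 100L,
                                                          burnin = 50L, iter = 100L))),
                 "single chain")
  rep2 <- convergence_report(small_fit)
  expect_true(all(c("parameter", "rhat", "ess", "flagged") %in% names(rep2$table)))
  expect_false(any(grepl("^theta|^hmis|^qpos", rep2$table$parameter)))
  js <- jsonlite::toJSON(rep2[c("table", "n_flagged", "chains")],
                         dataframe = "rows", auto_unbox = TRUE)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$n_flagged, rep2$n_flagged)
  expect_equal(nrow(back$table), nrow(rep2$table))
})

test_that("DIC is additive over components and has zero pD at a point mass", {
  dic <- compute_dic(small_fit, max_draws = 60)
  tot <- dic[dic$component == "total", ]
  expect_equal(tot$DIC, sum(dic$DIC[dic$component != "total"]))
  expect_false(dic$comparable_across_families[dic$component == "hrqol"])
  # the HRQoL component carries many real parameters; its effective size is
  # clearly positive (components with plugged-in latent data can go mildly
  # negative, a known artifact of conditional DIC)
  expect_gt(dic$pD[dic$component == "hrqol"], 5)

  # a point-mass posterior: every draw replaced by draw 1
  point <- small_fit
  for (nm in names(point$draws)) {
    d <- point$draws[[nm]]
    if (is.null(dim(d))) {
      point$draws[[nm]] <- rep(d[1], length(d))
    } else {
      one <- apply(d, seq_along(dim(d))[-1], function(x) x[1])
      point$draws[[nm]] <- array(rep(as.numeric(one), each = dim(d)[1]),
                                 dim = dim(d))
    }
  }
  dic_pt <- compute_dic(point, max_draws = 40)
  expect_true(all(abs(dic_pt$pD) < 1e-6))
  expect_equal(dic_pt$DIC, dic_pt$Dbar, tolerance = 1e-8)
})

test_that("random intercepts lower the DIC on multi-level data", {
  ds <- complete_dataset(60, seed = 14)   # generated with theta_sd = 0.4
  mc <- list(chains = 1L, adapt = 150L, burnin = 100L, iter = 300L)
  fit_ri <- sample_posterior(build_joint_model(ds,
    joint_model_spec("normal", build_scenario("CCA"),
                     include_random_intercepts = TRUE)),
    chains = mc$chains, adapt = mc$adapt, burnin = mc$burnin, iter = mc$iter,
    seed = 2)
  fit_no <- sample_posterior(build_joint_model(ds,
    joint_model_spec("normal", build_scenario("CCA"),
                     include_random_intercepts = FALSE)),
    chains = mc$chains, adapt = mc$adapt, burnin = mc$burnin, iter = mc$iter,
    seed = 2)
  dic_ri <- compute_dic(fit_ri, max_draws = 100)
  dic_no <- compute_dic(fit_no, max_draws = 100)
  expect_lt(dic_ri$DIC[dic_ri$component == "hrqol"],
            dic_no$DIC[dic_no$component == "hrqol"])
})

test_that("grid posterior normalizes, converges under refinement, and refuses 3D", {
  lp <- function(x) dnorm(x[1], 0.3, 0.5, log = TRUE)
  g1 <- brute_force_posterior(lp, list(a = seq(-3, 3, length.out = 301)))
  dx <- diff(g1$grid$a)[1]
  expect_lt(abs(sum(g1$density) * dx - 1), 1e-6)
  expect_equal(unname(g1$mean["a"]), 0.3, tolerance = 1e-6)
  g2 <- brute_force_posterior(lp, list(a = seq(-3, 3, length.out = 601)))
  expect_lt(abs(g1$mean["a"] - g2$mean["a"]), 1e-3)
  expect_error(brute_force_posterior(lp, list(a = 1:3, b = 1:3, c = 1:3)),
               "2 dimensions")
})

test_that("posterior predictive checks expose the missing spike under a gamma family", {
  ds <- complete_dataset(50, seed = 16)
  expect_gt(mean(ds$q == 0), 0.1)   # data carry a genuine spike at full health
  fit_g <- fit_quick(ds, "MAR", include_missingness_model = FALSE,
                     hrqol_family = "gamma", seed = 3,
                     mcmc = list(chains = 1L, adapt = 150L, burnin = 100L,
                                 iter = 200L))
  ppc <- posterior_predictive_check(fit_g, statistics = "zero_prop",
                                    max_draws = 60, seed = 9)
  expect_lt(ppc$p_value, 0.01)      # a plain gamma cannot generate zeros
  # empty statistic list -> empty table
  empty <- posterior_predictive_check(small_fit, statistics = character(0))
  expect_equal(nrow(empty), 0L)
  # well-specified model: observed spike is not flagged
  ppc_h <- posterior_predictive_check(small_fit, statistics = c("zero_prop", "cost_mean"),
                                      max_draws = 60, seed = 9)
  expect_true(all(ppc_h$p_value > 0.01 & ppc_h$p_value < 0.99))
})
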