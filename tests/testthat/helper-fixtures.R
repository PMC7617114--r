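# small programmatic fixtures shared across test files

toy_patients <- function(n, arm = rep(c("MM", "LS"), length.out = n),
                         recv = arm, bq = rep(0.3, n)) {
  data.frame(patient_id = sprintf("T%03d", seq_len(n)),
             arm_randomized = arm, arm_received = recv,
             age = seq(40, 55, length.out = n), bmi = seq(24, 32, length.out = n),
             sex = rep_len(c(0, 1), n), bq = bq, stringsAsFactors = FALSE)
}

# dataset with hand-set missingness patterns; obs cells get q = 0.2 + t/100
ds_from_patterns <- function(patterns) {
  n <- length(patterns)
  q <- matrix(NA_real_, n, 6L)
  for (i in seq_len(n)) {
    obs <- patterns[[i]]
    q[i, obs] <- 0.2 + obs / 100
  }
  ac <- matrix(rep(c(500, 200, 200, 200, 200), each = n), n, 5L)
  cea_dataset(toy_patients(n), q, ac)
}

# complete synthetic dataset (missingness switched off)
complete_config <- function(n, seed = 1L) {
  cfg <- default_reflux_like_config(n_patients = n, seed = seed)
  for (a in c("MM", "LS")) cfg$missing_truth[[a]]$kappa0[] <- -30
  cfg$bq_missing_prob <- 0
  cfg$cost_year_missing_prob <- 0
  cfg
}

complete_dataset <- function(n, seed = 1L) {
  generate_dataset(complete_config(n, seed))$dataset
}

quick_mcmc <- list(chains = 1L, adapt = 150L, burnin = 100L, iter = 300L)

fit_quick <- function(ds, scenario = "MAR", include_missingness_model = NULL,
                      hrqol_family = "hurdle", seed = 1L, mcmc = quick_mcmc) {
  fit_scenario(ds, scenario, hrqol_family = hrqol_family,
               include_missingness_model = include_missingness_model,
               chains = mcmc$chains, adapt = mcmc$adapt, burnin = mcmc$burnin,
               iter = mcmc$iter, seed = seed)
}

# posterior mean of a missing decrement under the selection factor, by
# quadrature of hurdle density x multinomial category probability
selection_mean <- function(hpar, mpar, covs, bq, t, prev, m_cat) {
  wts <- function(q) {
    vapply(q, function(qq) {
      dens <- exp(hrqol_logdensity(hpar, 0, covs, bq, t, qq))
      sel <- missingness_probs(mpar, covs, t, prev, compute_change_q(prev, qq))[m_cat]
      dens * sel
    }, numeric(1))
  }
  grid <- seq(1e-6, 4, length.out = 2000)
  dx <- diff(grid)[1]
  w0 <- wts(0)
  wc <- wts(grid)
  (sum(grid * wc) * dx) / (w0 + sum(wc) * dx)
}

# mock posterior: S identical draws at hand-set parameter values, attached to
# a real (unfitted) model object, for closed-form output checks
mock_fit <- function(ds, params_mm, params_ls, cost_mm, cost_ls, S = 3L,
                     scenario = build_scenario("MAR")) {
  spec <- joint_model_spec(scenario = scenario,
                           include_missingness_model = FALSE)
  model <- build_joint_model(ds, spec)
  rep_arr <- function(x) {
    d <- c(S, dim(as.array(x)))
    array(rep(as.numeric(x), each = S), dim = d)
  }
  hp <- list(params_mm, params_ls)
  cp <- list(cost_mm, cost_ls)
  draws <- list(
    gamma0 = rep_arr(rbind(hp[[1]]$gamma0, hp[[2]]$gamma0)),
    omega = rep_arr(rbind(hp[[1]]$omega, hp[[2]]$omega)),
    alpha0 = rep_arr(rbind(hp[[1]]$alpha0, hp[[2]]$alpha0)),
    beta = rep_arr(rbind(hp[[1]]$beta, hp[[2]]$beta)),
    shape.q = rep_arr(c(hp[[1]]$shape_q, hp[[2]]$shape_q)),
    sigma.theta = rep_arr(c(hp[[1]]$theta_sd, hp[[2]]$theta_sd)),
    zeta = rep_arr(rbind(cp[[1]]$zeta, cp[[2]]$zeta)),
    xi = rep_arr(c(cp[[1]]$xi, cp[[2]]$xi)),
    shape.c = rep_arr(c(cp[[1]]$shape_c, cp[[2]]$shape_c)),
    shape.bq = rep(1, S), rate.bq = rep(1, S),
    theta = matrix(0, S, ds$n)
  )
  structure(list(draws = draws, coda = NULL, model = model, S = S,
                 mcmc = list()), class = "cea_fit")
}
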