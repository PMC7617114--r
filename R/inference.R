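EPS_DECREMENT <- 1e-4
ZEROS_C <- 10000

#' Specification of the joint Bayesian model
#'
#' Collects the structural choices for one fit: the HRQoL outcome family,
#' whether patient random intercepts are used, the missing-data scenario, and
#' whether the response-missingness sub-model is included.  Omitting the
#' missingness model leaves the missing values drawn from their posterior
#' under missing-at-random.  A CCA scenario forces complete-case subsetting
#' and drops the missingness model.
#'
#' @param hrqol_family `"hurdle"`, `"gamma"`, or `"normal"`.
#' @param scenario a `scenario_spec` from [build_scenario()] /
#'   [custom_scenario()].
#' @param include_random_intercepts logical.
#' @param include_missingness_model logical; defaults to the scenario's flag.
#' @return list of class `joint_model_spec`.
#' @export
joint_model_spec <- function(hrqol_family = c("hurdle", "gamma", "normal"),
                             scenario = build_scenario("MAR"),
                             include_random_intercepts = TRUE,
                             include_missingness_model = scenario$include_missingness_model) {
  hrqol_family <- match.arg(hrqol_family)
  stopifnot(inherits(scenario, "scenario_spec"))
  if (scenario$complete_cases && include_missingness_model) {
    stop("a complete-case scenario cannot include the missingness model")
  }
  structure(list(hrqol_family = hrqol_family, scenario = scenario,
                 include_random_intercepts = include_random_intercepts,
                 include_missingness_model = include_missingness_model),
            class = "joint_model_spec")
}

complete_case_subset <- function(ds) {
  keep <- rowSums(is.na(ds$q)) == 0L & !is.na(ds$patients$bq) &
    ds$total_cost_status == "observed"
  cea_dataset(ds$patients[keep, , drop = FALSE], ds$q[keep, , drop = FALSE],
              ds$annual_cost[keep, , drop = FALSE])
}

# one JAGS code block per model component; assembled conditionally
jags_priors_block <- function(spec) {
  ri <- spec$include_random_intercepts
  fam <- spec$hrqol_family
  txt <- c(
    "  for (a in 1:2) {",
    "    for (t in 1:6) { alpha0[a,t] ~ dnorm(0, 0.01) }",
    "    for (j in 1:4) { beta[a,j] ~ dnorm(0, 0.01) }",
    if (fam == "hurdle") c(
      "    for (t in 1:6) { gamma0[a,t] ~ dnorm(0, 0.01) }",
      "    for (j in 1:4) { omega[a,j] ~ dnorm(0, 0.01) }"),
    if (fam != "normal") "    shape.q[a] ~ dnorm(0, 0.01) T(0.001,)",
    if (fam == "normal") c("    sd.q[a] ~ dnorm(0, 0.01) T(0.001,)",
                           "    tau.q[a] <- 1/pow(sd.q[a],2)"),
    if (ri) c("    sigma.theta[a] ~ dnorm(0, 0.04) T(0.001,)",
              "    tau.theta[a] <- 1/pow(sigma.theta[a],2)"),
    "    for (j in 1:4) { zeta[a,j] ~ dnorm(0, 0.01) }",
    "    xi[a] ~ dnorm(0, 0.01)",
    "    shape.c[a] ~ dnorm(0, 0.01) T(0.001,)",
    if (spec$include_missingness_model) c(
      "    for (t in 1:6) { for (r in 1:2) { kappa0[a,t,r] ~ dnorm(0, 0.01) } }",
      "    for (r in 1:2) { for (j in 1:4) { kappa[a,r,j] ~ dnorm(0, 0.01) } }"),
    "  }",
    "  shape.bq ~ dnorm(0, 0.01) T(0.001,)",
    "  rate.bq ~ dnorm(0, 0.01) T(0.001,)"
  )
  txt
}

jags_linpred_block <- function(spec) {
  ri <- spec$include_random_intercepts
  fam <- spec$hrqol_family
  th <- if (ri) " + theta[i]" else ""
  c(
    "  for (i in 1:N) {",
    "    bqe[i] ~ dgamma(shape.bq, rate.bq) T(, 1.2001)",
    "    bqi[i] <- bqe[i] - 0.0001",
    if (ri) "    theta[i] ~ dnorm(0, tau.theta[arm[i]])",
    "    for (t in 1:6) {",
    if (fam == "hurdle") c(
      "      logit(p[i,t]) <- gamma0[arm[i],t] + omega[arm[i],1]*bqi[i] + omega[arm[i],2]*cbmi[i] + omega[arm[i],3]*cage[i] + omega[arm[i],4]*sex[i]"),
    paste0("      eta.q[i,t] <- alpha0[arm[i],t]", th,
           " + beta[arm[i],1]*bqi[i] + beta[arm[i],2]*cbmi[i] + beta[arm[i],3]*cage[i] + beta[arm[i],4]*sex[i]"),
    # the exp() caps keep gamma rates finite during adaptation excursions;
    # they are far outside the data-supported region and inactive at the
    # posterior
    if (fam == "normal") "      mu.q[i,t] <- eta.q[i,t]"
    else "      mu.q[i,t] <- exp(min(max(eta.q[i,t], -20), 7))",
    # predicted decrements feeding mu.Q are held to the viable EQ-5D range,
    # like the latent imputations; without the bound a transient excursion
    # of the gamma-part mean sends mu.Q off scale and flattens the cost
    # conditionals into an inescapable plateau
    switch(spec$hrqol_family,
      hurdle = "      pred.q[i,t] <- min((1-p[i,t])*mu.q[i,t], 1.6)",
      gamma  = "      pred.q[i,t] <- min(mu.q[i,t] - 0.0001, 1.6)",
      normal = "      pred.q[i,t] <- min(max(mu.q[i,t], -0.6), 1.6)"),
    "    }",
    "    mu.Q[i] <- 0.5*(1-pred.q[i,1]) + 0.875*(1-pred.q[i,2]) + (1-pred.q[i,3]) + (1-pred.q[i,4]) + (1-pred.q[i,5]) + 0.5*(1-pred.q[i,6])",
    "    Q[i] <- 0.5*(1-qq[i,1]) + 0.875*(1-qq[i,2]) + (1-qq[i,3]) + (1-qq[i,4]) + (1-qq[i,5]) + 0.5*(1-qq[i,6])",
    "    eta.c[i] <- zeta[arm[i],1] + zeta[arm[i],2]*cbmi[i] + zeta[arm[i],3]*cage[i] + zeta[arm[i],4]*sex[i] + xi[arm[i]]*(Q[i]-mu.Q[i])",
    "    v.c[i] <- exp(min(max(eta.c[i], -20), 23))",
    "    cst[i] ~ dgamma(shape.c[arm[i]], shape.c[arm[i]]/v.c[i]) T(clb[i],)",
    "  }"
  )
}

jags_hrqol_block <- function(spec, has_missing) {
  fam <- spec$hrqol_family
  if (fam == "hurdle") {
    c(
      "  for (j in 1:Nobs) {",
      "    qq[obsI[j], obsT[j]] <- qdat[j]",
      "    ll[j] <- zq[j]*log(p[obsI[j],obsT[j]]) + (1-zq[j])*(log(1-p[obsI[j],obsT[j]])",
      "             + shape.q[arm[obsI[j]]]*log(shape.q[arm[obsI[j]]]/mu.q[obsI[j],obsT[j]])",
      "             + (shape.q[arm[obsI[j]]]-1)*log(qsafe[j])",
      "             - (shape.q[arm[obsI[j]]]/mu.q[obsI[j],obsT[j]])*qsafe[j]",
      "             - loggam(shape.q[arm[obsI[j]]]))",
      paste0("    zeros[j] ~ dpois(", ZEROS_C, " - ll[j])"),
      "  }",
      if (has_missing) c(
        "  for (k in 1:Nmis) {",
        "    hmis[k] ~ dbern(p[misI[k], misT[k]])",
        # latent decrements are restricted to the viable EQ-5D range
        # (utility >= -0.6), mirroring the 1.2 bound on baseline decrements
        "    qpos[k] ~ dgamma(shape.q[arm[misI[k]]], shape.q[arm[misI[k]]]/mu.q[misI[k],misT[k]]) T(,1.6)",
        "    qq[misI[k], misT[k]] <- (1-hmis[k])*qpos[k]",
        "  }")
    )
  } else if (fam == "gamma") {
    c("  for (i in 1:N) { for (t in 1:6) {",
      "    qe[i,t] ~ dgamma(shape.q[arm[i]], shape.q[arm[i]]/mu.q[i,t])",
      "    qq[i,t] <- qe[i,t] - 0.0001",
      "  } }")
  } else {
    c("  for (i in 1:N) { for (t in 1:6) {",
      "    qn[i,t] ~ dnorm(mu.q[i,t], tau.q[arm[i]])",
      "    qq[i,t] <- qn[i,t]",
      "  } }")
  }
}

jags_missingness_block <- function() {
  c(
    "  for (u in 1:Nm) {",
    "    prevq[u] <- ifelse(mT[u]==1, bqi[mI[u]], qq[mI[u], mTm1[u]])",
    "    chq[u] <- prevq[u] - qq[mI[u], mT[u]]",
    "    phi[u,1] <- 1",
    "    for (r in 1:2) {",
    "      log(phi[u,r+1]) <- kappa0[arm[mI[u]],mT[u],r] + kappa[arm[mI[u]],r,1]*cbmi[mI[u]] + kappa[arm[mI[u]],r,2]*cage[mI[u]] + kappa[arm[mI[u]],r,3]*sex[mI[u]] + kappa[arm[mI[u]],r,4]*prevq[u] + lambda[arm[mI[u]],r]*chq[u]",
    "    }",
    "    mcat[u] ~ dcat(phi[u,1:3])",
    "  }"
  )
}

#' Assemble the joint model for a dataset and specification
#'
#' Builds the full joint posterior: the HRQoL likelihood over observed cells
#' plus latent nodes for missing cells, the (lower-truncated, for partially
#' observed totals) cost likelihood, the truncated-gamma baseline imputation
#' model, the multinomial missingness likelihood wired to the latent
#' decrements through `change.q` when enabled, and the priors.  All outcome
#' parameters are indexed by the arm received; age and BMI are centred at
#' their sample means (stored on the object).
#'
#' @param ds a [cea_dataset()].
#' @param spec a [joint_model_spec()].
#' @return list of class `cea_joint_model` with the generated JAGS program
#'   (`model_string`), the data list, cell index maps, and the (possibly
#'   complete-case subsetted) dataset.
#' @export
build_joint_model <- function(ds, spec) {
  stopifnot(inherits(ds, "cea_dataset"), inherits(spec, "joint_model_spec"))
  if (spec$scenario$complete_cases) ds <- complete_case_subset(ds)
  if (ds$n < 2L) stop("dataset too small to fit (", ds$n, " patients)")
  p <- ds$patients
  arm <- ifelse(p$arm_received == "LS", 2L, 1L)
  centers <- c(age = mean(p$age), bmi = mean(p$bmi))
  cage <- p$age - centers["age"]
  cbmi <- p$bmi - centers["bmi"]

  obs <- which(!is.na(ds$q), arr.ind = TRUE)
  mis <- which(is.na(ds$q), arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("no observed HRQoL values")
  ind <- classify_missingness(ds)
  tmax <- ifelse(is.na(ind$ltfu_time), 6L, ind$ltfu_time)
  mcells <- do.call(rbind, lapply(seq_len(ds$n), function(i) cbind(i, seq_len(tmax[i]))))
  mcat <- ind$m[mcells]

  lambda <- matrix(spec$scenario$lambda, 2L, 2L, byrow = TRUE)  # rows MM, LS

  dat <- list(N = ds$n, arm = arm, cbmi = as.numeric(cbmi),
              cage = as.numeric(cage), sex = as.numeric(p$sex),
              bqe = p$bq + EPS_DECREMENT,
              cst = ds$total_cost,
              # truncation bounds act only on imputed partial totals;
              # observed totals must not be truncated at their own value
              clb = ifelse(ds$total_cost_status == "partial",
                           ds$cost_lower, 0))
  fam <- spec$hrqol_family
  if (fam == "hurdle") {
    qobs <- ds$q[obs]
    dat <- c(dat, list(Nobs = nrow(obs), obsI = obs[, 1], obsT = obs[, 2],
                       qdat = qobs, zq = as.integer(qobs == 0),
                       qsafe = pmax(qobs, 1e-12), zeros = rep(0, nrow(obs))))
    if (nrow(mis) > 0L) {
      dat <- c(dat, list(Nmis = nrow(mis), misI = mis[, 1], misT = mis[, 2]))
    }
  } else if (fam == "gamma") {
    dat$qe <- ds$q + EPS_DECREMENT
  } else {
    dat$qn <- ds$q
  }
  if (spec$include_missingness_model) {
    dat <- c(dat, list(Nm = nrow(mcells), mI = mcells[, 1], mT = mcells[, 2],
                       mTm1 = pmax(mcells[, 2] - 1L, 1L), mcat = mcat,
                       lambda = lambda))
  }

  model_string <- paste(c(
    "model {",
    jags_priors_block(spec),
    jags_linpred_block(spec),
    jags_hrqol_block(spec, has_missing = nrow(mis) > 0L),
    if (spec$include_missingness_model) jags_missingness_block(),
    "}"), collapse = "\n")

  structure(list(
    model_string = model_string, data = dat, spec = spec, ds = ds,
    centers = centers, arm = arm, obs_cells = obs, mis_cells = mis,
    multinomial_cells = mcells, mcat = mcat, indicators = ind,
    n_latent_q = nrow(mis),
    n_partial_costs = sum(ds$total_cost_status == "partial"),
    partial_cost_bounds = ds$cost_lower[ds$total_cost_status == "partial"],
    n_missing_bq = sum(is.na(p$bq))
  ), class = "cea_joint_model")
}

model_monitors <- function(model) {
  spec <- model$spec
  mon <- c("alpha0", "beta", "zeta", "xi", "shape.c", "shape.bq", "rate.bq")
  mon <- c(mon, switch(spec$hrqol_family,
                       hurdle = c("gamma0", "omega", "shape.q"),
                       gamma = "shape.q", normal = "sd.q"))
  if (spec$include_random_intercepts) mon <- c(mon, "sigma.theta", "theta")
  if (spec$include_missingness_model) mon <- c(mon, "kappa0", "kappa")
  if (spec$hrqol_family == "hurdle" && model$n_latent_q > 0L) {
    mon <- c(mon, "hmis", "qpos")
  }
  if (spec$hrqol_family == "gamma" && model$n_latent_q > 0L) mon <- c(mon, "qe")
  if (spec$hrqol_family == "normal" && model$n_latent_q > 0L) mon <- c(mon, "qn")
  if (model$n_missing_bq > 0L) mon <- c(mon, "bqe")
  if (any(is.na(model$data$cst))) mon <- c(mon, "cst")
  mon
}

model_inits <- function(model, chain, seed) {
  init <- list(.RNG.name = "base::Mersenne-Twister",
               .RNG.seed = as.integer((seed %% 100000L) * 100L + chain))
  fam <- model$spec$hrqol_family
  if (fam != "normal") init$shape.q <- c(1, 1) else init$sd.q <- c(0.3, 0.3)
  init$shape.c <- c(1, 1)
  init$shape.bq <- 1
  init$rate.bq <- 2
  obs_cost <- model$data$cst[!is.na(model$data$cst)]
  mc <- if (length(obs_cost) > 0L) log(mean(obs_cost) + 1) else 7
  init$zeta <- matrix(c(mc, 0, 0, 0, mc, 0, 0, 0), 2L, 4L, byrow = TRUE)
  init$alpha0 <- matrix(if (fam == "normal") 0.3 else -1, 2L, 6L)
  if (model$spec$include_random_intercepts) init$sigma.theta <- c(0.3, 0.3)
  init
}

#' Draw from the joint posterior with JAGS
#'
#' Runs MCMC on a built model and returns structured posterior draws over
#' every parameter block, the random intercepts, and all imputed missing
#' quantities.  Deterministic given `seed` and the chain settings: chain
#' RNG seeds are derived from `seed`.
#'
#' @param model a [build_joint_model()] result.
#' @param chains,adapt,burnin,iter,thin MCMC settings.
#' @param seed integer seed.
#' @param quiet suppress JAGS progress output.
#' @return list of class `cea_fit` with `draws` (named list of arrays, first
#'   dimension = retained draws pooled over chains), `coda`
#'   (a [coda::mcmc.list]), `model`, and the MCMC settings.
#' @export
sample_posterior <- function(model, chains = 2L, adapt = 500L, burnin = 500L,
                             iter = 1000L, thin = 1L, seed = 1L, quiet = TRUE) {
  stopifnot(inherits(model, "cea_joint_model"))
  inits <- lapply(seq_len(chains), function(ch) model_inits(model, ch, seed))
  dat <- Filter(Negate(is.null), model$data)
  jm <- rjags::jags.model(textConnection(model$model_string), data = dat,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  if (burnin > 0L) stats::update(jm, burnin, progress.bar = "none")
  mon <- model_monitors(model)
  co <- rjags::coda.samples(jm, variable.names = mon, n.iter = iter,
                            thin = thin, progress.bar = "none")
  mat <- as.matrix(co)
  draws <- split_draws(mat)
  structure(list(draws = draws, coda = co, model = model, S = nrow(mat),
                 mcmc = list(chains = chains, adapt = adapt, burnin = burnin,
                             iter = iter, thin = thin, seed = seed)),
            class = "cea_fit")
}

# reshape a flat coda matrix into one array per JAGS variable
split_draws <- function(mat) {
  vn <- colnames(mat)
  base <- sub("\\[.*$", "", vn)
  out <- list()
  for (nm in unique(base)) {
    cols <- which(base == nm)
    idx_str <- sub("^[^\\[]*\\[?", "", sub("\\]$", "", vn[cols]))
    if (all(idx_str == "")) {
      out[[nm]] <- mat[, cols]
      next
    }
    idx <- do.call(rbind, lapply(strsplit(idx_str, ","), as.integer))
    dims <- apply(idx, 2L, max)
    arr <- array(NA_real_, dim = c(nrow(mat), dims))
    for (j in seq_along(cols)) {
      pos <- cbind(seq_len(nrow(mat)),
                   matrix(idx[j, ], nrow(mat), ncol(idx), byrow = TRUE))
      arr[pos] <- mat[, cols[j]]
    }
    out[[nm]] <- arr
  }
  out
}

n_draws <- function(fit) {
  if (!is.null(fit$S)) fit$S
  else nrow(as.matrix(fit$coda[[1]])) * length(fit$coda)
}

#' Per-draw imputed decrement matrix
#'
#' Fills the missing HRQoL cells of the model's dataset with their posterior
#' draws (observed cells are constant across draws).
#'
#' @param fit a [sample_posterior()] result.
#' @return array `[draws, patients, 6]`.
#' @export
imputed_q <- function(fit) {
  model <- fit$model
  S <- n_draws(fit)
  qarr <- array(rep(t(ifelse(is.na(model$ds$q), 0, model$ds$q)), each = S),
                dim = c(S, model$ds$n, 6L))
  mis <- model$mis_cells
  if (nrow(mis) > 0L) {
    fam <- model$spec$hrqol_family
    for (k in seq_len(nrow(mis))) {
      v <- switch(fam,
        hurdle = (1 - fit$draws$hmis[, k]) * fit$draws$qpos[, k],
        gamma = fit$draws$qe[, mis[k, 1], mis[k, 2]] - EPS_DECREMENT,
        normal = fit$draws$qn[, mis[k, 1], mis[k, 2]])
      qarr[, mis[k, 1], mis[k, 2]] <- v
    }
  }
  qarr
}

#' Per-draw baseline decrements (imputed where missing)
#' @param fit a [sample_posterior()] result.
#' @return matrix `[draws, patients]`.
#' @export
imputed_bq <- function(fit) {
  model <- fit$model
  S <- n_draws(fit)
  out <- matrix(rep(model$ds$patients$bq, each = S), S, model$ds$n)
  if (model$n_missing_bq > 0L) {
    midx <- which(is.na(model$ds$patients$bq))
    out[, midx] <- fit$draws$bqe[, midx, drop = FALSE] - EPS_DECREMENT
  }
  out
}

#' Per-draw total costs (imputed above their lower bounds where missing)
#' @param fit a [sample_posterior()] result.
#' @return matrix `[draws, patients]`.
#' @export
imputed_cost <- function(fit) {
  model <- fit$model
  S <- n_draws(fit)
  out <- matrix(rep(model$ds$total_cost, each = S), S, model$ds$n)
  if (any(is.na(model$ds$total_cost))) {
    midx <- which(is.na(model$ds$total_cost))
    out[, midx] <- fit$draws$cst[, midx, drop = FALSE]
  }
  out
}

#' Convenience wrapper: build and fit one scenario
#'
#' @param ds a [cea_dataset()].
#' @param scenario a scenario name (see [scenario_names()]) or
#'   `scenario_spec`.
#' @param hrqol_family outcome family, see [joint_model_spec()].
#' @param include_missingness_model override; defaults to the scenario flag.
#' @param ... passed to [sample_posterior()] (`chains`, `iter`, `seed`, ...).
#' @return a `cea_fit`.
#' @export
fit_scenario <- function(ds, scenario = "MAR", hrqol_family = "hurdle",
                         include_missingness_model = NULL, ...) {
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  spec <- joint_model_spec(
    hrqol_family = hrqol_family, scenario = scenario,
    include_missingness_model = if (is.null(include_missingness_model))
      scenario$include_missingness_model else include_missingness_model)
  sample_posterior(build_joint_model(ds, spec), ...)
}

split_rhat <- function(x_by_chain) {
  halves <- unlist(lapply(x_by_chain, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L || m < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Split-R-hat and effective sample size for every scalar model parameter
#' (random intercepts and imputed values excluded), plus a flag for
#' parameters with R-hat above the threshold.  With a single chain the
#' split-R-hat uses the two chain halves and a warning is issued.
#'
#' @param fit a `cea_fit`.
#' @param rhat_threshold flagging threshold (default 1.05).
#' @return list of class `convergence_report`: `table` (data.frame with
#'   `parameter`, `rhat`, `ess`, `flagged`), `n_flagged`, `chains`,
#'   `rhat_threshold`.  Serializable with [jsonlite::toJSON()].
#' @export
convergence_report <- function(fit, rhat_threshold = 1.05) {
  skip <- c("theta", "hmis", "qpos", "qe", "qn", "bqe", "cst")
  keep <- !(sub("\\[.*$", "", coda::varnames(fit$coda)) %in% skip)
  vn <- coda::varnames(fit$coda)[keep]
  if (length(fit$coda) < 2L) {
    warning("single chain: split-R-hat computed from chain halves only")
  }
  rhat <- vapply(vn, function(v) {
    split_rhat(lapply(fit$coda, function(ch) as.numeric(ch[, v])))
  }, numeric(1))
  ess <- vapply(vn, function(v) {
    sum(vapply(fit$coda, function(ch) coda::effectiveSize(ch[, v]), numeric(1)))
  }, numeric(1))
  tab <- data.frame(parameter = vn, rhat = unname(rhat), ess = unname(ess),
                    flagged = unname(!is.na(rhat) & rhat > rhat_threshold))
  structure(list(table = tab, n_flagged = sum(tab$flagged),
                 chains = length(fit$coda), rhat_threshold = rhat_threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> ", nrow(x$table), " parameters, ",
      x$n_flagged, " flagged (split-R-hat > ", x$rhat_threshold, ")\n", sep = "")
  if (x$n_flagged > 0L) print(x$table[x$table$flagged, ])
  invisible(x)
}

# same viable-range clamp the sampler applies to predicted decrements
clamp_pred_q <- function(x, fam) {
  if (fam == "normal") pmin(pmax(x, -0.6), 1.6) else pmin(x, 1.6)
}

arm_params_from_draw <- function(draws, s, a, fam) {
  hrqol_params(
    gamma0 = if (fam == "hurdle") draws$gamma0[s, a, ] else rep(0, 6),
    omega = if (fam == "hurdle") draws$omega[s, a, ] else rep(0, 4),
    alpha0 = draws$alpha0[s, a, ], beta = draws$beta[s, a, ],
    shape_q = if (fam != "normal") draws$shape.q[s, a] else 1,
    theta_sd = if (!is.null(draws$sigma.theta)) draws$sigma.theta[s, a] else 1,
    sd_q = if (fam == "normal") draws$sd.q[s, a] else 1)
}

# observed-data log-likelihood components at one draw (or at plug-in values)
component_loglik <- function(model, params_mm, params_ls, cost_mm, cost_ls,
                             shape_bq, rate_bq, theta, q_latent, bq_all,
                             miss_mm = NULL, miss_ls = NULL) {
  ds <- model$ds
  fam <- model$spec$hrqol_family
  arm <- model$arm
  cov <- cbind(model$data$cbmi, model$data$cage, model$data$sex)
  hp <- list(params_mm, params_ls)
  obs <- model$obs_cells
  ll_h <- 0
  for (j in seq_len(nrow(obs))) {
    i <- obs[j, 1]; t <- obs[j, 2]
    q <- ds$q[i, t]
    ll_h <- ll_h + switch(fam,
      hurdle = hrqol_logdensity(hp[[arm[i]]], theta[i], cov[i, ], bq_all[i], t, q),
      gamma = hrqol_logdensity_gamma_variant(hp[[arm[i]]], theta[i], cov[i, ],
                                             bq_all[i], t, q + EPS_DECREMENT),
      normal = hrqol_logdensity_normal_variant(hp[[arm[i]]], theta[i], cov[i, ],
                                               bq_all[i], t, q))
  }
  cp <- list(cost_mm, cost_ls)
  ll_c <- 0
  for (i in which(!is.na(ds$total_cost))) {
    Q_i <- qaly_from_decrements(q_latent[i, ])
    predq <- vapply(1:6, function(t) {
      pr <- predict_hrqol(hp[[arm[i]]], cov[i, ], bq_all[i], t, theta[i])
      switch(fam, hurdle = pr$pred_q, gamma = pr$mu_q - EPS_DECREMENT,
             normal = hp[[arm[i]]]$alpha0[t] + theta[i] +
               sum(hp[[arm[i]]]$beta * c(bq_all[i], cov[i, ])))
    }, numeric(1))
    muQ_i <- qaly_from_decrements(clamp_pred_q(predq, fam))
    ll_c <- ll_c + cost_logdensity(cp[[arm[i]]], cov[i, ], Q_i, muQ_i,
                                   ds$total_cost[i])
  }
  obq <- which(!is.na(ds$patients$bq))
  ub <- 1.2 + EPS_DECREMENT
  bqe <- ds$patients$bq[obq] + EPS_DECREMENT
  ll_b <- sum(stats::dgamma(bqe, shape_bq, rate_bq, log = TRUE) -
                stats::pgamma(ub, shape_bq, rate_bq, log.p = TRUE))
  out <- c(hrqol = ll_h, cost = ll_c, baseline = ll_b)
  if (!is.null(miss_mm)) {
    ds_f <- ds
    ds_f$patients$bq <- bq_all
    out["missingness"] <- missingness_loglik(list(MM = miss_mm, LS = miss_ls),
                                             ds_f, model$indicators, q_latent)
  }
  out
}

draw_loglik_components <- function(fit, s) {
  model <- fit$model
  d <- fit$draws
  fam <- model$spec$hrqol_family
  theta <- if (!is.null(d$theta)) d$theta[s, ] else rep(0, model$ds$n)
  q_lat <- imputed_q_row(fit, s)
  bq_all <- imputed_bq_row(fit, s)
  mk <- function(a) if (model$spec$include_missingness_model) {
    missingness_params(kappa0 = d$kappa0[s, a, , ], kappa = d$kappa[s, a, , ],
                       lambda = matrix(model$spec$scenario$lambda, 2, 2,
                                       byrow = TRUE)[a, ])
  } else NULL
  component_loglik(
    model,
    arm_params_from_draw(d, s, 1L, fam), arm_params_from_draw(d, s, 2L, fam),
    cost_params(zeta = d$zeta[s, 1, ], xi = d$xi[s, 1], shape_c = d$shape.c[s, 1]),
    cost_params(zeta = d$zeta[s, 2, ], xi = d$xi[s, 2], shape_c = d$shape.c[s, 2]),
    d$shape.bq[s], d$rate.bq[s], theta, q_lat, bq_all,
    miss_mm = mk(1L), miss_ls = mk(2L))
}

imputed_q_row <- function(fit, s) {
  model <- fit$model
  q <- ifelse(is.na(model$ds$q), 0, model$ds$q)
  mis <- model$mis_cells
  if (nrow(mis) > 0L) {
    fam <- model$spec$hrqol_family
    for (k in seq_len(nrow(mis))) {
      q[mis[k, 1], mis[k, 2]] <- switch(fam,
        hurdle = (1 - fit$draws$hmis[s, k]) * fit$draws$qpos[s, k],
        gamma = fit$draws$qe[s, mis[k, 1], mis[k, 2]] - EPS_DECREMENT,
        normal = fit$draws$qn[s, mis[k, 1], mis[k, 2]])
    }
  }
  q
}

imputed_bq_row <- function(fit, s) {
  bq <- fit$model$ds$patients$bq
  if (fit$model$n_missing_bq > 0L) {
    midx <- which(is.na(bq))
    bq[midx] <- fit$draws$bqe[s, midx] - EPS_DECREMENT
  }
  bq
}

#' Deviance information criterion per likelihood component
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior means)`, computed on the
#' observed-data likelihood of each component (HRQoL, cost, baseline, and --
#' when included -- missingness), with latent imputations and random
#' intercepts plugged in at their draws (posterior means for the plug-in
#' deviance).  Hurdle-family HRQoL DICs include the hurdle part and are not
#' comparable with gamma/normal-family DICs; the output flags this.
#'
#' @param fit a `cea_fit`.
#' @param max_draws cap on the number of posterior draws used.
#' @return data.frame with one row per component plus a total row: columns
#'   `component`, `Dbar`, `Dhat`, `pD`, `DIC`, `comparable_across_families`.
#' @export
compute_dic <- function(fit, max_draws = 400L) {
  S <- n_draws(fit)
  use <- if (S > max_draws) round(seq(1L, S, length.out = max_draws)) else seq_len(S)
  ll <- t(vapply(use, function(s) draw_loglik_components(fit, s),
                 draw_loglik_components(fit, use[1])))
  if (any(!is.finite(ll))) {
    stop("non-finite deviance at draw(s): ",
         paste(utils::head(use[rowSums(!is.finite(ll)) > 0L], 5L), collapse = ", "))
  }
  dbar <- -2 * colMeans(ll)

  # plug-in deviance at posterior means (parameters, intercepts, imputations)
  mean_fit <- fit
  for (nm in names(fit$draws)) {
    d <- fit$draws[[nm]]
    m <- if (is.matrix(d) || is.array(d)) {
      apply(d, seq_along(dim(d))[-1], mean)
    } else mean(d)
    dm <- if (is.null(dim(m))) c(1L, length(m)) else c(1L, dim(m))
    mean_fit$draws[[nm]] <- array(m, dim = dm)
  }
  if (!is.null(mean_fit$draws$hmis)) {
    # hurdle status is binary: plug in the modal status
    mean_fit$draws$hmis[] <- round(mean_fit$draws$hmis)
  }
  dhat <- -2 * draw_loglik_components(mean_fit, 1L)
  pd <- dbar - dhat
  fam <- fit$model$spec$hrqol_family
  out <- data.frame(component = names(dbar), Dbar = unname(dbar),
                    Dhat = unname(dhat), pD = unname(pd),
                    DIC = unname(dbar + pd))
  out <- rbind(out, data.frame(component = "total", Dbar = sum(out$Dbar),
                               Dhat = sum(out$Dhat), pD = sum(out$pD),
                               DIC = sum(out$DIC)))
  out$comparable_across_families <-
    ifelse(out$component %in% c("hrqol", "total"), fam != "hurdle", TRUE)
  out
}

#' Compare HRQoL outcome families by DIC
#'
#' Fits the joint model under the normal, gamma, and hurdle families on the
#' complete cases (the model-selection step run before any missingness
#' modelling) and tabulates the per-component DICs.  The hurdle row's HRQoL
#' DIC also models the point mass at full health, so it is flagged as not
#' directly comparable with the other two.
#'
#' @param ds a [cea_dataset()].
#' @param families character subset of `c("normal", "gamma", "hurdle")`.
#' @param include_random_intercepts logical.
#' @param ... passed to [sample_posterior()].
#' @return data.frame with `family`, `DIC_hrqol`, `DIC_cost`, `DIC_total`,
#'   `comparable`.
#' @export
compare_families <- function(ds, families = c("normal", "gamma", "hurdle"),
                             include_random_intercepts = TRUE, ...) {
  rows <- lapply(families, function(f) {
    spec <- joint_model_spec(hrqol_family = f, scenario = build_scenario("CCA"),
                             include_random_intercepts = include_random_intercepts)
    fit <- sample_posterior(build_joint_model(ds, spec), ...)
    dic <- compute_dic(fit)
    data.frame(family = f,
               DIC_hrqol = dic$DIC[dic$component == "hrqol"],
               DIC_cost = dic$DIC[dic$component == "cost"],
               DIC_total = dic$DIC[dic$component == "total"],
               comparable = f != "hurdle")
  })
  do.call(rbind, rows)
}

#' Normalized posterior on a grid by direct summation (test oracle)
#'
#' Evaluates an arbitrary log-posterior over a 1- or 2-dimensional grid and
#' normalizes by summation, for cross-checking MCMC on tiny models.  Refuses
#' more than two dimensions.
#'
#' @param log_post function taking a numeric vector (one value per grid
#'   dimension) and returning the unnormalized log-posterior.
#' @param grid named list of 1 or 2 numeric vectors (regularly spaced).
#' @return list with `grid`, `density` (array over the grid integrating to 1),
#'   `mean` (posterior mean per dimension), `Z_log` (log normalizing sum).
#' @export
brute_force_posterior <- function(log_post, grid) {
  if (length(grid) > 2L) stop("grid posterior limited to <= 2 dimensions")
  steps <- vapply(grid, function(g) {
    if (length(g) < 2L) return(1)
    d <- diff(g)
    if (max(abs(d - d[1])) > 1e-8 * abs(d[1])) stop("grid must be regularly spaced")
    d[1]
  }, numeric(1))
  pts <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  lp <- apply(pts, 1L, function(x) log_post(as.numeric(x)))
  mx <- max(lp)
  w <- exp(lp - mx)
  Z <- sum(w) * prod(steps)
  dens <- array(w / Z, dim = vapply(grid, length, integer(1)))
  post_mean <- vapply(seq_along(grid), function(k) {
    sum(pts[, k] * w) / sum(w)
  }, numeric(1))
  names(post_mean) <- names(grid)
  list(grid = grid, density = dens, mean = post_mean, Z_log = log(Z) + mx)
}

#' Tiny hurdle model fitted by MCMC (test oracle counterpart)
#'
#' A single-arm, single-timepoint hurdle-gamma model with fixed hurdle
#' probability and free `(alpha, shape)`: `q_j = 0` w.p. `p_fix`, else
#' `Gamma(shape, shape/exp(alpha))`.  Shares the zeros-trick likelihood
#' construction used by the joint model so the MCMC path can be checked
#' against [brute_force_posterior()].
#'
#' @param q decrement observations (a few values).
#' @param p_fix fixed hurdle probability.
#' @param prior_mean,prior_sd normal prior on `alpha`.
#' @param shape_prior_sd half-normal prior scale on `shape`.
#' @param iter,burnin,adapt,seed MCMC settings (single chain).
#' @return list with `alpha` and `shape` draw vectors.
#' @export
fit_hurdle_toy <- function(q, p_fix = 0.3, prior_mean = 0, prior_sd = 2,
                           shape_prior_sd = 5, iter = 4000L, burnin = 500L,
                           adapt = 500L, seed = 1L) {
  stopifnot(all(q >= 0), length(q) <= 12L)
  ms <- paste(c(
    "model {",
    sprintf("  alpha ~ dnorm(%g, %g)", prior_mean, 1 / prior_sd^2),
    sprintf("  shape ~ dnorm(0, %g) T(0.001,)", 1 / shape_prior_sd^2),
    "  log(mu) <- alpha",
    "  for (j in 1:J) {",
    "    ll[j] <- z[j]*log(p) + (1-z[j])*(log(1-p) + shape*log(shape/mu)",
    "             + (shape-1)*log(qs[j]) - (shape/mu)*qs[j] - loggam(shape))",
    paste0("    zeros[j] ~ dpois(", ZEROS_C, " - ll[j])"),
    "  }",
    "}"), collapse = "\n")
  dat <- list(J = length(q), z = as.integer(q == 0), qs = pmax(q, 1e-12),
              p = p_fix, zeros = rep(0, length(q)))
  jm <- rjags::jags.model(textConnection(ms), data = dat,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = as.integer(seed),
                                       alpha = 0, shape = 1),
                          n.chains = 1L, n.adapt = adapt, quiet = TRUE)
  stats::update(jm, burnin, progress.bar = "none")
  co <- rjags::coda.samples(jm, c("alpha", "shape"), iter, progress.bar = "none")
  m <- as.matrix(co)
  list(alpha = m[, "alpha"], shape = m[, "shape"])
}

#' Posterior predictive checks on the fitted joint model
#'
#' For each retained draw, replicate data are simulated at the observed
#' cells and summary statistics are compared with their observed values;
#' the tail probability `P(T_rep >= T_obs)` is reported with ties split.
#' Available statistics: `zero_prop` (share of decrements at 0, the spike at
#' full health), `mean_decrement_t1` ... `mean_decrement_t6`, `cost_mean`,
#' and `cost_skewness` (moment skewness of observed totals).
#'
#' @param fit a `cea_fit`.
#' @param statistics character vector of statistic names; empty gives an
#'   empty table.
#' @param max_draws cap on the number of draws used.
#' @param seed RNG seed for the replicate draws.
#' @return data.frame with `statistic`, `observed`, `p_value`.
#' @export
posterior_predictive_check <- function(fit,
                                       statistics = c("zero_prop",
                                                      paste0("mean_decrement_t", 1:6),
                                                      "cost_mean", "cost_skewness"),
                                       max_draws = 200L, seed = 1L) {
  if (length(statistics) == 0L) {
    return(data.frame(statistic = character(0), observed = numeric(0),
                      p_value = numeric(0)))
  }
  model <- fit$model
  fam <- model$spec$hrqol_family
  ds <- model$ds
  set.seed(seed)
  S <- n_draws(fit)
  use <- if (S > max_draws) round(seq(1L, S, length.out = max_draws)) else seq_len(S)
  obs <- model$obs_cells
  cov <- cbind(model$data$cbmi, model$data$cage, model$data$sex)
  arm <- model$arm
  skew <- function(x) {
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) return(0)
    mean((x - m)^3) / s^3
  }
  obs_cost_idx <- which(!is.na(ds$total_cost))
  stat_fun <- function(qcells, costs) {
    out <- c(zero_prop = mean(qcells == 0))
    for (t in 1:6) {
      out[paste0("mean_decrement_t", t)] <- mean(qcells[obs[, 2] == t])
    }
    out["cost_mean"] <- if (length(costs)) mean(costs) else NA_real_
    out["cost_skewness"] <- if (length(costs) > 2L) skew(costs) else NA_real_
    out
  }
  t_obs <- stat_fun(ds$q[obs], ds$total_cost[obs_cost_idx])
  ge <- numeric(length(t_obs))
  eq <- numeric(length(t_obs))
  names(ge) <- names(eq) <- names(t_obs)
  d <- fit$draws
  for (s in use) {
    theta <- if (!is.null(d$theta)) d$theta[s, ] else rep(0, ds$n)
    bq_all <- imputed_bq_row(fit, s)
    qrep <- numeric(nrow(obs))
    for (j in seq_len(nrow(obs))) {
      i <- obs[j, 1]; t <- obs[j, 2]
      par <- arm_params_from_draw(d, s, arm[i], fam)
      lp <- hrqol_linpreds(par, theta[i], cov[i, ], bq_all[i], t)
      qrep[j] <- switch(fam,
        hurdle = if (stats::runif(1) < lp$p) 0 else
          stats::rgamma(1L, par$shape_q, par$shape_q / lp$mu),
        gamma = stats::rgamma(1L, par$shape_q, par$shape_q / lp$mu) - EPS_DECREMENT,
        normal = stats::rnorm(1L, par$alpha0[t] + theta[i] +
                                sum(par$beta * c(bq_all[i], cov[i, ])), par$sd_q))
    }
    q_lat <- imputed_q_row(fit, s)
    crep <- vapply(obs_cost_idx, function(i) {
      a <- arm[i]
      cp <- cost_params(zeta = d$zeta[s, a, ], xi = d$xi[s, a],
                        shape_c = d$shape.c[s, a])
      hpar <- arm_params_from_draw(d, s, a, fam)
      predq <- vapply(1:6, function(t) {
        lp <- hrqol_linpreds(hpar, theta[i], cov[i, ], bq_all[i], t)
        switch(fam, hurdle = (1 - lp$p) * lp$mu, gamma = lp$mu - EPS_DECREMENT,
               normal = hpar$alpha0[t] + theta[i] +
                 sum(hpar$beta * c(bq_all[i], cov[i, ])))
      }, numeric(1))
      v <- cost_mean_conditional(cp, cov[i, ], qaly_from_decrements(q_lat[i, ]),
                                 qaly_from_decrements(clamp_pred_q(predq, fam)))
      stats::rgamma(1L, cp$shape_c, cp$shape_c / v)
    }, numeric(1))
    t_rep <- stat_fun(qrep, crep)
    ge <- ge + as.numeric(t_rep > t_obs)
    eq <- eq + as.numeric(t_rep == t_obs)
  }
  p <- (ge + 0.5 * eq) / length(use)
  keep <- intersect(statistics, names(t_obs))
  bad <- setdiff(statistics, names(t_obs))
  if (length(bad) > 0L) stop("unknown statistic(s): ", paste(bad, collapse = ", "))
  data.frame(statistic = keep, observed = unname(t_obs[keep]),
             p_value = unname(p[keep]))
}
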