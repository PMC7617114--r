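YEAR_LABELS <- c(paste("Year", 1:5), "5 year total")

# year-level decomposition of the QALY trapezoid: rows sum to the 5-year
# total.  Year 1 takes the 3-month and year-1 terms; years 2-4 the unit
# weights; year 5 the closing half weight.
year_values <- function(qmat) {
  cbind(0.5 * (1 - qmat[, 1]) + 0.875 * (1 - qmat[, 2]),
        1 - qmat[, 3], 1 - qmat[, 4], 1 - qmat[, 5],
        0.5 * (1 - qmat[, 6]))
}

#' Recycled predictions of incremental QALYs and costs under ITT
#'
#' For every posterior draw, outcomes are predicted for all patients from
#' their baseline covariates under assignment to MM and then to LS; patients
#' who crossed over are predicted with the parameters of the arm they
#' actually received under both assignments, so randomization only tells us
#' how to average.  Incremental QALYs and costs are the means of the
#' per-patient differences; per-year arm means average the assignment-
#' specific predictions over all patients.  Costs use the marginal
#' (covariate-only) cost mean; QALY predictions integrate the patient random
#' intercept out analytically (`theta_mode = "integrate"`, the lognormal
#' mean factor `exp(sigma_theta^2/2)` on the gamma part) or by drawing one
#' intercept per patient and draw (`"draw"`).
#'
#' @param fit a `cea_fit`.
#' @param theta_mode `"integrate"` or `"draw"`.
#' @param seed RNG seed, used only in `"draw"` mode.
#' @return list of class `cea_pred`: `delta_q`, `delta_c` (draw vectors,
#'   LS minus MM), `year_arm` (`[draws, arm, year]`, arm 1 = MM, 2 = LS),
#'   `total_arm` (`[draws, arm]` 5-year QALYs), `cost_arm` (`[draws, arm]`),
#'   `scenario`.
#' @export
recycled_predictions <- function(fit, theta_mode = c("integrate", "draw"),
                                 seed = 1L) {
  theta_mode <- match.arg(theta_mode)
  model <- fit$model
  ds <- model$ds
  d <- fit$draws
  fam <- model$spec$hrqol_family
  S <- n_draws(fit)
  n <- ds$n
  cross <- ds$patients$arm_randomized != ds$patients$arm_received
  recv <- model$arm
  cbmi <- model$data$cbmi
  cage <- model$data$cage
  sex <- model$data$sex
  bq_draws <- imputed_bq(fit)
  if (theta_mode == "draw") set.seed(seed)

  delta_q <- numeric(S)
  delta_c <- numeric(S)
  year_arm <- array(NA_real_, c(S, 2L, 5L))
  total_arm <- matrix(NA_real_, S, 2L)
  cost_arm <- matrix(NA_real_, S, 2L)
  for (s in seq_len(S)) {
    bq <- bq_draws[s, ]
    Qa <- matrix(NA_real_, n, 2L)
    Ca <- matrix(NA_real_, n, 2L)
    Ya <- array(NA_real_, c(n, 2L, 5L))
    for (a in 1:2) {
      eff <- ifelse(cross, recv, a)
      sig <- if (!is.null(d$sigma.theta)) d$sigma.theta[s, ][eff] else rep(0, n)
      thadd <- switch(theta_mode,
                      integrate = if (fam == "normal") rep(0, n) else sig^2 / 2,
                      draw = stats::rnorm(n, 0, sig))
      qmat <- matrix(NA_real_, n, 6L)
      for (t in 1:6) {
        eta_mu <- d$alpha0[s, , t][eff] + thadd +
          d$beta[s, , 1][eff] * bq + d$beta[s, , 2][eff] * cbmi +
          d$beta[s, , 3][eff] * cage + d$beta[s, , 4][eff] * sex
        qmat[, t] <- clamp_pred_q(switch(fam,
          hurdle = {
            p <- stats::plogis(d$gamma0[s, , t][eff] +
                                 d$omega[s, , 1][eff] * bq +
                                 d$omega[s, , 2][eff] * cbmi +
                                 d$omega[s, , 3][eff] * cage +
                                 d$omega[s, , 4][eff] * sex)
            (1 - p) * exp(eta_mu)
          },
          gamma = exp(eta_mu) - EPS_DECREMENT,
          normal = eta_mu), fam)
      }
      yv <- year_values(qmat)
      Ya[, a, ] <- yv
      Qa[, a] <- rowSums(yv)
      Ca[, a] <- exp(d$zeta[s, , 1][eff] + d$zeta[s, , 2][eff] * cbmi +
                       d$zeta[s, , 3][eff] * cage + d$zeta[s, , 4][eff] * sex)
    }
    delta_q[s] <- mean(Qa[, 2] - Qa[, 1])
    delta_c[s] <- mean(Ca[, 2] - Ca[, 1])
    total_arm[s, ] <- colMeans(Qa)
    cost_arm[s, ] <- colMeans(Ca)
    year_arm[s, , ] <- apply(Ya, c(2L, 3L), mean)
  }
  structure(list(delta_q = delta_q, delta_c = delta_c, year_arm = year_arm,
                 total_arm = total_arm, cost_arm = cost_arm,
                 scenario = model$spec$scenario$name),
            class = "cea_pred")
}

tie_split_prob <- function(x) mean(x > 0) + 0.5 * mean(x == 0)

#' Incremental net monetary benefit from posterior draws
#'
#' `INB_s = wtp * dQ_s - dC_s`, draw-wise exactly; summarized by the
#' posterior mean, the central 95% credible interval, and `P(INB > 0)` with
#' ties split.
#'
#' @param delta_q,delta_c equal-length draw vectors (or pass a `cea_pred` as
#'   `delta_q` to take both from it).
#' @param wtp willingness to pay per QALY in GBP (default 20000).
#' @return list of class `cea_inb`: `draws`, `wtp`, `mean`, `cri`
#'   (length 2), `p_positive`.
#' @export
incremental_net_benefit <- function(delta_q, delta_c = NULL, wtp = 20000) {
  if (inherits(delta_q, "cea_pred")) {
    delta_c <- delta_q$delta_c
    delta_q <- delta_q$delta_q
  }
  if (length(delta_q) != length(delta_c)) {
    stop("delta_q and delta_c draw vectors must have equal length")
  }
  inb <- wtp * delta_q - delta_c
  structure(list(draws = inb, wtp = wtp, mean = mean(inb),
                 cri = unname(stats::quantile(inb, c(0.025, 0.975))),
                 p_positive = tie_split_prob(inb)),
            class = "cea_inb")
}

#' Cost-effectiveness acceptability curve
#'
#' `P(INB > 0)` (ties split) evaluated over a willingness-to-pay grid.
#'
#' @inheritParams incremental_net_benefit
#' @param wtp_grid non-negative grid of willingness-to-pay values.
#' @return data.frame with `wtp` and `probability`.
#' @export
ceac <- function(delta_q, delta_c = NULL, wtp_grid = seq(0, 50000, by = 1000)) {
  if (inherits(delta_q, "cea_pred")) {
    delta_c <- delta_q$delta_c
    delta_q <- delta_q$delta_q
  }
  if (length(wtp_grid) == 0L) stop("wtp_grid must be non-empty")
  if (any(wtp_grid < 0)) stop("willingness-to-pay values must be >= 0")
  prob <- vapply(wtp_grid, function(w) tie_split_prob(w * delta_q - delta_c),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

summ3 <- function(x) {
  c(mean = mean(x), lo = unname(stats::quantile(x, 0.025)),
    hi = unname(stats::quantile(x, 0.975)))
}

#' Per-year QALY summary table (disaggregated results)
#'
#' One row per follow-up year plus the 5-year total: posterior mean and 95%
#' credible interval of the mean QALYs per arm, their difference (LS minus
#' MM) and the probability the difference favors LS (ties split).  The
#' year-level values use the trapezoid decomposition whose rows sum to the
#' 5-year total.
#'
#' @param pred a `cea_pred` from [recycled_predictions()].
#' @return data.frame with one row per year and the total.
#' @export
annual_qaly_table <- function(pred) {
  stopifnot(inherits(pred, "cea_pred"))
  rows <- lapply(1:6, function(r) {
    if (r <= 5L) {
      ls <- pred$year_arm[, 2L, r]
      mm <- pred$year_arm[, 1L, r]
    } else {
      ls <- pred$total_arm[, 2L]
      mm <- pred$total_arm[, 1L]
    }
    di <- ls - mm
    s_ls <- summ3(ls); s_mm <- summ3(mm); s_d <- summ3(di)
    data.frame(period = YEAR_LABELS[r],
               mean_LS = s_ls["mean"], lo_LS = s_ls["lo"], hi_LS = s_ls["hi"],
               mean_MM = s_mm["mean"], lo_MM = s_mm["lo"], hi_MM = s_mm["hi"],
               difference = s_d["mean"], lo_diff = s_d["lo"], hi_diff = s_d["hi"],
               prob_favors_LS = tie_split_prob(di), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Bundle one scenario's CEA outputs
#'
#' @param pred a `cea_pred`.
#' @param wtp willingness to pay per QALY (GBP).
#' @param scenario optional scenario label override.
#' @return list of class `cea_result` with the draw vectors, the INB
#'   summary, and per-arm QALY/cost summaries.
#' @export
cea_result <- function(pred, wtp = 20000, scenario = pred$scenario) {
  stopifnot(inherits(pred, "cea_pred"))
  inb <- incremental_net_benefit(pred, wtp = wtp)
  structure(list(scenario = scenario, pred = pred, wtp = wtp, inb = inb,
                 delta_q = pred$delta_q, delta_c = pred$delta_c),
            class = "cea_result")
}

#' Five-year scenario comparison table
#'
#' One row per scenario: posterior mean (95% CrI) of mean QALYs and costs
#' per arm and their differences, and the INB summary at the stated
#' willingness to pay.  Costs are reported in GBP.
#'
#' @param results list of `cea_result` objects with distinct scenario names.
#' @return data.frame, one row per scenario.
#' @export
scenario_compare <- function(results) {
  stopifnot(length(results) >= 1L)
  nm <- vapply(results, function(r) r$scenario, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicated scenario name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  rows <- lapply(results, function(r) {
    p <- r$pred
    qls <- summ3(p$total_arm[, 2L]); qmm <- summ3(p$total_arm[, 1L])
    qd <- summ3(p$delta_q)
    cls <- summ3(p$cost_arm[, 2L]); cmm <- summ3(p$cost_arm[, 1L])
    cd <- summ3(p$delta_c)
    data.frame(scenario = r$scenario,
               qaly_LS = qls["mean"], qaly_LS_lo = qls["lo"], qaly_LS_hi = qls["hi"],
               qaly_MM = qmm["mean"], qaly_MM_lo = qmm["lo"], qaly_MM_hi = qmm["hi"],
               qaly_diff = qd["mean"], qaly_diff_lo = qd["lo"], qaly_diff_hi = qd["hi"],
               cost_LS = cls["mean"], cost_LS_lo = cls["lo"], cost_LS_hi = cls["hi"],
               cost_MM = cmm["mean"], cost_MM_lo = cmm["lo"], cost_MM_hi = cmm["hi"],
               cost_diff = cd["mean"], cost_diff_lo = cd["lo"], cost_diff_hi = cd["hi"],
               inb = r$inb$mean, inb_lo = r$inb$cri[1], inb_hi = r$inb$cri[2],
               p_inb_positive = r$inb$p_positive, wtp = r$wtp, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Posterior summaries of imputed HRQoL values
#'
#' For requested missing cells: the posterior mean, quantiles and the
#' zero-mass probability (share of draws at the full-health hurdle) of the
#' imputed decrement.  Requesting an observed cell is an error.
#'
#' @param fit a `cea_fit`.
#' @param patient_ids,timepoints equal-length vectors identifying the cells.
#' @return data.frame with `patient_id`, `timepoint`, `scenario`,
#'   `zero_mass_prob`, `mean`, `q2.5`, `median`, `q97.5`.
#' @export
imputation_density_summary <- function(fit, patient_ids, timepoints) {
  stopifnot(length(patient_ids) == length(timepoints))
  model <- fit$model
  rows <- match(as.character(patient_ids), model$ds$patients$patient_id)
  if (any(is.na(rows))) {
    stop("unknown patient id(s): ",
         paste(patient_ids[is.na(rows)], collapse = ", "))
  }
  mis <- model$mis_cells
  out <- lapply(seq_along(rows), function(j) {
    i <- rows[j]; t <- as.integer(timepoints[j])
    k <- which(mis[, 1] == i & mis[, 2] == t)
    if (length(k) == 0L) {
      stop("cell (", patient_ids[j], ", t=", t,
           ") is observed; imputation summaries exist only for missing cells")
    }
    v <- switch(model$spec$hrqol_family,
      hurdle = (1 - fit$draws$hmis[, k]) * fit$draws$qpos[, k],
      gamma = fit$draws$qe[, i, t] - EPS_DECREMENT,
      normal = fit$draws$qn[, i, t])
    zm <- if (model$spec$hrqol_family == "hurdle") mean(fit$draws$hmis[, k]) else mean(v == 0)
    qs <- stats::quantile(v, c(0.025, 0.5, 0.975))
    data.frame(patient_id = patient_ids[j], timepoint = t,
               scenario = model$spec$scenario$name, zero_mass_prob = zm,
               mean = mean(v), q2.5 = unname(qs[1]), median = unname(qs[2]),
               q97.5 = unname(qs[3]))
  })
  do.call(rbind, out)
}
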