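#' Response-missingness model parameters (one block per treatment arm)
#'
#' Three-category multinomial-logistic model for the missing-value indicator
#' (1 = observed, 2 = interim missing, 3 = loss to follow-up).  Category 1 is
#' the reference; for r in {2, 3},
#' `log(phi_r) = kappa0[t, r-1] + kappa[r-1, ] %*% (bmi, age, sex, previous.q)
#'  + lambda[r-1] * change.q`.
#' The selection coefficients `lambda` are fixed constants (point priors),
#' never sampled; they index the MNAR sensitivity scenarios.
#'
#' @param kappa0 6 x 2 matrix of time intercepts (columns: interim, LTFU).
#' @param kappa 2 x 4 matrix of coefficients on (bmi, age, sex, previous.q).
#' @param lambda length-2 selection coefficients on change.q (interim, LTFU).
#' @return list of class `missingness_params`.
#' @export
missingness_params <- function(kappa0 = matrix(0, 6, 2),
                               kappa = matrix(0, 2, 4),
                               lambda = c(0, 0)) {
  kappa0 <- as.matrix(kappa0)
  kappa <- as.matrix(kappa)
  stopifnot(all(dim(kappa0) == c(6L, 2L)), all(dim(kappa) == c(2L, 4L)),
            length(lambda) == 2L)
  if (any(!is.finite(c(kappa0, kappa, lambda)))) {
    stop("missingness parameters must be finite")
  }
  structure(list(kappa0 = kappa0, kappa = kappa, lambda = lambda),
            class = "missingness_params")
}

#' Change in HRQoL between consecutive timepoints, on the utility scale
#'
#' Defined as `previous_decrement - current_decrement`, i.e. the change in
#' HRQoL utility, so a positive value means health improved.  At the first
#' timepoint the previous decrement is the baseline decrement.  The
#' `previous.q` covariate itself stays on the decrement scale.  With this
#' convention a selection coefficient `lambda = log(2)` encodes a twofold
#' increase in the missingness odds-ratio scale per unit HRQoL improvement,
#' so positive selection pushes imputed utilities above their MAR values.
#'
#' @param previous_decrement,current_decrement finite decrements (the current
#'   one may be a latent imputed value).
#' @return change in utility (scalar).
#' @export
compute_change_q <- function(previous_decrement, current_decrement) {
  previous_decrement - current_decrement
}

#' Multinomial missingness-category probabilities
#'
#' Softmax over (observed, interim, LTFU) with category 1 as reference;
#' guarded against overflow by max subtraction.
#'
#' @param params a [missingness_params()] block.
#' @param covariates numeric length-3 `(bmi, age, sex)`.
#' @param t timepoint 1..6.
#' @param previous_q previous decrement (baseline decrement at t = 1).
#' @param change_q utility-scale change, see [compute_change_q()].
#' @return probability 3-vector summing to 1.
#' @export
missingness_probs <- function(params, covariates, t, previous_q, change_q) {
  stopifnot(length(covariates) == 3L)
  eta <- c(0, vapply(1:2, function(r) {
    params$kappa0[t, r] + sum(params$kappa[r, ] * c(covariates, previous_q)) +
      params$lambda[r] * change_q
  }, numeric(1)))
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Multinomial missingness log-likelihood
#'
#' Sums `log s[m_it]` over patients and timepoints `t = 1 ..
#' min(6, first LTFU timepoint)`: dropout is absorbing, so timepoints after
#' the first category-3 event contribute nothing.  `q_latent` supplies
#' decrements for missing cells so that the possibly unobserved `previous.q`
#' and `change.q` are available.
#'
#' @param params_by_arm list with elements `MM` and `LS`, each a
#'   [missingness_params()] block (indexed by arm received).
#' @param ds a [cea_dataset()]; its `bq` must be complete (supply imputed
#'   values if needed).
#' @param indicators output of [classify_missingness()] on `ds`.
#' @param q_latent n x 6 matrix of decrements with missing cells filled in
#'   (observed cells must match `ds$q`).
#' @return total log-likelihood (scalar).
#' @export
missingness_loglik <- function(params_by_arm, ds, indicators, q_latent) {
  q_latent <- as.matrix(q_latent)
  if (!all(dim(q_latent) == dim(ds$q))) stop("q_latent must match ds$q in shape")
  ok <- is.na(ds$q) | (abs(q_latent - ds$q) < 1e-12)
  if (!all(ok, na.rm = TRUE) || any(!is.finite(q_latent))) {
    stop("q_latent must equal ds$q on observed cells and be finite everywhere")
  }
  m <- indicators$m
  if (!all(dim(m) == dim(ds$q))) stop("indicators inconsistent with dataset")
  if (any((m == 1L) != !is.na(ds$q))) {
    stop("indicators disagree with observed cells of the dataset")
  }
  ll <- 0
  for (i in seq_len(ds$n)) {
    arm <- ds$patients$arm_received[i]
    par <- params_by_arm[[arm]]
    cov <- c(ds$patients$bmi[i], ds$patients$age[i], ds$patients$sex[i])
    bq <- ds$patients$bq[i]
    if (is.na(bq)) stop("missingness_loglik requires bq (supply an imputed value) for patient ", i)
    first3 <- which(m[i, ] == 3L)[1]
    tmax <- if (is.na(first3)) 6L else first3
    for (t in seq_len(tmax)) {
      prev <- if (t == 1L) bq else q_latent[i, t - 1L]
      ch <- compute_change_q(prev, q_latent[i, t])
      s <- missingness_probs(par, cov, t, prev, ch)
      ll <- ll + log(s[m[i, t]])
    }
  }
  ll
}

scenario_table <- function() {
  # lambda quadruple order: (MM interim, MM LTFU, LS interim, LS LTFU)
  up <- 0.69
  list(
    CCA   = c(0, 0, 0, 0),
    MAR   = c(0, 0, 0, 0),
    MNAR1 = c(-up, -up,  up,  up),
    MNAR2 = c( up,  up, -up, -up),
    MNAR3 = c(  0, -up,   0,  up),
    MNAR4 = c(  0,  up,   0, -up),
    MNAR5 = c(-up,   0,  up,   0),
    MNAR6 = c( up,   0, -up,   0),
    MNAR7 = c(-up, -up, -up, -up),
    MNAR8 = c( up,  up,  up,  up)
  )
}

#' Names of the built-in missing-data scenarios
#' @return character vector: CCA, MAR, MNAR1..MNAR8.
#' @export
scenario_names <- function() names(scenario_table())

#' Build a missing-data sensitivity scenario
#'
#' Maps a scenario name to the four fixed selection coefficients
#' (MM interim, MM LTFU, LS interim, LS LTFU).  Positive MNAR selection
#' (`+0.69 = log 2`) makes missingness twice as likely per unit HRQoL
#' improvement, pulling imputations above MAR; negative selection
#' (`-0.69`) pulls them below.  MNAR1 assumes negative selection in MM and
#' positive in LS for both missingness types; MNAR2 is its mirror; MNAR3/4
#' restrict selection to loss to follow-up, MNAR5/6 to interim missingness;
#' MNAR7/8 apply the same direction to both arms.  MAR sets every coefficient
#' to zero; CCA analyses complete cases only and omits the missingness model.
#'
#' @param name scenario name, one of [scenario_names()].
#' @return list of class `scenario_spec` with `name`, `lambda` (named
#'   quadruple), `complete_cases` flag, and `include_missingness_model` flag.
#' @export
build_scenario <- function(name) {
  tab <- scenario_table()
  if (!is.character(name) || length(name) != 1L || !(name %in% names(tab))) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(tab), collapse = ", "))
  }
  lam <- tab[[name]]
  names(lam) <- c("MM_interim", "MM_ltfu", "LS_interim", "LS_ltfu")
  structure(list(name = name, lambda = lam,
                 complete_cases = identical(name, "CCA"),
                 include_missingness_model = !identical(name, "CCA")),
            class = "scenario_spec")
}

#' Custom scenario from an explicit lambda quadruple
#'
#' @param lambda numeric length-4 `(MM interim, MM LTFU, LS interim, LS
#'   LTFU)` selection coefficients.
#' @param name label for reporting.
#' @return a `scenario_spec`, as from [build_scenario()].
#' @export
custom_scenario <- function(lambda, name = "custom") {
  stopifnot(length(lambda) == 4L, all(is.finite(lambda)))
  lam <- as.numeric(lambda)
  names(lam) <- c("MM_interim", "MM_ltfu", "LS_interim", "LS_ltfu")
  structure(list(name = name, lambda = lam, complete_cases = FALSE,
                 include_missingness_model = TRUE), class = "scenario_spec")
}
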