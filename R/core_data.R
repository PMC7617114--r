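#' Longitudinal cost-effectiveness dataset
#'
#' Container for patient-level trial data on the decrement scale: one record
#' per patient holding randomized and received arm, baseline covariates,
#' HRQoL decrements at the six post-baseline timepoints (3 months and years
#' 1--5), and per-year costs for years 1--5.  Health utilities are stored as
#' decrements (`1 - utility`), so 0 means full health.  The 5-year total cost
#' is derived deterministically from the annual costs: fully observed annual
#' costs give an observed total; a partially observed year pattern gives a
#' `"partial"` total whose lower bound is the sum of the observed annual
#' costs; no observed annual costs give a `"missing"` total.
#'
#' @param patients data.frame with columns `patient_id`, `arm_randomized`,
#'   `arm_received` (each `"MM"` or `"LS"`), `age`, `bmi`, `sex` (0/1), and
#'   `bq` (baseline HRQoL decrement, possibly `NA`).
#' @param q numeric matrix, one row per patient and 6 columns of HRQoL
#'   decrements (`NA` = missing).
#' @param annual_cost numeric matrix, one row per patient and 5 columns of
#'   per-year costs in GBP (`NA` = missing).
#'
#' @return An object of class `cea_dataset`: a list with elements `patients`,
#'   `q`, `annual_cost`, `total_cost`, `total_cost_status` (one of
#'   `"observed"`, `"partial"`, `"missing"` per patient), `cost_lower`
#'   (the truncation lower bound, 0 when nothing is observed) and `n`.
#' @export
cea_dataset <- function(patients, q, annual_cost) {
  req <- c("patient_id", "arm_randomized", "arm_received", "age", "bmi", "sex", "bq")
  miss <- setdiff(req, names(patients))
  if (length(miss) > 0L) {
    stop("patients is missing required column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(patients)
  q <- as.matrix(q)
  annual_cost <- as.matrix(annual_cost)
  if (n > 0L && (nrow(q) != n || ncol(q) != 6L)) {
    stop("q must be an n x 6 matrix of HRQoL decrements")
  }
  if (n > 0L && (nrow(annual_cost) != n || ncol(annual_cost) != 5L)) {
    stop("annual_cost must be an n x 5 matrix")
  }
  if (n == 0L) {
    q <- matrix(numeric(0), 0L, 6L)
    annual_cost <- matrix(numeric(0), 0L, 5L)
  }
  patients$arm_randomized <- as.character(patients$arm_randomized)
  patients$arm_received <- as.character(patients$arm_received)
  bad_arm <- !(patients$arm_randomized %in% c("MM", "LS")) |
    !(patients$arm_received %in% c("MM", "LS"))
  if (any(bad_arm)) {
    stop("arm_randomized/arm_received must be 'MM' or 'LS' for every patient; offending patient(s): ",
         paste(utils::head(patients$patient_id[bad_arm], 5L), collapse = ", "))
  }
  for (v in c("age", "bmi", "sex")) {
    if (any(!is.finite(patients[[v]]))) {
      stop("covariate '", v, "' must be fully observed and finite")
    }
  }
  if (!all(patients$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (any(q < 0, na.rm = TRUE)) {
    stop("observed HRQoL decrements must be >= 0 (utility <= 1)")
  }
  bad_bq <- which(!is.na(patients$bq) & (patients$bq > 1.2 | patients$bq < 0))
  if (length(bad_bq) > 0L) {
    stop("baseline HRQoL decrement outside [0, 1.2] for patient(s): ",
         paste(patients$patient_id[bad_bq], collapse = ", "),
         " (decrements above 1.2 are not viable EQ-5D values)")
  }
  if (any(annual_cost < 0, na.rm = TRUE)) stop("annual costs must be >= 0")

  n_obs_cost <- rowSums(!is.na(annual_cost))
  cost_lower <- rowSums(annual_cost, na.rm = TRUE)
  total_cost_status <- ifelse(n_obs_cost == 5L, "observed",
                              ifelse(n_obs_cost == 0L, "missing", "partial"))
  total_cost <- ifelse(total_cost_status == "observed", cost_lower, NA_real_)
  cost_lower[total_cost_status == "missing"] <- 0
  if (n == 0L) {
    total_cost_status <- character(0)
    total_cost <- numeric(0)
    cost_lower <- numeric(0)
  }
  structure(list(
    patients = patients, q = q, annual_cost = annual_cost,
    total_cost = total_cost, total_cost_status = total_cost_status,
    cost_lower = cost_lower, n = n
  ), class = "cea_dataset")
}

#' @export
print.cea_dataset <- function(x, ...) {
  cat("<cea_dataset> ", x$n, " patients (",
      sum(x$patients$arm_randomized == "LS"), " randomized LS, ",
      sum(x$patients$arm_randomized == "MM"), " MM)\n", sep = "")
  if (x$n > 0L) {
    cat("  missing HRQoL cells: ", sum(is.na(x$q)), "/", length(x$q),
        "; total cost: ", sum(x$total_cost_status == "observed"), " observed, ",
        sum(x$total_cost_status == "partial"), " partial, ",
        sum(x$total_cost_status == "missing"), " missing",
        "; missing baseline: ", sum(is.na(x$patients$bq)), "\n", sep = "")
  }
  invisible(x)
}

default_schema <- function() {
  list(patient_id = "patient_id", arm_randomized = "arm_randomized",
       arm_received = "arm_received", age = "age", bmi = "bmi", sex = "sex",
       time = "time", utility = "utility", cost_period = "cost_period",
       baseline_utility = "baseline_utility")
}

num_or_die <- function(x, col, rows) {
  if (is.numeric(x)) return(x)
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(y))
  if (length(bad) > 0L) {
    stop("non-numeric value in column '", col, "' at input row(s): ",
         paste(utils::head(rows[bad], 5L), collapse = ", "))
  }
  y
}

#' Read a long-format trial CSV
#'
#' Expects one row per patient-timepoint with `time` in 1..6 (3 months, years
#' 1--5).  Utilities are converted to decrements (`1 - utility`) at load time
#' so every sub-model shares one scale.  The `cost_period` value on the row
#' for timepoint `t >= 2` is the cost of the year ending at `t` (year
#' `t - 1`); the value at `t = 1` is ignored.  Baseline covariates and the
#' baseline utility are taken from the patient's first row.
#'
#' @param path CSV file path.
#' @param schema_config optional column mapping: a named list overriding the
#'   default column names, or the path to a YAML file containing one.
#' @return A validated [cea_dataset()].
#' @export
load_long_dataset <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- default_schema()
  if (!is.null(schema_config)) {
    if (is.character(schema_config) && length(schema_config) == 1L) {
      schema_config <- yaml::read_yaml(schema_config)
    }
    sch[names(schema_config)] <- schema_config
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(sch[c("patient_id", "arm_randomized", "arm_received", "age",
                       "bmi", "sex", "time", "utility", "cost_period",
                       "baseline_utility")])
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0L) {
    stop("input is missing required column(s): ", paste(absent, collapse = ", "))
  }
  rows <- seq_len(nrow(raw))
  util <- num_or_die(raw[[sch$utility]], sch$utility, rows)
  cst <- num_or_die(raw[[sch$cost_period]], sch$cost_period, rows)
  butil <- num_or_die(raw[[sch$baseline_utility]], sch$baseline_utility, rows)
  tm <- as.integer(raw[[sch$time]])
  if (any(is.na(tm)) || (nrow(raw) > 0L && !all(tm %in% 1:6))) {
    stop("column '", sch$time, "' must contain timepoints 1..6")
  }
  ids <- as.character(raw[[sch$patient_id]])
  uid <- unique(ids)
  n <- length(uid)
  q <- matrix(NA_real_, n, 6L)
  ac <- matrix(NA_real_, n, 5L)
  first <- match(uid, ids)
  patients <- data.frame(
    patient_id = uid,
    arm_randomized = as.character(raw[[sch$arm_randomized]])[first],
    arm_received = as.character(raw[[sch$arm_received]])[first],
    age = num_or_die(raw[[sch$age]], sch$age, rows)[first],
    bmi = num_or_die(raw[[sch$bmi]], sch$bmi, rows)[first],
    sex = num_or_die(raw[[sch$sex]], sch$sex, rows)[first],
    bq = 1 - butil[first],
    stringsAsFactors = FALSE
  )
  ridx <- match(ids, uid)
  q[cbind(ridx, tm)] <- 1 - util
  yr <- tm - 1L
  keep <- yr >= 1L
  ac[cbind(ridx[keep], yr[keep])] <- cst[keep]
  cea_dataset(patients, q, ac)
}

#' Write a dataset back to long format
#'
#' Inverse of [load_long_dataset()]: values round-trip bit-exactly (numbers
#' are written with 17 significant digits) and missing cells stay missing.
#'
#' @param ds a [cea_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_dataset <- function(ds, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  p <- ds$patients
  out <- do.call(rbind, lapply(seq_len(ds$n), function(i) {
    data.frame(
      patient_id = p$patient_id[i], arm_randomized = p$arm_randomized[i],
      arm_received = p$arm_received[i],
      age = fmt(p$age[i]), bmi = fmt(p$bmi[i]), sex = fmt(p$sex[i]),
      time = 1:6,
      utility = fmt(1 - ds$q[i, ]),
      cost_period = fmt(c(NA, ds$annual_cost[i, ])),
      baseline_utility = fmt(1 - p$bq[i]),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) out <- data.frame()
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a canonical wide-format CSV (one row per patient) for inspection
#'
#' @param ds a [cea_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wide_dataset <- function(ds, path) {
  qd <- as.data.frame(ds$q)
  names(qd) <- paste0("q", 1:6)
  cd <- as.data.frame(ds$annual_cost)
  names(cd) <- paste0("cost_year", 1:5)
  out <- cbind(ds$patients, qd, cd,
               total_cost = ds$total_cost,
               total_cost_status = ds$total_cost_status,
               cost_lower = ds$cost_lower)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Classify each patient-timepoint as observed, interim missing, or LTFU
#'
#' Category 1 = HRQoL observed; 2 = interim missing (a later timepoint is
#' observed); 3 = loss to follow-up (missing with no later observation;
#' absorbing, so every subsequent timepoint is also 3).  A patient missing
#' every timepoint is loss to follow-up from the first timepoint.
#'
#' @param ds a [cea_dataset()].
#' @return list with `m` (n x 6 integer matrix of categories) and
#'   `ltfu_time` (first LTFU timepoint per patient, `NA` if none).
#' @export
classify_missingness <- function(ds) {
  n <- ds$n
  m <- matrix(1L, n, 6L)
  ltfu <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    obs <- !is.na(ds$q[i, ])
    last_obs <- if (any(obs)) max(which(obs)) else 0L
    for (t in 1:6) {
      m[i, t] <- if (obs[t]) 1L else if (t < last_obs) 2L else 3L
    }
    if (last_obs < 6L) ltfu[i] <- last_obs + 1L
  }
  list(m = m, ltfu_time = ltfu)
}

patient_pattern <- function(m) {
  has2 <- apply(m == 2L, 1L, any)
  has3 <- apply(m == 3L, 1L, any)
  ifelse(!has2 & !has3, "complete",
         ifelse(has2 & !has3, "interim_only",
                ifelse(!has2 & has3, "ltfu_only", "both")))
}

#' Tabulate patient-level missingness patterns by arm
#'
#' Partitions patients into four mutually exclusive categories -- complete,
#' interim missingness only, loss to follow-up only, or both -- and counts
#' them by randomized arm and overall.
#'
#' @param ds a [cea_dataset()].
#' @return data.frame with columns `arm`, `pattern`, `count`, `pct`
#'   (percentages sum to 100 within arm); zero rows for an empty dataset.
#' @export
summarize_missing_patterns <- function(ds) {
  lev <- c("complete", "interim_only", "ltfu_only", "both")
  if (ds$n == 0L) {
    return(data.frame(arm = character(0), pattern = character(0),
                      count = integer(0), pct = numeric(0)))
  }
  pat <- factor(patient_pattern(classify_missingness(ds)$m), levels = lev)
  one <- function(sel, arm) {
    tab <- table(pat[sel])
    data.frame(arm = arm, pattern = lev, count = as.integer(tab),
               pct = if (sum(tab) > 0L) 100 * as.integer(tab) / sum(tab) else rep(NA_real_, 4L))
  }
  rbind(one(ds$patients$arm_randomized == "MM", "MM"),
        one(ds$patients$arm_randomized == "LS", "LS"),
        one(rep(TRUE, ds$n), "overall"))
}
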