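# Synthetic ICU cohort generator.
#
# Emulates the statistical regime the pipeline assumes: hourly autocorrelated
# vitals, ~daily labs, heavy (~79%) raw missingness, a configurable sepsis
# prevalence, and a pre-onset physiological drift that makes early onset
# learnable. It makes no attempt at multi-organ trajectory realism.

# Physiological set-points: mean, spread (1 sd), and hard plausibility clips.
PARAM_SETPOINTS <- local({
  m <- rbind(
    HR = c(85, 12, 30, 200), O2Sat = c(97, 2, 70, 100),
    Temp = c(36.9, 0.4, 33, 42), SBP = c(120, 15, 50, 230),
    MAP = c(85, 10, 35, 160), DBP = c(65, 10, 25, 140),
    Resp = c(17, 3, 4, 50), EtCO2 = c(38, 4, 15, 70),
    BaseExcess = c(0, 3, -20, 20), HCO3 = c(24, 3, 8, 45),
    FiO2 = c(0.4, 0.1, 0.21, 1), pH = c(7.38, 0.04, 6.9, 7.7),
    PaCO2 = c(40, 5, 15, 90), SaO2 = c(96, 2, 70, 100),
    AST = c(35, 15, 5, 500), BUN = c(18, 7, 2, 150),
    Alkalinephos = c(80, 25, 10, 500), Calcium = c(8.8, 0.6, 5, 13),
    Chloride = c(103, 4, 80, 130), Creatinine = c(1.0, 0.3, 0.1, 12),
    Bilirubin_direct = c(0.3, 0.15, 0.01, 20), Glucose = c(120, 30, 30, 600),
    Lactate = c(1.5, 0.5, 0.3, 20), Magnesium = c(2.0, 0.25, 0.8, 5),
    Phosphate = c(3.5, 0.7, 0.8, 10), Potassium = c(4.1, 0.4, 2, 8),
    Bilirubin_total = c(0.8, 0.4, 0.05, 30), TroponinI = c(0.05, 0.04, 0.001, 30),
    Hct = c(33, 5, 12, 60), Hgb = c(11, 1.7, 4, 20),
    PTT = c(32, 6, 15, 150), WBC = c(9, 2.5, 0.2, 60),
    Fibrinogen = c(300, 70, 50, 900), Platelets = c(220, 60, 5, 800)
  )
  colnames(m) <- c("mu", "sigma", "lo", "hi")
  m[PSV_TIMEVARYING, ]
})

# Pre-onset drift directions (z-units are scaled by each parameter's sigma).
DRIFT_DIRECTIONS <- c(HR = 1, SBP = -1, Resp = 1, Temp = 1, WBC = 1,
                      Lactate = 1, Creatinine = 1, Platelets = -1)

# Parameters observed in only a minority of patients, so that the
# drop-if-missing-in->80%-of-patients feature-selection rule has real work.
RARE_PARAMS <- c("EtCO2", "TroponinI", "Fibrinogen", "Bilirubin_direct")
RARE_PATIENT_PRESENCE <- 0.15

#' Configuration for the synthetic ICU cohort generator
#'
#' Defaults are the study conditions the rest of the package is exercised
#' under: 7.26% sepsis prevalence, stays of 8-336 hours, hourly vitals,
#' ~daily labs, 79% overall raw missingness, and a 10-hour linear pre-onset
#' drift of 2.5 z-units on HR, SBP, Resp, Temp, WBC, Lactate, Creatinine and
#' Platelets (signs follow the physiology: blood pressure and platelets fall,
#' the rest rise).
#'
#' @param n_patients Number of patients to generate.
#' @param prevalence Probability that a patient is septic (default 0.0726).
#' @param min_stay,max_stay Stay-length bounds in hours (defaults 8 and 336).
#' @param vital_sampling_gap Hours between vital-sign observations (default 1).
#' @param lab_sampling_gap Hours between lab draws (default 24).
#' @param target_missingness Overall raw-cell missing fraction over the 34
#'   time-varying columns that MCAR thinning is calibrated to (default 0.79).
#' @param onset_drift_lead Hours before onset over which the drift ramps
#'   linearly from 0 to full effect (default 10).
#' @param effect_sizes Named vector of drift magnitudes in z-units; defaults
#'   to 2.5 for the eight drifting parameters.
#' @param seed Integer seed; identical config + seed reproduce the cohort
#'   byte-identically.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 200, prevalence = 0.0726,
                          min_stay = 8, max_stay = 336,
                          vital_sampling_gap = 1, lab_sampling_gap = 24,
                          target_missingness = 0.79, onset_drift_lead = 10,
                          effect_sizes = NULL, seed = 1L) {
  if (!is_count(n_patients)) stopf("n_patients must be a positive count")
  if (!is_prop(prevalence)) stopf("prevalence must lie in [0, 1]")
  if (min_stay < 8) stopf("min_stay must be at least 8 hours")
  if (max_stay < min_stay) stopf("max_stay must be >= min_stay")
  if (onset_drift_lead < 0) stopf("onset_drift_lead must be >= 0")
  if (!is_prop(target_missingness)) stopf("target_missingness must lie in [0, 1]")
  if (prevalence > 0 && n_patients * prevalence < 1)
    stopf("infeasible config: prevalence %.4f needs at least %d patients to expect a positive",
          prevalence, ceiling(1 / prevalence))
  if (is.null(effect_sizes))
    effect_sizes <- setNames(rep(2.5, length(DRIFT_DIRECTIONS)),
                             names(DRIFT_DIRECTIONS))
  unknown <- setdiff(names(effect_sizes), PSV_TIMEVARYING)
  if (length(unknown)) stopf("unknown parameter in effect_sizes: %s",
                             paste(unknown, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 min_stay = as.integer(min_stay), max_stay = as.integer(max_stay),
                 vital_sampling_gap = as.integer(vital_sampling_gap),
                 lab_sampling_gap = as.integer(lab_sampling_gap),
                 target_missingness = target_missingness,
                 onset_drift_lead = as.integer(onset_drift_lead),
                 effect_sizes = effect_sizes, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic ICU cohort
#'
#' Each patient gets a stay length drawn from a clipped lognormal, hourly
#' vital and lab trajectories from a first-order mean-reverting (AR1,
#' phi = 0.9) process around the physiological set-points, lab observations
#' every `lab_sampling_gap` hours with a random phase, and MCAR thinning of
#' the observed cells calibrated so the overall raw missing fraction hits
#' `target_missingness`. Septic patients receive a monotone linear drift in
#' z-units starting `onset_drift_lead` hours before onset and holding after
#' it, and `SepsisLabel` is 1 from the (unshifted) onset hour onward. Onset
#' never occurs before hour 5.
#'
#' @param config A [cohort_config()].
#' @return List with `records` (named list of [patient_record()]s) and
#'   `truth` (data frame `patient_id`, `is_septic`, `onset_hour`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 42))
#' table(cohort$truth$is_septic)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("S%05d", seq_len(n))
  stays <- pmin(config$max_stay,
                pmax(config$min_stay, round(rlnorm(n, log(42), 0.5))))
  septic <- rbinom(n, 1L, config$prevalence) == 1L
  if (config$prevalence > 0 && !any(septic)) septic[1] <- TRUE
  onsets <- rep(NA_integer_, n)
  for (i in which(septic))
    onsets[i] <- if (stays[i] <= 5L) stays[i]
                 else sample(5:stays[i], 1L)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- synth_patient(ids[i], stays[i], septic[i], onsets[i], config)
  }

  # Calibrate MCAR thinning: scaffold missingness m0 is lifted to the target
  # by dropping each observed cell independently with probability q.
  m0 <- measure_missingness(records)
  if (m0 < config$target_missingness) {
    q <- (config$target_missingness - m0) / (1 - m0)
    for (i in seq_len(n)) {
      v <- records[[i]]$values
      obs <- which(!is.na(v))
      drop <- obs[runif(length(obs)) < q]
      v[drop] <- NA_real_
      records[[i]]$values <- v
    }
  }
  names(records) <- ids
  truth <- data.frame(patient_id = ids, is_septic = septic,
                      onset_hour = onsets, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

synth_patient <- function(id, stay, is_septic, onset, config) {
  p <- nrow(PARAM_SETPOINTS)
  mu <- PARAM_SETPOINTS[, "mu"]; sg <- PARAM_SETPOINTS[, "sigma"]
  phi <- 0.9
  # AR1 deviations, innovation scaled so the stationary sd equals sigma.
  z <- matrix(rnorm(stay * p), stay, p)
  dev <- matrix(0, stay, p)
  dev[1, ] <- z[1, ]
  if (stay > 1) {
    s <- sqrt(1 - phi^2)
    for (t in 2:stay) dev[t, ] <- phi * dev[t - 1, ] + s * z[t, ]
  }
  vals <- sweep(sweep(dev, 2, sg, `*`), 2, mu, `+`)
  colnames(vals) <- rownames(PARAM_SETPOINTS)

  if (is_septic && config$onset_drift_lead > 0) {
    ramp <- pmin(1, pmax(0, (seq_len(stay) - (onset - config$onset_drift_lead)) /
                              config$onset_drift_lead))
    for (param in names(config$effect_sizes)) {
      dir <- DRIFT_DIRECTIONS[param]
      if (is.na(dir)) dir <- 1
      vals[, param] <- vals[, param] +
        dir * config$effect_sizes[[param]] * sg[param] * ramp
    }
  }
  vals <- pmin(pmax(vals, matrix(PARAM_SETPOINTS[, "lo"], stay, p, byrow = TRUE)),
               matrix(PARAM_SETPOINTS[, "hi"], stay, p, byrow = TRUE))
  vals <- round(vals, 2)

  # Observation scaffold: vitals on their (usually hourly) grid, labs on a
  # daily grid with a per-patient random phase, rare parameters present in
  # only a minority of patients.
  mask <- matrix(FALSE, stay, p, dimnames = dimnames(vals))
  vg <- config$vital_sampling_gap
  mask[, PSV_VITALS] <- (seq_len(stay) - 1L) %% vg == 0L
  for (lab in PSV_LABS) {
    phase <- sample.int(config$lab_sampling_gap, 1L)
    mask[, lab] <- (seq_len(stay) - phase) %% config$lab_sampling_gap == 0L
  }
  for (param in RARE_PARAMS) {
    if (runif(1) > RARE_PATIENT_PRESENCE) mask[, param] <- FALSE
  }
  vals[!mask] <- NA_real_

  demo <- c(Age = round(pmin(100, pmax(18, rnorm(1, 62, 15)))),
            Gender = rbinom(1, 1L, 0.5),
            Unit1 = NA_real_, Unit2 = NA_real_,
            HospAdmTime = -round(runif(1, 1, 120), 2))
  demo["Unit1"] <- rbinom(1, 1L, 0.5)
  demo["Unit2"] <- 1 - demo["Unit1"]

  label <- integer(stay)
  if (is_septic) label[seq_len(stay) >= onset] <- 1L
  patient_record(id, vals, demo, label)
}

#' Raw-cell missing fraction of a cohort
#'
#' Fraction of `NA` cells over the 34 time-varying (vital + lab) columns,
#' pooled across all hours of all records; demographics are excluded.
#'
#' @param records List of [patient_record()]s (or a single record).
#' @return A proportion in \[0, 1\].
#' @export
measure_missingness <- function(records) {
  if (inherits(records, "patient_record")) records <- list(records)
  na_cells <- vapply(records, function(r) sum(is.na(r$values)), numeric(1))
  all_cells <- vapply(records, function(r) length(r$values), numeric(1))
  sum(na_cells) / sum(all_cells)
}

#' Deterministic per-hour probability fixtures for the alarm logic
#'
#' Builds the four canonical risk-trajectory shapes used to exercise the
#' warning/alert system: a quiet negative, a negative with isolated
#' threshold crossings that never satisfy the 3-in-5 rule, an ideal positive
#' whose alert fires well before onset, and a positive whose first warning
#' cluster is too sparse but whose second cluster raises the alarm closer to
#' onset. Probabilities start at hour 4, the first hour a 4-hour window
#' exists.
#'
#' @param truth One-row slice of a ground-truth table (fields `is_septic`
#'   and `onset_hour`), or a list with those fields.
#' @param profile One of `"ideal_negative"`, `"isolated_warnings"`,
#'   `"ideal_positive"`, `"clustered_late"`.
#' @param hours Total stay length; defaults to `onset_hour + 6` for septic
#'   profiles and 24 otherwise.
#' @return Numeric probability vector with attribute `hours` giving the
#'   ICULOS index of each entry (starting at 4).
#' @export
inject_probability_stream <- function(truth, profile, hours = NULL) {
  profiles <- c("ideal_negative", "isolated_warnings", "ideal_positive",
                "clustered_late")
  if (!profile %in% profiles)
    stopf("unknown probability profile '%s'", profile)
  septic_profile <- profile %in% c("ideal_positive", "clustered_late")
  is_septic <- isTRUE(as.logical(truth$is_septic))
  if (septic_profile && !is_septic)
    stopf("profile '%s' needs a septic patient", profile)
  onset <- if (is_septic) as.integer(truth$onset_hour) else NA_integer_
  if (is.null(hours)) hours <- if (septic_profile) onset + 6L else 24L
  hrs <- 4:hours
  if (length(hrs) < 1L) stopf("stay too short for a probability stream")
  p <- 0.15 + 0.1 * abs(sin(hrs / 3))

  if (profile == "isolated_warnings") {
    p[hrs %% 8L == 0L] <- 0.7
  } else if (profile == "ideal_positive") {
    start <- max(4L, onset - 10L)
    if (start + 6L > onset)
      stopf("onset hour %d too early for the ideal_positive profile", onset)
    p[hrs >= start] <- 0.85
  } else if (profile == "clustered_late") {
    if (onset < 12L)
      stopf("onset hour %d too early for the clustered_late profile", onset)
    early <- max(4L, onset - 12L)
    p[hrs %in% c(early, early + 1L)] <- 0.65
    p[hrs >= onset - 6L & hrs <= onset - 4L] <- 0.8
  }
  attr(p, "hours") <- hrs
  p
}
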