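# Preprocessing: exclusion rules, label shifting, time-limited
# sample-and-hold imputation, min-max rescaling to [1,5] with a -1 sentinel,
# feature selection, derived clinical features, and overlapping 4x21 window
# construction with negative undersampling.

#' Sample-and-hold imputation policy
#'
#' Per-parameter hold limits in hours: an observed value is carried forward
#' into subsequent missing hours for at most this long. Defaults follow the
#' inter-measurement analysis behind the pipeline: 4 h for vitals, 24 h for
#' labs. `fill_value` is the sentinel written into cells that remain missing
#' after the hold (set it to `NA` to keep them missing, e.g. when raw-unit
#' clinical scores are computed next).
#'
#' @param vitals Hold limit in hours for the 8 vital signs (default 4).
#' @param labs Hold limit in hours for the 26 lab values (default 24).
#' @param overrides Optional named vector of per-parameter hold limits.
#' @param fill_value Sentinel for still-missing cells (default -1).
#' @return An `imputation_policy`: list with `hold_limits` (named over all
#'   34 time-varying parameters) and `fill_value`.
#' @export
imputation_policy <- function(vitals = 4, labs = 24, overrides = NULL,
                              fill_value = -1) {
  if (vitals < 1 || labs < 1 || vitals != round(vitals) || labs != round(labs))
    stopf("hold limits must be positive integer hours")
  limits <- c(setNames(rep(as.integer(vitals), length(PSV_VITALS)), PSV_VITALS),
              setNames(rep(as.integer(labs), length(PSV_LABS)), PSV_LABS))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(limits))
    if (length(unknown)) stopf("no such parameter: %s",
                               paste(unknown, collapse = ", "))
    if (any(overrides < 1 | overrides != round(overrides)))
      stopf("hold limits must be positive integer hours")
    limits[names(overrides)] <- as.integer(overrides)
  }
  structure(list(hold_limits = limits, fill_value = fill_value),
            class = "imputation_policy")
}

#' Apply the cohort exclusion rules
#'
#' Drops patients with fewer than 8 hours of ICU data, drops septic patients
#' whose onset falls before hour 4, and truncates every remaining record at
#' 336 hours (two weeks).
#'
#' @param records List of [patient_record()]s.
#' @param min_hours Minimum stay length kept (default 8).
#' @param min_onset Earliest allowed sepsis onset hour (default 4).
#' @param max_hours Truncation horizon in hours (default 336).
#' @return List with `records` (kept, possibly truncated) and `log`
#'   (data frame `patient_id`, `reason` for every exclusion/truncation).
#' @export
apply_exclusions <- function(records, min_hours = 8, min_onset = 4,
                             max_hours = 336) {
  kept <- list()
  log <- data.frame(patient_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  note <- function(id, why) {
    log[nrow(log) + 1L, ] <<- list(id, why)
  }
  for (rec in records) {
    n <- nrow(rec$values)
    if (n < min_hours) {
      note(rec$patient_id, sprintf("stay<%dh", min_hours))
      next
    }
    onset <- onset_hour(rec)
    if (!is.na(onset) && onset < min_onset) {
      note(rec$patient_id, sprintf("onset<%dh", min_onset))
      next
    }
    if (n > max_hours) {
      rec$values <- rec$values[seq_len(max_hours), , drop = FALSE]
      rec$iculos <- rec$iculos[seq_len(max_hours)]
      rec$sepsis_label <- rec$sepsis_label[seq_len(max_hours)]
      note(rec$patient_id, sprintf("truncated at %dh", max_hours))
    }
    kept[[rec$patient_id]] <- rec
  }
  list(records = kept, log = log)
}

#' Shift sepsis labels for early prediction
#'
#' For a septic patient with onset at hour H, the per-hour prediction target
#' is 1 from hour `max(1, H - lookahead)` onward (default lookahead 6 hours),
#' so the classifier learns to fire ahead of onset. Non-septic targets are
#' all zero.
#'
#' @param rec A [patient_record()].
#' @param lookahead Hours the positive block is extended backwards
#'   (default 6; must be >= 0).
#' @return Integer 0/1 target vector, one entry per hour.
#' @export
#' @examples
#' # onset at hour 20 -> targets become positive at hour 14
shift_labels <- function(rec, lookahead = 6) {
  if (lookahead < 0) stopf("lookahead must be >= 0")
  lab <- rec$sepsis_label
  if (length(lab) > 1L && any(diff(lab) < 0L))
    stopf("sepsis label must be monotone non-decreasing")
  targets <- integer(length(lab))
  onset <- onset_hour(rec)
  if (!is.na(onset))
    targets[rec$iculos >= max(1L, onset - as.integer(lookahead))] <- 1L
  targets
}

#' Time-limited sample-and-hold imputation
#'
#' For each parameter independently, every observed value is carried forward
#' into subsequent missing hours for at most its hold limit; observed cells
#' are never altered, and a fresh observation restarts the hold clock. Cells
#' still missing afterwards (including fully absent parameters) are set to
#' the policy's `fill_value` sentinel (-1 by default; `NA` keeps them
#' missing). The operation is idempotent.
#'
#' @param rec A [patient_record()].
#' @param policy An [imputation_policy()].
#' @return The record with its `values` matrix imputed.
#' @export
impute_sample_hold <- function(rec, policy = imputation_policy()) {
  if (!inherits(policy, "imputation_policy")) stopf("need an imputation_policy")
  v <- rec$values
  absent <- setdiff(colnames(v), names(policy$hold_limits))
  if (length(absent)) stopf("no hold limit for parameter(s): %s",
                            paste(absent, collapse = ", "))
  n <- nrow(v)
  for (p in colnames(v)) {
    col <- v[, p]
    limit <- policy$hold_limits[[p]]
    last_val <- NA_real_
    age <- Inf
    for (t in seq_len(n)) {
      if (!is.na(col[t])) {
        last_val <- col[t]
        age <- 0L
      } else {
        age <- age + 1L
        if (age <= limit) col[t] <- last_val
      }
    }
    v[, p] <- col
  }
  if (!is.na(policy$fill_value)) v[is.na(v)] <- policy$fill_value
  rec$values <- v
  rec
}

#' Min-max rescale to \[1, 5\] with a -1 missing sentinel
#'
#' Values are truncated to the parameter's configured `[x_min, x_max]` range
#' and mapped linearly so that `x_min` becomes 1 and `x_max` becomes 5:
#' `Y = 4 (x - x_min) / (x_max - x_min) + 1`. Missing values map to -1, a
#' sentinel the classifier's masking understands. The narrow [1, 5] band
#' keeps small physiological changes numerically visible.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param limits Length-2 numeric `c(x_min, x_max)` with `x_min < x_max`.
#' @return Numeric vector with entries in `{-1}` union `[1, 5]`.
#' @export
#' @examples
#' normalize_minmax(c(30, 105, 180, NA), c(30, 180))
normalize_minmax <- function(x, limits) {
  limits <- as.numeric(limits)
  if (length(limits) != 2L || !all(is.finite(limits)) || limits[1] >= limits[2])
    stopf("degenerate normalization limits")
  clamped <- pmin(pmax(x, limits[1]), limits[2])
  y <- 4 * (clamped - limits[1]) / (limits[2] - limits[1]) + 1
  y[is.na(x)] <- -1
  y
}

#' Select model parameters from a cohort
#'
#' First drops every time-varying parameter that is entirely unobserved in
#' more than `max_missing_fraction` of the patients, then checks that the
#' configured final parameter set survived. The final raw set (default: 7
#' vitals, 8 labs, Age and Gender) is what [build_feature_matrix()] extends
#' with the 4 derived parameters to the 21-column model input.
#'
#' @param records List of raw (pre-imputation) [patient_record()]s.
#' @param max_missing_fraction Patient-level missingness above which a
#'   parameter is dropped (default 0.80).
#' @param config Feature configuration from [feature_config()].
#' @return List with `selected` (the raw parameter names kept, demographics
#'   included), `dropped` (parameters removed by the missingness rule) and
#'   `patient_missing_fraction` (named fractions over all 34 parameters).
#' @export
select_features <- function(records, max_missing_fraction = 0.80,
                            config = feature_config()) {
  if (!length(records)) stopf("empty cohort")
  absent <- vapply(records, function(r) colSums(!is.na(r$values)) == 0L,
                   logical(length(PSV_TIMEVARYING)))
  frac_missing <- rowMeans(absent)
  dropped <- names(frac_missing)[frac_missing > max_missing_fraction]
  selected_tv <- setdiff(config$selected_raw, config$selected_demographics)
  unknown <- setdiff(selected_tv, PSV_TIMEVARYING)
  if (length(unknown)) stopf("selected parameter not present in data: %s",
                             paste(unknown, collapse = ", "))
  gone <- intersect(selected_tv, dropped)
  if (length(gone))
    stopf("selected parameter(s) removed by the %.0f%% missingness rule: %s",
          100 * max_missing_fraction, paste(gone, collapse = ", "))
  list(selected = config$selected_raw, dropped = dropped,
       patient_missing_fraction = frac_missing)
}

#' Assemble the raw 21-parameter feature matrix for one record
#'
#' From a sample-and-hold imputed record (hold applied, still-missing cells
#' left as `NA`): the selected raw vitals, labs and demographics, plus the 4
#' derived parameters — shock index, BUN/creatinine ratio, MEWS and partial
#' SOFA. The two ratios propagate missingness; the two scores treat missing
#' components as 0 points and are therefore always defined.
#'
#' @param rec A [patient_record()] whose values have been hold-imputed with
#'   `fill_value = NA`.
#' @param config Feature configuration from [feature_config()].
#' @param bands Band tables from [score_bands()].
#' @return Numeric matrix, hours x 21, in native units with `NA` for missing.
#' @export
build_feature_matrix <- function(rec, config = feature_config(),
                                 bands = score_bands()) {
  v <- rec$values
  n <- nrow(v)
  raw_tv <- setdiff(config$selected_raw, config$selected_demographics)
  mat <- v[, raw_tv, drop = FALSE]
  demo <- matrix(rep(rec$demographics[config$selected_demographics], each = n),
                 nrow = n,
                 dimnames = list(NULL, config$selected_demographics))
  derived <- cbind(
    ShockIndex = shock_index(v[, "HR"], v[, "SBP"]),
    BUN_CR_Ratio = bun_creatinine_ratio(v[, "BUN"], v[, "Creatinine"]),
    MEWS = as.numeric(mews(v[, "SBP"], v[, "HR"], v[, "Resp"], v[, "Temp"],
                           bands)),
    pSOFA = as.numeric(psofa(v[, "MAP"], v[, "Bilirubin_total"],
                             v[, "Platelets"], bands))
  )
  out <- cbind(mat, demo, derived)
  out[, c(raw_tv, config$selected_demographics, config$derived_parameters),
      drop = FALSE]
}

#' Normalize a raw feature matrix
#'
#' Applies [normalize_minmax()] column-wise with each parameter's configured
#' limits; every entry of the result is -1 (missing) or in \[1, 5\].
#'
#' @param mat Raw feature matrix from [build_feature_matrix()].
#' @param config Feature configuration from [feature_config()].
#' @return Matrix of the same shape.
#' @export
normalize_features <- function(mat, config = feature_config()) {
  for (p in colnames(mat)) {
    lim <- config$normalization_limits[[p]]
    if (is.null(lim)) stopf("no normalization limits for parameter '%s'", p)
    mat[, p] <- normalize_minmax(mat[, p], lim)
  }
  mat
}

#' Full preprocessing of one record
#'
#' Runs sample-and-hold imputation (hold limits from the configuration,
#' missing kept as `NA`), assembles the raw 21-parameter feature matrix,
#' normalizes it to `{-1}` union \[1, 5\], and shifts the per-hour targets by
#' the configured lookahead.
#'
#' @param rec A raw [patient_record()].
#' @param config Feature configuration from [feature_config()].
#' @param bands Band tables from [score_bands()].
#' @return A `processed_record`: list with `patient_id`, `features`
#'   (hours x 21 normalized matrix), `targets` (shifted 0/1), `iculos`,
#'   `onset_hour`.
#' @export
preprocess_record <- function(rec, config = feature_config(),
                              bands = score_bands()) {
  policy <- imputation_policy(config$hold_limits$vitals,
                              config$hold_limits$labs, fill_value = NA)
  held <- impute_sample_hold(rec, policy)
  feats <- normalize_features(build_feature_matrix(held, config, bands),
                              config)
  structure(
    list(patient_id = rec$patient_id, features = feats,
         targets = shift_labels(rec, config$label_lookahead),
         iculos = rec$iculos, onset_hour = onset_hour(rec)),
    class = "processed_record"
  )
}

#' Slice a processed record into overlapping windows
#'
#' One `n_hours` x 21 window per end hour from `n_hours` to the stay length
#' (stride 1 by default); each window's target is the shifted label at its
#' end hour. No padding: predictions start once a full window exists
#' (hour 4 with defaults).
#'
#' @param proc A `processed_record` from [preprocess_record()].
#' @param n_hours Window length in hours (default 4).
#' @param stride Step between window end hours (default 1).
#' @return List of `feature_window`s: each has `matrix` (n_hours x 21),
#'   `end_hour`, `target`, `patient_id`.
#' @export
build_windows <- function(proc, n_hours = 4, stride = 1) {
  n <- nrow(proc$features)
  if (n < n_hours)
    stopf("patient %s: record shorter than the %d-hour window",
          proc$patient_id, n_hours)
  ends <- seq(n_hours, n, by = stride)
  lapply(ends, function(e) {
    structure(
      list(matrix = proc$features[(e - n_hours + 1L):e, , drop = FALSE],
           end_hour = proc$iculos[e],
           target = proc$targets[e],
           patient_id = proc$patient_id),
      class = "feature_window"
    )
  })
}

#' Undersample negative windows
#'
#' Keeps every positive window and randomly subsamples the negatives, pooled
#' across the whole negative cohort, down to `ratio` times the positive
#' count. Drawing from the pooled negatives (rather than per patient) keeps
#' the retained negative subset heterogeneous.
#'
#' @param windows List of `feature_window`s.
#' @param ratio Negatives kept per positive (default 1.0).
#' @param seed Integer seed; the same seed reproduces the same subsample.
#' @return List of windows, positives first.
#' @export
undersample_negatives <- function(windows, ratio = 1.0, seed = 1L) {
  targets <- vapply(windows, `[[`, numeric(1), "target")
  pos <- which(targets == 1)
  neg <- which(targets == 0)
  if (!length(pos)) stopf("no positive windows to balance against")
  n_keep <- min(length(neg), round(ratio * length(pos)))
  keep_neg <- with_seed(seed, sample(neg, n_keep))
  windows[c(pos, sort(keep_neg))]
}

#' Stack windows into classifier arrays
#'
#' @param windows List of `feature_window`s.
#' @return List with `x` (array, n_windows x n_hours x n_features),
#'   `y` (numeric targets), `patient_id`, `end_hour`.
#' @export
stack_windows <- function(windows) {
  if (!length(windows)) stopf("no windows to stack")
  d <- dim(windows[[1]]$matrix)
  x <- array(NA_real_, c(length(windows), d[1], d[2]))
  for (i in seq_along(windows)) x[i, , ] <- windows[[i]]$matrix
  list(x = x,
       y = vapply(windows, `[[`, numeric(1), "target"),
       patient_id = vapply(windows, `[[`, character(1), "patient_id"),
       end_hour = vapply(windows, function(w) as.numeric(w$end_hour),
                         numeric(1)))
}
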