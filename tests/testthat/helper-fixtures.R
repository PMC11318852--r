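# Shared fixtures, built in code and memoized so expensive cohorts are
# generated once per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# A small hand-made record: `obs` is a named list parameter -> numeric
# vector (NA = missing); unstated parameters are fully missing.
toy_record <- function(hours, obs = list(), label = integer(hours),
                       id = "toy",
                       demo = c(Age = 60, Gender = 1, Unit1 = 1, Unit2 = 0,
                                HospAdmTime = -5)) {
  vals <- matrix(NA_real_, hours, 34,
                 dimnames = list(NULL, psv_columns("timevarying")))
  for (p in names(obs)) vals[, p] <- obs[[p]]
  patient_record(id, vals, demo, as.integer(label))
}

# Default small synthetic cohort shared across test files.
small_cohort <- function() {
  memo("small_cohort",
       generate_cohort(cohort_config(n_patients = 40, prevalence = 0.2,
                                     seed = 7)))
}

# Brute-force alert oracle: scan every hour's trailing window.
brute_force_alert <- function(warning_hours, x, w, horizon = 60L) {
  for (t in seq_len(horizon)) {
    if (sum(warning_hours >= t - w + 1L & warning_hours <= t) >= x)
      return(t)
  }
  NA_integer_
}

# Brute-force per-cell sample-and-hold oracle.
brute_force_hold <- function(col, limit, fill = -1) {
  out <- col
  for (t in seq_along(col)) {
    if (is.na(col[t])) {
      obs <- which(!is.na(col[seq_len(t - 1)]))
      if (length(obs) && t - max(obs) <= limit) {
        out[t] <- col[max(obs)]
      } else {
        out[t] <- fill
      }
    }
  }
  if (is.na(fill)) out else {
    out[is.na(out)] <- fill
    out
  }
}

# Quadratic-time pairwise AUROC oracle.
brute_force_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
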