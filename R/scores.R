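# Derived clinical features and comparator severity scores.
#
# Missing inputs never raise errors here: the two ratios propagate
# missingness, the banded scores let a missing component contribute 0
# points. Under ~79% raw missingness that is the only computable policy,
# and it is stated openly rather than hidden.

#' Shock index
#'
#' Heart rate divided by systolic blood pressure.
#'
#' @param hr Heart rate, beats/min.
#' @param sbp Systolic blood pressure, mmHg.
#' @return `hr / sbp`; `NA` where either input is missing or `sbp <= 0`.
#'   Vectorized.
#' @export
#' @examples
#' shock_index(120, 80)  # 1.5
shock_index <- function(hr, sbp) {
  out <- ifelse(is.na(hr) | is.na(sbp) | sbp <= 0, NA_real_, hr / sbp)
  as.numeric(out)
}

#' Blood urea nitrogen to creatinine ratio
#'
#' @param bun Blood urea nitrogen, mg/dL.
#' @param creatinine Serum creatinine, mg/dL.
#' @return `bun / creatinine`; `NA` where either input is missing or
#'   `creatinine <= 0`. Vectorized.
#' @export
bun_creatinine_ratio <- function(bun, creatinine) {
  out <- ifelse(is.na(bun) | is.na(creatinine) | creatinine <= 0,
                NA_real_, bun / creatinine)
  as.numeric(out)
}

# Points for one banded component: first rule whose [lower, upper] interval
# contains the value; NA contributes 0.
band_points <- function(value, rules) {
  pts <- numeric(length(value))
  ok <- !is.na(value)
  if (any(ok)) {
    v <- value[ok]
    idx <- vapply(v, function(x) {
      hit <- which(x >= rules[, "lower"] & x <= rules[, "upper"])
      if (!length(hit)) stopf("value %g falls outside every band", x)
      hit[1]
    }, integer(1))
    pts[ok] <- rules[idx, "points"]
  }
  pts
}

score_from_bands <- function(score_name, inputs, bands = score_bands()) {
  tab <- bands[[score_name]]
  if (is.null(tab)) stopf("unknown score '%s'", score_name)
  n <- max(lengths(inputs))
  total <- numeric(n)
  for (comp in names(tab$components)) {
    v <- inputs[[comp]]
    if (is.null(v)) v <- rep(NA_real_, n)
    total <- total + band_points(rep_len(v, n), tab$components[[comp]])
  }
  as.integer(total)
}

#' Partial SOFA score (MAP, bilirubin, platelets)
#'
#' The organ-dysfunction sub-scores computable from routinely charted data:
#' cardiovascular without vasopressor tiers (MAP < 70 mmHg scores 1), liver
#' (total bilirubin bands 0-4) and coagulation (platelet bands 0-4), summed
#' to 0-9 points. Missing components contribute 0.
#'
#' @param map Mean arterial pressure, mmHg.
#' @param bilirubin Total bilirubin, mg/dL.
#' @param platelets Platelet count, 10^3/uL.
#' @param bands Band tables from [score_bands()].
#' @return Integer points, 0-9. Vectorized.
#' @export
#' @examples
#' psofa(65, 2.5, 90)  # 1 + 2 + 2 = 5
psofa <- function(map, bilirubin, platelets, bands = score_bands()) {
  if (any(c(map, bilirubin, platelets) < 0, na.rm = TRUE))
    stopf("negative physiological inputs")
  score_from_bands("psofa",
                   list(MAP = map, Bilirubin_total = bilirubin,
                        Platelets = platelets), bands)
}

#' SIRS criteria count and flag
#'
#' One criterion each for deranged temperature (>38 or <36 C), tachycardia
#' (HR > 90), tachypnea or hypocapnia (Resp > 20 or PaCO2 < 32 mmHg), and
#' white-cell derangement (WBC > 12 or < 4 x 10^3/uL). A missing component
#' is counted as not met; the flag fires at >= 2 criteria.
#'
#' @param temp Temperature, degrees C.
#' @param hr Heart rate, beats/min.
#' @param resp Respiratory rate, breaths/min.
#' @param paco2 PaCO2, mmHg.
#' @param wbc White-cell count, 10^3/uL.
#' @param bands Band tables from [score_bands()] (uses the `sirs` entry).
#' @return List with integer `count` (0-4) and logical `flag`. Vectorized.
#' @export
#' @examples
#' sirs(39, 100, 22, wbc = 13)$count  # 4
sirs <- function(temp = NA, hr = NA, resp = NA, paco2 = NA, wbc = NA,
                 bands = score_bands()) {
  inputs <- list(Temp = temp, HR = hr, Resp = resp, PaCO2 = paco2, WBC = wbc)
  n <- max(lengths(inputs))
  inputs <- lapply(inputs, rep_len, n)
  count <- integer(n)
  for (crit in bands$sirs$criteria) {
    met <- rep(FALSE, n)
    for (cond in crit) {
      v <- inputs[[cond$parameter]]
      hit <- switch(cond$op,
                    gt = v > cond$value,
                    lt = v < cond$value,
                    stopf("unknown criterion op '%s'", cond$op))
      met <- met | (!is.na(hit) & hit)
    }
    count <- count + met
  }
  list(count = count, flag = count >= bands$sirs$trigger_threshold)
}

#' National Early Warning Score (available components)
#'
#' Standard NEWS bands over respiratory rate, oxygen saturation,
#' temperature, systolic blood pressure and heart rate. The supplemental
#' oxygen and consciousness components are not recorded in the hourly
#' files and contribute 0.
#'
#' @param resp,o2sat,temp,sbp,hr Component values in native units.
#' @param bands Band tables from [score_bands()].
#' @return List with integer `points` and logical `flag`
#'   (at the `news` trigger threshold, default 7). Vectorized.
#' @export
#' @examples
#' news(resp = 25, o2sat = 91, sbp = 95)$points  # 3 + 3 + 2 = 8
news <- function(resp = NA, o2sat = NA, temp = NA, sbp = NA, hr = NA,
                 bands = score_bands()) {
  pts <- score_from_bands("news",
                          list(Resp = resp, O2Sat = o2sat, Temp = temp,
                               SBP = sbp, HR = hr), bands)
  list(points = pts, flag = pts >= bands$news$trigger_threshold)
}

#' Modified Early Warning Score (available components)
#'
#' Standard MEWS bands over systolic blood pressure, heart rate,
#' respiratory rate and temperature; the AVPU consciousness component is
#' unavailable and contributes 0.
#'
#' @param sbp,hr,resp,temp Component values in native units.
#' @param bands Band tables from [score_bands()].
#' @return Integer points. Vectorized.
#' @export
#' @examples
#' mews(sbp = 75, hr = 115)  # 2 + 2 = 4
mews <- function(sbp = NA, hr = NA, resp = NA, temp = NA,
                 bands = score_bands()) {
  score_from_bands("mews",
                   list(SBP = sbp, HR = hr, Resp = resp, Temp = temp), bands)
}

#' Per-hour score stream for one record
#'
#' Computes a severity score for every hour of a record from the raw
#' (unnormalized, typically sample-and-hold imputed) values.
#'
#' @param rec A [patient_record()].
#' @param score_name One of `"sirs"`, `"news"`, `"mews"`, `"psofa"`.
#' @param bands Band tables from [score_bands()].
#' @return Integer vector of per-hour points (criteria count for SIRS).
#' @export
score_stream <- function(rec, score_name, bands = score_bands()) {
  v <- rec$values
  switch(score_name,
    sirs = sirs(v[, "Temp"], v[, "HR"], v[, "Resp"], v[, "PaCO2"],
                v[, "WBC"], bands)$count,
    news = news(v[, "Resp"], v[, "O2Sat"], v[, "Temp"], v[, "SBP"],
                v[, "HR"], bands)$points,
    mews = mews(v[, "SBP"], v[, "HR"], v[, "Resp"], v[, "Temp"], bands),
    psofa = psofa(v[, "MAP"], v[, "Bilirubin_total"], v[, "Platelets"], bands),
    stopf("unknown score '%s'", score_name)
  )
}

#' Hourly binary alarm stream from a comparator score
#'
#' Turns a severity score into a stand-alone hourly alarm (score at or above
#' the trigger threshold), so SIRS/NEWS/MEWS/pSOFA feed the same
#' patient-level evaluation as the model's alerts.
#'
#' @param rec A [patient_record()] (raw or imputed values).
#' @param score_name One of `"sirs"`, `"news"`, `"mews"`, `"psofa"`.
#' @param threshold Points needed to alarm; defaults to the score's
#'   configured trigger threshold.
#' @param bands Band tables from [score_bands()].
#' @return List with `hours`, integer `score`, logical `alarm`, and
#'   `alert_hour` (first alarmed hour or `NA`).
#' @export
comparator_alarm_trace <- function(rec, score_name, threshold = NULL,
                                   bands = score_bands()) {
  stream <- score_stream(rec, score_name, bands)
  if (is.null(threshold)) threshold <- bands[[score_name]]$trigger_threshold
  alarm <- stream >= threshold
  list(patient_id = rec$patient_id, hours = rec$iculos, score = stream,
       alarm = alarm,
       alert_hour = if (any(alarm)) rec$iculos[which(alarm)[1]] else NA_integer_)
}
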