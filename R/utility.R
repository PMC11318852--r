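# Timeliness-aware utility score.
#
# Per-hour rewards and penalties around the true onset: a positive
# prediction earns a reward ramping from 0 twelve hours before onset to its
# maximum six hours before, decaying to 0 three hours after; a negative
# prediction near or after onset is penalized down to the worst
# missed-detection value; false-positive hours on non-septic patients cost
# a small constant. The cohort total is normalized between the all-negative
# predictor (score 0) and the reference ideal predictor that turns positive
# exactly `optimal_offset` hours before every onset (score 1).

#' Utility score parameters
#'
#' @param early_window Hours before onset at which the true-positive reward
#'   ramp starts (default 12).
#' @param optimal_offset Hours before onset of maximal reward (default 6,
#'   tied to the 6-hour label shift).
#' @param late_limit Hours after onset at which penalties saturate
#'   (default 3).
#' @param u_fp Per-hour false-positive penalty (default -0.05).
#' @param u_fn_min Worst per-hour missed-detection penalty (default -2).
#' @param u_tn Per-hour true-negative reward (default 0).
#' @return A `utility_params` list.
#' @export
utility_params <- function(early_window = 12, optimal_offset = 6,
                           late_limit = 3, u_fp = -0.05, u_fn_min = -2,
                           u_tn = 0) {
  if (early_window <= optimal_offset || optimal_offset < 0)
    stopf("need early_window > optimal_offset >= 0")
  if (late_limit < 0) stopf("late_limit must be >= 0")
  if (u_fp > 0 || u_fn_min > 0) stopf("penalties must be <= 0")
  structure(list(early_window = early_window,
                 optimal_offset = optimal_offset, late_limit = late_limit,
                 u_fp = u_fp, u_fn_min = u_fn_min, u_tn = u_tn),
            class = "utility_params")
}

# Raw (unnormalized) utility of one patient's hourly 0/1 predictions.
patient_utility <- function(predictions, onset, params) {
  t <- seq_along(predictions)
  pred <- as.numeric(predictions)
  if (is.na(onset)) {
    return(sum(ifelse(pred == 1, params$u_fp, params$u_tn)))
  }
  up <- params$optimal_offset; ew <- params$early_window
  ll <- params$late_limit
  # positive-prediction utility
  ramp_up <- (t - (onset - ew)) / (ew - up)
  ramp_down <- ((onset + ll) - t) / (ll + up)
  u_pos <- ifelse(t <= onset - up,
                  pmax(ramp_up, params$u_fp),
                  ifelse(t <= onset + ll, ramp_down, 0))
  u_pos <- pmin(u_pos, 1)
  # negative-prediction utility: 0 until the optimal hour, then ramping to
  # the worst missed-detection penalty, which saturates after late_limit
  u_neg <- ifelse(t <= onset - up, 0,
                  ifelse(t <= onset + ll,
                         params$u_fn_min * (t - (onset - up)) / (ll + up),
                         params$u_fn_min))
  sum(ifelse(pred == 1, u_pos, u_neg))
}

# The reference ideal predictor: positive from optimal_offset hours before
# onset to the end of stay, negative everywhere else.
ideal_predictions <- function(stay, onset, params) {
  pred <- integer(stay)
  if (!is.na(onset)) pred[seq_len(stay) >= max(1, onset - params$optimal_offset)] <- 1L
  pred
}

#' Normalized cohort utility score
#'
#' Sums the per-hour utilities over all patients and rescales them between
#' two anchors computed on the same cohort: the all-negative predictor
#' (normalized score 0) and the reference ideal predictor, positive exactly
#' from `optimal_offset` hours before each true onset onward with no false
#' positives (normalized score 1).
#'
#' @param predictions Named list of per-patient hourly 0/1 vectors, aligned
#'   to ICULOS hours 1..stay.
#' @param truth Ground-truth data frame with `patient_id`, `is_septic`,
#'   `onset_hour`.
#' @param params A [utility_params()].
#' @return List with `normalized`, and the raw totals `total`, `optimal`,
#'   `all_negative`.
#' @export
#' @examples
#' truth <- data.frame(patient_id = "a", is_septic = TRUE, onset_hour = 20)
#' pred <- list(a = as.integer(seq_len(30) >= 14))
#' utility_score(pred, truth)$normalized  # 1
utility_score <- function(predictions, truth, params = utility_params()) {
  ids <- truth$patient_id
  missing <- setdiff(ids, names(predictions))
  if (length(missing)) stopf("no predictions for patient(s): %s",
                             paste(head(missing, 3), collapse = ", "))
  total <- 0; optimal <- 0; allneg <- 0
  for (i in seq_along(ids)) {
    pred <- predictions[[ids[i]]]
    onset <- if (isTRUE(as.logical(truth$is_septic[i])))
      as.integer(truth$onset_hour[i]) else NA_integer_
    stay <- length(pred)
    total <- total + patient_utility(pred, onset, params)
    optimal <- optimal + patient_utility(ideal_predictions(stay, onset, params),
                                         onset, params)
    allneg <- allneg + patient_utility(integer(stay), onset, params)
  }
  if (optimal == allneg)
    stopf("degenerate normalization: ideal and all-negative utilities coincide")
  list(normalized = (total - allneg) / (optimal - allneg),
       total = total, optimal = optimal, all_negative = allneg)
}

#' Expand an alarm trace into hourly binary predictions
#'
#' Converts an alert (or, optionally, warnings) into the latched hourly 0/1
#' prediction vector the utility score consumes: 0 until the alarm fires,
#' 1 from that hour to the end of the stay.
#'
#' @param trace An [alarm_trace()].
#' @param stay Stay length in hours.
#' @param use One of `"alert"` (default) or `"warning"` (latch at the first
#'   warning instead).
#' @return Integer 0/1 vector of length `stay`.
#' @export
trace_to_predictions <- function(trace, stay, use = c("alert", "warning")) {
  use <- match.arg(use)
  fire <- if (use == "alert") trace$alert_hour
          else if (length(trace$warning_hours)) trace$warning_hours[1]
          else NA_integer_
  pred <- integer(stay)
  if (!is.na(fire) && fire <= stay) pred[fire:stay] <- 1L
  pred
}
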