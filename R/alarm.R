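# Warning/alert logic: isolated threshold crossings become warnings; an
# alert fires only when x warnings accumulate inside a trailing w-hour
# window, which is what suppresses alarm-fatigue-inducing false positives.

#' Alarm policy
#'
#' @param probability_threshold Probability above which an hour raises a
#'   warning (strictly greater than; default 0.5).
#' @param x Warnings required inside the window to raise an alert
#'   (default 3).
#' @param w Trailing window length in hours (default 5).
#' @return An `alarm_policy` list.
#' @export
alarm_policy <- function(probability_threshold = 0.5, x = 3, w = 5) {
  if (!is.numeric(probability_threshold) || probability_threshold <= 0 ||
      probability_threshold >= 1)
    stopf("probability_threshold must lie strictly in (0, 1)")
  if (!is_count(x) || !is_count(w) || x > w)
    stopf("need integer warnings x and window w with 1 <= x <= w")
  structure(list(probability_threshold = probability_threshold,
                 x = as.integer(x), w = as.integer(w)),
            class = "alarm_policy")
}

#' Hours whose probability crosses the warning threshold
#'
#' A warning is raised at every hour whose sepsis probability strictly
#' exceeds the threshold (ties at exactly the threshold do not warn).
#'
#' @param probabilities Per-hour probability stream in \[0, 1\]; its `hours`
#'   attribute (set by [predict_patient()] and
#'   [inject_probability_stream()]) gives each entry's clock hour, else
#'   hours are assumed to start at `start_hour`.
#' @param policy An [alarm_policy()].
#' @param start_hour Clock hour of the first probability when no `hours`
#'   attribute is present (default 4, the first hour a full window exists).
#' @return Sorted integer vector of warning hours.
#' @export
#' @examples
#' detect_warnings(c(0.2, 0.6, 0.5, 0.9), alarm_policy(), start_hour = 1)
detect_warnings <- function(probabilities, policy = alarm_policy(),
                            start_hour = 4L) {
  p <- as.numeric(probabilities)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("probabilities must lie in [0, 1]")
  hours <- attr(probabilities, "hours") %||%
    seq.int(start_hour, length.out = length(p))
  as.integer(hours[p > policy$probability_threshold])
}

#' First hour at which the alert criterion is met
#'
#' Scans clock hours in order and fires at the earliest hour `t` such that
#' at least `x` warnings fall in the inclusive trailing window
#' `[t - w + 1, t]`. The alarm latches: only the first alert is reported.
#' The window slides over clock hours, so gaps in the prediction stream
#' still age warnings out.
#'
#' @param warning_hours Integer warning hours from [detect_warnings()].
#' @param policy An [alarm_policy()].
#' @return The alert hour, or `NA` if the criterion is never met.
#' @export
#' @examples
#' detect_alert(c(1, 3, 5), alarm_policy(x = 3, w = 5))   # 5
#' detect_alert(c(1, 7, 13), alarm_policy(x = 3, w = 5))  # NA: isolated
detect_alert <- function(warning_hours, policy = alarm_policy()) {
  wh <- sort(unique(as.integer(warning_hours)))
  if (length(wh) < policy$x) return(NA_integer_)
  # The earliest qualifying hour is always a warning hour, so scanning the
  # window ending at each warning suffices.
  for (k in seq_along(wh)) {
    t <- wh[k]
    if (sum(wh >= t - policy$w + 1L & wh <= t) >= policy$x) return(t)
  }
  NA_integer_
}

#' Full alarm trace for one probability stream
#'
#' @param probabilities Per-hour probability stream (see
#'   [detect_warnings()]).
#' @param policy An [alarm_policy()].
#' @param patient_id Optional identifier carried on the trace.
#' @param start_hour Clock hour of the first probability if the stream has
#'   no `hours` attribute.
#' @return An `alarm_trace`: list with `patient_id`, `hours`,
#'   `probabilities`, `warning_hours`, `alert_hour`.
#' @export
alarm_trace <- function(probabilities, policy = alarm_policy(),
                        patient_id = NA_character_, start_hour = 4L) {
  hours <- attr(probabilities, "hours") %||%
    seq.int(start_hour, length.out = length(probabilities))
  warnings <- detect_warnings(probabilities, policy, start_hour)
  structure(
    list(patient_id = patient_id, hours = as.integer(hours),
         probabilities = as.numeric(probabilities),
         warning_hours = warnings,
         alert_hour = detect_alert(warnings, policy)),
    class = "alarm_trace"
  )
}

#' @export
print.alarm_trace <- function(x, ...) {
  cat(sprintf("<alarm_trace %s>  hours %d-%d, %d warnings, %s\n",
              x$patient_id, min(x$hours), max(x$hours),
              length(x$warning_hours),
              if (is.na(x$alert_hour)) "no alert"
              else sprintf("alert at hour %d", x$alert_hour)))
  invisible(x)
}

#' Warning and alert lookahead relative to true onset
#'
#' Hours between the true sepsis onset and the first warning / the alert;
#' positive values mean the alarm came early, negative late, `NA` that it
#' never fired.
#'
#' @param trace An [alarm_trace()].
#' @param truth One-row ground-truth slice with `is_septic` and
#'   `onset_hour`.
#' @return List with `warning_lookahead` and `alert_lookahead` (hours).
#' @export
lookahead <- function(trace, truth) {
  if (!isTRUE(as.logical(truth$is_septic)))
    stopf("lookahead is defined only for septic patients")
  onset <- as.integer(truth$onset_hour)
  list(
    warning_lookahead = if (length(trace$warning_hours))
      onset - trace$warning_hours[1] else NA_integer_,
    alert_lookahead = if (!is.na(trace$alert_hour))
      onset - trace$alert_hour else NA_integer_
  )
}

#' Patient-level performance over a grid of alarm policies
#'
#' Re-derives warnings and alerts from the stored probability streams for
#' every `(x, w)` pair and evaluates the patient-level confusion (positive =
#' the alert fired anywhere in the stay) against ground truth.
#'
#' @param traces List of [alarm_trace()]s (one per patient; their stored
#'   probabilities are re-thresholded).
#' @param truth Ground-truth data frame (`patient_id`, `is_septic`).
#' @param x_grid Integer vector of warning-count thresholds.
#' @param w_grid Integer vector of window lengths.
#' @param probability_threshold Warning threshold (default 0.5).
#' @return Data frame with one row per valid `(x, w)` pair (x <= w):
#'   confusion counts, sensitivity, specificity, accuracy and
#'   false-alarm ratio.
#' @export
sweep_policy <- function(traces, truth, x_grid = 1:5, w_grid = 2:8,
                         probability_threshold = 0.5) {
  if (!length(traces) || !nrow(truth)) stopf("empty cohort")
  if (!length(x_grid) || !length(w_grid)) stopf("empty policy grid")
  ids <- vapply(traces, `[[`, character(1), "patient_id")
  septic <- setNames(truth$is_septic, truth$patient_id)[ids]
  rows <- list()
  for (w in sort(unique(as.integer(w_grid)))) {
    for (x in sort(unique(as.integer(x_grid)))) {
      if (x > w) next
      policy <- alarm_policy(probability_threshold, x, w)
      alerted <- vapply(traces, function(tr) {
        p <- tr$probabilities
        attr(p, "hours") <- tr$hours
        !is.na(detect_alert(detect_warnings(p, policy), policy))
      }, logical(1))
      cts <- confusion_counts(as.integer(alerted), as.integer(septic))
      rows[[length(rows) + 1L]] <- data.frame(
        x = x, w = w, tp = cts$tp, fp = cts$fp, tn = cts$tn, fn = cts$fn,
        n_alerts = sum(alerted),
        sensitivity = binary_rate(cts$tp, cts$tp + cts$fn),
        specificity = binary_rate(cts$tn, cts$tn + cts$fp),
        accuracy = (cts$tp + cts$tn) / length(alerted),
        far = false_alarm_ratio(cts)
      )
    }
  }
  do.call(rbind, rows)
}
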