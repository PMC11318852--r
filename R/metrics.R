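# Time-level and patient-level evaluation metrics.

binary_rate <- function(num, den) if (den > 0) num / den else NA_real_

#' Confusion counts
#'
#' @param predictions Binary 0/1 vector (per hour, or per patient where
#'   "positive" means an alert fired anywhere in the stay).
#' @param truths Binary 0/1 vector of the same length.
#' @return A `confusion_counts` list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stopf("predictions and truths must align (%d vs %d)",
          length(predictions), length(truths))
  p <- as.integer(predictions); y <- as.integer(truths)
  if (!all(p %in% 0:1) || !all(y %in% 0:1))
    stopf("predictions and truths must be binary")
  structure(list(tp = sum(p == 1L & y == 1L), fp = sum(p == 1L & y == 0L),
                 tn = sum(p == 0L & y == 0L), fn = sum(p == 0L & y == 1L)),
            class = "confusion_counts")
}

#' False-alarm ratio
#'
#' `FP / (TP + FP) * 100`, the percentage of raised alarms that were false —
#' the complement of positive predictive value in percent. When no alarm
#' was raised at all (TP + FP = 0) the ratio is defined as 0.
#'
#' @param counts A [confusion_counts()] (or list with `tp`, `fp`).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' false_alarm_ratio(list(tp = 3, fp = 1))  # 25
false_alarm_ratio <- function(counts) {
  tp <- counts$tp; fp <- counts$fp
  if (tp + fp == 0) return(0)
  100 * fp / (tp + fp)
}

#' Threshold-free ranking metrics
#'
#' AUROC via the trapezoidal rule with midrank tie handling (equivalently
#' the Wilcoxon statistic: the probability a random positive outscores a
#' random negative, ties counting one half), and AUPRC via step
#' interpolation over descending unique score thresholds.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return List with `auroc` and `auprc`.
#' @export
ranking_metrics <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(scores) != length(y)) stopf("scores and labels must align")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)  # midranks for ties
  auroc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1L - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  auprc <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, auprc = auprc)
}

#' Median and interquartile lookahead summary
#'
#' Summarizes warning and alert lookaheads over the septic patients; alarms
#' that never fired (`NA` lookahead) are reported separately as missed, and
#' negative lookaheads (fired after onset) as late.
#'
#' @param lookaheads Numeric vector of per-patient lookaheads in hours
#'   (positive = early, `NA` = never fired).
#' @return List with `n`, `n_missed`, `n_late`, `median`, `q1`, `q3`.
#' @export
lookahead_summary <- function(lookaheads) {
  if (!length(lookaheads)) stopf("no septic patients to summarize")
  fired <- lookaheads[!is.na(lookaheads)]
  if (!length(fired))
    return(list(n = length(lookaheads), n_missed = length(lookaheads),
                n_late = 0L, median = NA_real_, q1 = NA_real_,
                q3 = NA_real_))
  q <- quantile(fired, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(lookaheads),
       n_missed = sum(is.na(lookaheads)),
       n_late = sum(fired < 0),
       median = q[2], q1 = q[1], q3 = q[3])
}

#' Positive count for a prevalence-matched test set
#'
#' Number of positive patients to pair with `negatives` negatives so the
#' set reflects a target disease prevalence:
#' `round(negatives * prevalence / (1 - prevalence))`.
#'
#' @param negatives Count of negative patients.
#' @param prevalence Target prevalence, strictly in (0, 1).
#' @return Integer count of positives.
#' @export
#' @examples
#' prevalence_testset(432, 0.072)  # 34
prevalence_testset <- function(negatives, prevalence) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must lie strictly in (0, 1)")
  if (negatives < 0) stopf("negatives must be a non-negative count")
  as.integer(round(negatives * prevalence / (1 - prevalence)))
}

#' Assemble an evaluation report
#'
#' Derives the standard metric set from confusion counts, optionally adding
#' ranking metrics, the false-alarm ratio, the normalized utility and a
#' lookahead summary.
#'
#' @param counts A [confusion_counts()].
#' @param level `"time"` or `"patient"`.
#' @param scores,labels Optional scores + labels for AUROC/AUPRC.
#' @param utility Optional normalized utility value to attach.
#' @param lookaheads Optional per-patient alert lookaheads to summarize.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(counts, level = c("time", "patient"),
                              scores = NULL, labels = NULL, utility = NULL,
                              lookaheads = NULL) {
  level <- match.arg(level)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stopf("empty confusion counts")
  rep <- list(
    level = level, counts = counts,
    sensitivity = binary_rate(tp, tp + fn),
    specificity = binary_rate(tn, tn + fp),
    accuracy = (tp + tn) / total,
    ppv = binary_rate(tp, tp + fp),
    npv = binary_rate(tn, tn + fn),
    f1 = binary_rate(2 * tp, 2 * tp + fp + fn),
    far = false_alarm_ratio(counts)
  )
  if (!is.null(scores)) {
    rm_ <- ranking_metrics(scores, labels)
    rep$auroc <- rm_$auroc
    rep$auprc <- rm_$auprc
  }
  if (!is.null(utility)) rep$utility <- utility
  if (!is.null(lookaheads)) rep$lookahead <- lookahead_summary(lookaheads)
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %s level>\n", x$level))
  cat(sprintf("  tp %d | fp %d | tn %d | fn %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  fmt_pct <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("  sensitivity %s  specificity %s  accuracy %s\n",
              fmt_pct(x$sensitivity), fmt_pct(x$specificity),
              fmt_pct(x$accuracy)))
  cat(sprintf("  PPV %s  NPV %s  F1 %s  false-alarm ratio %.2f%%\n",
              fmt_pct(x$ppv), fmt_pct(x$npv), fmt_pct(x$f1), x$far))
  if (!is.null(x$auroc))
    cat(sprintf("  AUROC %.3f  AUPRC %.3f\n", x$auroc, x$auprc))
  if (!is.null(x$utility))
    cat(sprintf("  normalized utility %.3f\n", x$utility))
  if (!is.null(x$lookahead) && !is.na(x$lookahead$median))
    cat(sprintf("  alert lookahead median %g h (IQR %g-%g), %d missed\n",
                x$lookahead$median, x$lookahead$q1, x$lookahead$q3,
                x$lookahead$n_missed))
  invisible(x)
}
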