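# Confusion counts, false-alarm ratio, ranking metrics, the normalized
# utility score, lookahead summaries and prevalence arithmetic.

test_that("confusion counts enumerate a hand-built cohort correctly", {
  # 2 septic (1 alerted), 2 non-septic (1 alerted)
  cts <- confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cts)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  perfect <- confusion_counts(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perfect$fp + perfect$fn, 0)
  allneg <- confusion_counts(rep(0, 4), c(1, 0, 1, 0))
  expect_equal(allneg$tp + allneg$fp, 0)
  expect_error(confusion_counts(1, c(1, 0)), "align")
  expect_error(confusion_counts(2, 1), "binary")
})

test_that("the false-alarm ratio follows FP/(TP+FP)x100 with 0/0 -> 0", {
  expect_equal(false_alarm_ratio(list(tp = 3, fp = 1)), 25.0)
  expect_equal(false_alarm_ratio(list(tp = 5, fp = 0)), 0.0)
  expect_equal(false_alarm_ratio(list(tp = 0, fp = 5)), 100.0)
  expect_equal(false_alarm_ratio(list(tp = 0, fp = 0)), 0.0)
})

test_that("FAR is the complement of PPV in percent whenever alarms were raised", {
  set.seed(10)
  for (i in 1:50) {
    pred <- rbinom(40, 1, 0.4)
    y <- rbinom(40, 1, 0.3)
    cts <- confusion_counts(pred, y)
    if (cts$tp + cts$fp > 0) {
      rep_ <- evaluation_report(cts, "patient")
      expect_equal(rep_$far + 100 * rep_$ppv, 100, tolerance = 1e-12)
    }
  }
})

test_that("AUROC matches the pairwise brute-force oracle including ties", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    rm_ <- ranking_metrics(scores, y)
    expect_equal(rm_$auroc, brute_force_auroc(scores, y), tolerance = 1e-9)
  }
})

test_that("perfect separation gives AUROC 1 and random scores hover near 0.5", {
  y <- rep(c(0, 1), each = 50)
  s <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  expect_equal(ranking_metrics(s, y)$auroc, 1.0)

  set.seed(3)
  y <- rbinom(4000, 1, 0.5)
  s <- runif(4000)
  expect_lt(abs(ranking_metrics(s, y)$auroc - 0.5), 0.03)
  expect_error(ranking_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("AUPRC equals hand-computed step areas on tiny instances", {
  # scores descending: labels 1,0,1 -> precision at recall steps: 1/1, 2/3
  expect_equal(ranking_metrics(c(3, 2, 1), c(1, 0, 1))$auprc,
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(ranking_metrics(c(3, 2, 1), c(1, 1, 0))$auprc, 1.0)
})

test_that("the reference early predictor scores exactly 1 and all-negative exactly 0", {
  cohort <- small_cohort()
  truth <- cohort$truth
  stays <- vapply(cohort$records, function(r) nrow(r$values), numeric(1))
  optimal <- lapply(seq_len(nrow(truth)), function(i) {
    pred <- integer(stays[[truth$patient_id[i]]])
    if (truth$is_septic[i])
      pred[seq_along(pred) >= max(1, truth$onset_hour[i] - 6)] <- 1L
    pred
  })
  names(optimal) <- truth$patient_id
  expect_equal(utility_score(optimal, truth)$normalized, 1.0)

  allneg <- lapply(optimal, function(p) integer(length(p)))
  expect_equal(utility_score(allneg, truth)$normalized, 0.0)
})

test_that("one false-positive hour on an optimal predictor costs exactly u_fp", {
  truth <- data.frame(patient_id = c("a", "b"),
                      is_septic = c(TRUE, FALSE), onset_hour = c(20, NA))
  pred <- list(a = as.integer(seq_len(30) >= 14), b = integer(25))
  base <- utility_score(pred, truth)
  expect_equal(base$normalized, 1.0)
  pred$b[10] <- 1L
  perturbed <- utility_score(pred, truth)
  expect_lt(perturbed$normalized, 1.0)
  expect_equal(perturbed$total, base$total - 0.05)
  # hand check of the raw anchors for the septic patient:
  # ramp-down rewards at hours 14..23 sum to (9+8+...+0)/9 = 5
  expect_equal(base$optimal, 5.0)
})

test_that("random predictors never beat the reference and missed onsets are penalized", {
  cohort <- small_cohort()
  truth <- cohort$truth
  stays <- vapply(cohort$records, function(r) nrow(r$values), numeric(1))
  set.seed(8)
  for (i in 1:20) {
    pred <- lapply(truth$patient_id,
                   function(id) rbinom(stays[[id]], 1, runif(1, 0, 0.5)))
    names(pred) <- truth$patient_id
    expect_lte(utility_score(pred, truth)$normalized, 1.0)
  }
  # an all-positive predictor is punished below 0 by false-positive hours
  allpos <- lapply(truth$patient_id, function(id) rep(1L, stays[[id]]))
  names(allpos) <- truth$patient_id
  expect_lt(utility_score(allpos, truth)$normalized, 1.0)
})

test_that("utility errors on degenerate normalization and missing patients", {
  truth <- data.frame(patient_id = "a", is_septic = FALSE, onset_hour = NA)
  expect_error(utility_score(list(a = integer(10)), truth), "degenerate")
  truth2 <- data.frame(patient_id = c("a", "b"), is_septic = c(TRUE, FALSE),
                       onset_hour = c(10, NA))
  expect_error(utility_score(list(a = integer(12)), truth2), "no predictions")
})

test_that("alarm traces expand to latched hourly predictions", {
  p <- rep(0.9, 6)
  attr(p, "hours") <- 4:9
  tr <- alarm_trace(p, alarm_policy())
  expect_equal(tr$alert_hour, 6L)
  expect_equal(trace_to_predictions(tr, 10), c(0, 0, 0, 0, 0, rep(1, 5)))
  expect_equal(trace_to_predictions(tr, 10, use = "warning"),
               c(0, 0, 0, rep(1, 7)))
  quiet <- alarm_trace(rep(0.1, 6), alarm_policy())
  expect_equal(trace_to_predictions(quiet, 8), integer(8))
})

test_that("lookahead summaries agree with a sorting-based oracle", {
  expect_equal(lookahead_summary(c(2, 4, 6))$median, 4)
  s <- lookahead_summary(c(NA, NA, 3))
  expect_equal(s$n_missed, 2L)
  allmiss <- lookahead_summary(c(NA_real_, NA_real_))
  expect_equal(allmiss$n_missed, 2L)
  expect_true(is.na(allmiss$median))

  set.seed(12)
  for (i in 1:20) {
    las <- sample(-5:30, sample(3:15, 1), replace = TRUE)
    s <- lookahead_summary(las)
    expect_equal(s$median, median(las))
    expect_equal(s$q1, sort(unname(quantile(las, 0.25))))
    expect_equal(s$n_late, sum(las < 0))
  }
  expect_error(lookahead_summary(numeric(0)), "no septic")
})

test_that("prevalence-matched test sets use round(neg * p / (1 - p))", {
  expect_equal(prevalence_testset(432, 0.072), 34L)
  expect_equal(prevalence_testset(100, 0.5), 100L)
  expect_equal(prevalence_testset(0, 0.3), 0L)
  expect_error(prevalence_testset(10, 1), "strictly in")
})
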