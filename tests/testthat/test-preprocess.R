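# Exclusion rules, label shifting, sample-and-hold, min-max rescaling,
# feature selection, windows and undersampling.

test_that("exclusion rules drop short stays and early onsets, truncate at 336h", {
  short <- toy_record(7, list(HR = rep(80, 7)), id = "short")
  early <- toy_record(10, list(HR = rep(80, 10)),
                      label = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1), id = "early")
  long <- toy_record(400, list(HR = rep(80, 400)), id = "long")
  ok <- toy_record(12, list(HR = rep(80, 12)), id = "ok")
  out <- apply_exclusions(list(short, early, long, ok))
  expect_setequal(names(out$records), c("long", "ok"))
  expect_equal(nrow(out$records$long$values), 336)
  expect_length(out$records$long$iculos, 336)
  expect_equal(out$log$reason[out$log$patient_id == "short"], "stay<8h")
  expect_equal(out$log$reason[out$log$patient_id == "early"], "onset<4h")
})

test_that("label shifting extends the positive block by the lookahead, clamped at hour 1", {
  rec <- toy_record(30, list(HR = rep(80, 30)),
                    label = c(rep(0, 19), rep(1, 11)))  # onset 20
  tg <- shift_labels(rec, 6)
  expect_equal(which(tg == 1)[1], 14)
  expect_true(all(tg[14:30] == 1) && all(tg[1:13] == 0))

  rec4 <- toy_record(10, list(HR = rep(80, 10)),
                     label = c(0, 0, 0, rep(1, 7)))  # onset 4
  expect_equal(shift_labels(rec4, 6), rep(1L, 10))

  neg <- toy_record(10, list(HR = rep(80, 10)))
  expect_equal(shift_labels(neg, 6), rep(0L, 10))
})

test_that("shifting preserves monotonicity and adds exactly min(lookahead, H-1) positives", {
  for (onset in c(2, 5, 9, 25)) {
    stay <- 30
    lab <- as.integer(seq_len(stay) >= onset)
    rec <- toy_record(stay, list(HR = rep(80, stay)), label = lab)
    tg <- shift_labels(rec, 6)
    expect_true(all(diff(tg) >= 0))
    expect_equal(sum(tg) - sum(lab), min(6, onset - 1))
  }
})

test_that("sample-and-hold respects the hold limits and the -1 sentinel", {
  # HR (hold 4): observed 80 at hour 1, missing 2-7
  rec <- toy_record(7, list(HR = c(80, rep(NA, 6))))
  out <- impute_sample_hold(rec, imputation_policy())
  expect_equal(out$values[, "HR"], c(80, 80, 80, 80, 80, -1, -1))

  # lab (hold 24): observed at hour 1 of a 30-hour stay
  rec <- toy_record(30, list(WBC = c(9, rep(NA, 29))))
  out <- impute_sample_hold(rec, imputation_policy())
  expect_equal(out$values[, "WBC"], c(rep(9, 25), rep(-1, 5)))

  # fully missing parameter -> all sentinel
  expect_true(all(out$values[, "Lactate"] == -1))
})

test_that("sample-and-hold matches a per-cell oracle, is idempotent, never edits observations", {
  set.seed(42)
  policy <- imputation_policy()
  for (rep_i in 1:20) {
    n <- sample(5:40, 1)
    col_v <- ifelse(runif(n) < 0.6, NA, round(runif(n, 60, 100), 1))
    col_l <- ifelse(runif(n) < 0.9, NA, round(runif(n, 5, 15), 1))
    rec <- toy_record(n, list(HR = col_v, WBC = col_l))
    out <- impute_sample_hold(rec, policy)
    expect_equal(out$values[, "HR"], brute_force_hold(col_v, 4))
    expect_equal(out$values[, "WBC"], brute_force_hold(col_l, 24))
    # observed cells unaltered
    expect_equal(out$values[, "HR"][!is.na(col_v)], col_v[!is.na(col_v)])
    # idempotent
    expect_identical(impute_sample_hold(out, policy)$values, out$values)
  }
})

test_that("min-max rescale maps limits to [1,5], midpoint to 3, missing to -1, truncates outliers", {
  lim <- c(30, 180)
  expect_equal(normalize_minmax(30, lim), 1)
  expect_equal(normalize_minmax(180, lim), 5)
  expect_equal(normalize_minmax(105, lim), 3)
  expect_equal(normalize_minmax(NA, lim), -1)
  expect_equal(normalize_minmax(190, lim), 5)
  expect_equal(normalize_minmax(-10, lim), 1)
  expect_error(normalize_minmax(1, c(5, 5)), "degenerate")
})

test_that("rescaling is monotone with image in {-1} union [1,5]", {
  set.seed(7)
  for (i in 1:10) {
    lim <- sort(runif(2, -50, 200))
    if (diff(lim) < 1) next
    x <- sort(runif(50, lim[1] - 20, lim[2] + 20))
    y <- normalize_minmax(x, lim)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y >= 1 & y <= 5))
  }
})

test_that("feature selection drops rarely-present parameters and keeps the 17-parameter raw set", {
  cohort <- small_cohort()
  sel <- select_features(cohort$records)
  # parameters present in only ~15% of patients exceed the 80% rule
  expect_true(all(c("TroponinI", "Fibrinogen") %in% sel$dropped))
  expect_false(any(c("HR", "WBC") %in% sel$dropped))
  expect_length(sel$selected, 17)

  # explicit threshold arithmetic: present in 15% of patients -> dropped,
  # present in 25% -> retained (probes outside the selected set so the
  # selected parameters stay intact)
  selected_tv <- setdiff(feature_config()$selected_raw, c("Age", "Gender"))
  recs <- lapply(1:20, function(i) {
    obs <- setNames(lapply(selected_tv, function(p) rep(50, 10)), selected_tv)
    if (i <= 3) obs$AST <- rep(30, 10)   # 15% of patients
    if (i <= 5) obs$Hgb <- rep(11, 10)   # 25% of patients
    toy_record(10, obs, id = sprintf("r%02d", i))
  })
  sel2 <- select_features(recs, max_missing_fraction = 0.80,
                          config = feature_config())
  expect_true("AST" %in% sel2$dropped)
  expect_false("Hgb" %in% sel2$dropped)
  # and a selected parameter that vanished from the cohort is a hard error
  gone <- lapply(recs, function(r) { r$values[, "Lactate"] <- NA; r })
  expect_error(select_features(gone, 0.80, feature_config()),
               "removed by the 80% missingness rule")
})

test_that("the assembled feature matrix is 17 raw + 4 derived = 21 columns", {
  rec <- small_cohort()$records[[1]]
  held <- impute_sample_hold(rec, imputation_policy(fill_value = NA))
  raw <- build_feature_matrix(held)
  expect_equal(ncol(raw), 21)
  expect_equal(colnames(raw)[18:21],
               c("ShockIndex", "BUN_CR_Ratio", "MEWS", "pSOFA"))
  norm <- normalize_features(raw)
  expect_true(all(norm == -1 | (norm >= 1 & norm <= 5)))
})

test_that("imputation more than halves missingness on the selected parameters", {
  cohort <- small_cohort()
  sel_tv <- setdiff(feature_config()$selected_raw, c("Age", "Gender"))
  frac_missing <- function(recs)
    mean(unlist(lapply(recs, function(r) is.na(r$values[, sel_tv]))))
  raw <- frac_missing(cohort$records)
  held <- lapply(cohort$records, impute_sample_hold,
                 policy = imputation_policy(fill_value = NA))
  expect_lt(frac_missing(held), raw / 2)
})

test_that("window construction yields stay-3 windows of shape 4x21 in the sentinel range", {
  rec <- small_cohort()$records[[1]]
  proc <- preprocess_record(rec)
  wins <- build_windows(proc)
  expect_length(wins, nrow(proc$features) - 3)
  expect_equal(wins[[1]]$end_hour, 4)
  expect_equal(dim(wins[[1]]$matrix), c(4, 21))
  expect_true(all(vapply(wins, function(w)
    all(w$matrix == -1 | (w$matrix >= 1 & w$matrix <= 5)), logical(1))))

  ten <- toy_record(10, list(HR = rep(80, 10)))
  expect_length(build_windows(preprocess_record(ten)), 7)
  short <- toy_record(3, list(HR = rep(80, 3)))
  expect_error(build_windows(preprocess_record(short)), "shorter than")
})

test_that("undersampling keeps all positives and draws ratio x negatives from many patients", {
  cohort <- small_cohort()
  procs <- lapply(cohort$records, preprocess_record)
  wins <- unlist(lapply(procs, build_windows), recursive = FALSE)
  targets <- vapply(wins, `[[`, numeric(1), "target")
  n_pos <- sum(targets == 1)
  expect_gt(n_pos, 0)

  bal1 <- undersample_negatives(wins, 1.0, seed = 3)
  t1 <- vapply(bal1, `[[`, numeric(1), "target")
  expect_equal(sum(t1 == 1), n_pos)
  expect_equal(sum(t1 == 0), n_pos)

  bal2 <- undersample_negatives(wins, 2.0, seed = 3)
  expect_equal(sum(vapply(bal2, `[[`, numeric(1), "target") == 0), 2 * n_pos)

  # reproducible, and heterogeneous across negative patients
  expect_identical(undersample_negatives(wins, 1.0, seed = 3), bal1)
  neg_patients <- unique(vapply(wins[targets == 0], `[[`, character(1),
                                "patient_id"))
  kept_patients <- unique(vapply(bal1[t1 == 0], `[[`, character(1),
                                 "patient_id"))
  expect_gte(length(kept_patients), length(neg_patients) / 2)

  expect_error(undersample_negatives(wins[targets == 0], 1, 1),
               "no positive windows")
})
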