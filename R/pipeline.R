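# End-to-end orchestration: generate -> preprocess -> train -> predict ->
# alarm -> evaluate -> compare, with versioned text artifacts per stage and
# a single global seed fanned out deterministically to the stages.

#' Pipeline run configuration
#'
#' One global seed deterministically derives the per-stage seeds (cohort
#' generation, cohort split, undersampling, model initialization), so a
#' whole run is reproducible from this object alone.
#'
#' @param output_dir Directory for run artifacts.
#' @param cohort A [cohort_config()] (its seed is overridden by the fanned-out
#'   stage seed).
#' @param model A [model_config()].
#' @param alarm A [alarm_policy()].
#' @param utility A [utility_params()].
#' @param features A [feature_config()].
#' @param test_fraction,train_fraction_of_rest Patient-level split
#'   proportions (defaults 0.15 and 0.80).
#' @param stratify_split Stratify the split by sepsis status (default FALSE).
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir = tempfile("sepsiswatch_run_"),
                       cohort = cohort_config(),
                       model = model_config(),
                       alarm = alarm_policy(),
                       utility = utility_params(),
                       features = feature_config(),
                       test_fraction = 0.15, train_fraction_of_rest = 0.80,
                       stratify_split = FALSE, seed = 1L) {
  cohort$seed <- derive_seed(seed, 1L)
  model$seed <- derive_seed(seed, 2L)
  structure(list(output_dir = output_dir, cohort = cohort, model = model,
                 alarm = alarm, utility = utility, features = features,
                 test_fraction = test_fraction,
                 train_fraction_of_rest = train_fraction_of_rest,
                 stratify_split = isTRUE(stratify_split),
                 seed = as.integer(seed),
                 split_seed = derive_seed(seed, 3L),
                 undersample_seed = derive_seed(seed, 4L)),
            class = "run_config")
}

PIPELINE_STAGES <- c("generate", "preprocess", "train", "predict", "alarm",
                     "evaluate", "compare")

need_stage <- function(state, field, stage, prerequisite) {
  if (is.null(state[[field]]))
    stopf("stage '%s' requires the '%s' stage to have run first",
          stage, prerequisite)
  state[[field]]
}

#' Run the pipeline
#'
#' Executes the requested stages in canonical order, threading results
#' through `state` and writing plain-text artifacts (PSV cohort, exclusion
#' log, training history, per-patient traces, JSON evaluation summary)
#' under `config$output_dir`.
#'
#' @param config A [run_config()].
#' @param stages Ordered subset of
#'   `c("generate", "preprocess", "train", "predict", "alarm", "evaluate",
#'   "compare")`; defaults to all.
#' @param state Optional state list from a previous partial run.
#' @return The updated state (invisibly): cohort, processed records, model,
#'   traces, and `summary` (the evaluation reports).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, state = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  state <- state %||% list()
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  for (stage in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    state <- switch(stage,
      generate = stage_generate(config, state),
      preprocess = stage_preprocess(config, state),
      train = stage_train(config, state),
      predict = stage_predict(config, state),
      alarm = stage_alarm(config, state),
      evaluate = stage_evaluate(config, state),
      compare = stage_compare(config, state)
    )
  }
  invisible(state)
}

stage_generate <- function(config, state) {
  cohort <- generate_cohort(config$cohort)
  write_cohort(cohort$records, file.path(config$output_dir, "cohort"),
               truth = cohort$truth)
  state$cohort <- cohort
  state
}

stage_preprocess <- function(config, state) {
  cohort <- need_stage(state, "cohort", "preprocess", "generate")
  excl <- apply_exclusions(cohort$records)
  utils::write.table(excl$log,
                     file.path(config$output_dir, "exclusion_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sel <- select_features(excl$records, config$features$max_missing_fraction,
                         config$features)
  truth <- cohort$truth[cohort$truth$patient_id %in% names(excl$records), ]
  split <- split_cohort(excl$records, config$test_fraction,
                        config$train_fraction_of_rest,
                        seed = config$split_seed,
                        stratify_by = if (config$stratify_split)
                          truth$is_septic[match(names(excl$records),
                                                truth$patient_id)])
  processed <- lapply(excl$records, preprocess_record, config = config$features)
  nh <- config$features$window_hours
  long_enough <- function(ids)
    ids[vapply(ids, function(id) nrow(processed[[id]]$features) >= nh,
               logical(1))]
  train_windows <- unlist(lapply(long_enough(split$train_ids), function(id)
    build_windows(processed[[id]], nh, config$features$window_stride)),
    recursive = FALSE)
  train_windows <- undersample_negatives(train_windows,
                                         config$features$undersample_ratio,
                                         seed = config$undersample_seed)
  state$exclusions <- excl$log
  state$selection <- sel
  state$truth <- truth
  state$split <- split
  state$processed <- processed
  state$train_windows <- train_windows
  state
}

stage_train <- function(config, state) {
  windows <- need_stage(state, "train_windows", "train", "preprocess")
  model <- train_sepsis_model(windows, config$model)
  utils::write.table(
    data.frame(epoch = seq_along(model$history), loss = model$history),
    file.path(config$output_dir, "training_history.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  state$model <- model
  state
}

stage_predict <- function(config, state) {
  model <- need_stage(state, "model", "predict", "train")
  split <- need_stage(state, "split", "predict", "preprocess")
  nh <- config$features$window_hours
  test_ids <- split$test_ids[vapply(split$test_ids, function(id)
    nrow(state$processed[[id]]$features) >= nh, logical(1))]
  state$probabilities <- lapply(
    setNames(test_ids, test_ids),
    function(id) predict_patient(model, state$processed[[id]], nh))
  state
}

stage_alarm <- function(config, state) {
  probs <- need_stage(state, "probabilities", "alarm", "predict")
  state$traces <- lapply(names(probs), function(id)
    alarm_trace(probs[[id]], config$alarm, patient_id = id))
  names(state$traces) <- names(probs)
  trace_rows <- do.call(rbind, lapply(state$traces, function(tr)
    data.frame(patient_id = tr$patient_id, hour = tr$hours,
               probability = tr$probabilities,
               warning = tr$hours %in% tr$warning_hours,
               alert = !is.na(tr$alert_hour) & tr$hours == tr$alert_hour)))
  utils::write.table(trace_rows,
                     file.path(config$output_dir, "alarm_traces.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state
}

stage_evaluate <- function(config, state) {
  traces <- need_stage(state, "traces", "evaluate", "alarm")
  truth <- state$truth
  ids <- names(traces)
  truth_t <- truth[match(ids, truth$patient_id), ]

  # Time level: hourly probabilities against the shifted targets.
  scores <- unlist(lapply(ids, function(id) state$probabilities[[id]]))
  hour_targets <- unlist(lapply(ids, function(id) {
    proc <- state$processed[[id]]
    proc$targets[attr(state$probabilities[[id]], "hours")]
  }))
  thr <- config$alarm$probability_threshold
  time_report <- evaluation_report(
    confusion_counts(as.integer(scores > thr), hour_targets),
    "time",
    scores = if (length(unique(hour_targets)) > 1) scores,
    labels = hour_targets)

  # Patient level: alert anywhere in the stay vs sepsis status.
  alerted <- vapply(traces, function(tr) !is.na(tr$alert_hour), logical(1))
  stays <- vapply(ids, function(id) nrow(state$processed[[id]]$features),
                  numeric(1))
  predictions <- lapply(setNames(ids, ids), function(id)
    trace_to_predictions(traces[[id]], stays[[id]]))
  util <- utility_score(predictions, truth_t, config$utility)
  septic <- truth_t$is_septic
  las <- rep(NA_real_, sum(septic))
  sep_ids <- ids[septic]
  for (i in seq_along(sep_ids)) {
    la <- lookahead(traces[[sep_ids[i]]],
                    truth_t[truth_t$patient_id == sep_ids[i], ])
    las[i] <- la$alert_lookahead
  }
  patient_report <- evaluation_report(
    confusion_counts(as.integer(alerted), as.integer(septic)),
    "patient", utility = util$normalized, lookaheads = las)

  sweep <- sweep_policy(traces, truth_t, x_grid = 1:5, w_grid = 2:8,
                        probability_threshold = thr)
  utils::write.table(sweep, file.path(config$output_dir, "policy_sweep.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state$summary <- list(time = time_report, patient = patient_report,
                        utility = util, sweep = sweep)
  jsonlite::write_json(
    list(time = unclass(time_report)[-2], patient = unclass(patient_report)[-2],
         seed = config$seed),
    file.path(config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = 6, pretty = TRUE, force = TRUE)
  state
}

stage_compare <- function(config, state) {
  split <- need_stage(state, "split", "compare", "preprocess")
  cohort <- need_stage(state, "cohort", "compare", "generate")
  truth <- state$truth
  ids <- intersect(split$test_ids, truth$patient_id)
  septic <- truth$is_septic[match(ids, truth$patient_id)]
  policy <- imputation_policy(config$features$hold_limits$vitals,
                              config$features$hold_limits$labs,
                              fill_value = NA)
  held <- lapply(cohort$records[ids], impute_sample_hold, policy = policy)
  rows <- lapply(c("sirs", "news", "mews", "psofa"), function(score) {
    alarmed <- vapply(held, function(rec)
      !is.na(comparator_alarm_trace(rec, score)$alert_hour), logical(1))
    cts <- confusion_counts(as.integer(alarmed), as.integer(septic))
    data.frame(score = score, tp = cts$tp, fp = cts$fp, tn = cts$tn,
               fn = cts$fn,
               sensitivity = binary_rate(cts$tp, cts$tp + cts$fn),
               specificity = binary_rate(cts$tn, cts$tn + cts$fp),
               far = false_alarm_ratio(cts))
  })
  state$comparators <- do.call(rbind, rows)
  utils::write.table(state$comparators,
                     file.path(config$output_dir, "comparator_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state
}
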