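#' Patient-level train/validation/test split
#'
#' Splits a cohort at the patient level (never at the row level): first a
#' held-out test set of `floor(N * test_fraction)` patients, then the
#' remainder divided into training and validation by
#' `train_fraction_of_rest`. With the defaults (0.15 held out, then 80/20)
#' 100 patients yield 15 test, 68 training and 17 validation patients.
#' Optionally the draw is stratified by sepsis status so each set preserves
#' prevalence as closely as integer counts allow.
#'
#' @param records List of [patient_record()]s (or a character vector of ids).
#' @param test_fraction Proportion held out for testing (default 0.15).
#' @param train_fraction_of_rest Proportion of the remainder used for
#'   training (default 0.80).
#' @param seed Integer seed; the same seed always reproduces the same split.
#' @param stratify_by Optional logical vector (one entry per patient, e.g.
#'   septic yes/no) to stratify on; `NULL` (default) draws unstratified.
#' @return A `cohort_split`: list with `train_ids`, `validation_ids`,
#'   `test_ids` (pairwise disjoint, union = all ids) and `seed`.
#' @export
#' @examples
#' ids <- sprintf("p%03d", 1:100)
#' sp <- split_cohort(ids, 0.15, 0.80, seed = 1)
#' lengths(sp[c("train_ids", "validation_ids", "test_ids")])
split_cohort <- function(records, test_fraction = 0.15,
                         train_fraction_of_rest = 0.80, seed = 1L,
                         stratify_by = NULL) {
  ids <- if (is.character(records)) records
         else vapply(records, `[[`, character(1), "patient_id")
  if (!length(ids)) stopf("empty cohort")
  if (length(ids) < 3L) stopf("need at least 3 patients to split")
  if (anyDuplicated(ids)) stopf("duplicated patient ids")
  if (!is_prop(test_fraction) || test_fraction <= 0 || test_fraction >= 1 ||
      !is_prop(train_fraction_of_rest) || train_fraction_of_rest <= 0 ||
      train_fraction_of_rest >= 1)
    stopf("fractions must lie strictly in (0, 1)")

  draw <- function(pool, n_test, n_train) {
    shuffled <- sample(pool)
    list(test = shuffled[seq_len(n_test)],
         train = shuffled[n_test + seq_len(n_train)],
         validation = shuffled[-seq_len(n_test + n_train)])
  }

  parts <- with_seed(seed, {
    if (is.null(stratify_by)) {
      pools <- list(ids)
    } else {
      if (length(stratify_by) != length(ids))
        stopf("stratify_by must have one entry per patient")
      pools <- split(ids, as.logical(stratify_by))
    }
    out <- list(test = character(0), train = character(0),
                validation = character(0))
    for (pool in pools) {
      n_test <- floor(length(pool) * test_fraction)
      n_train <- floor((length(pool) - n_test) * train_fraction_of_rest)
      p <- draw(pool, n_test, n_train)
      out <- Map(c, out, p)
    }
    out
  })

  structure(
    list(train_ids = unname(parts$train),
         validation_ids = unname(parts$validation),
         test_ids = unname(parts$test),
         seed = as.integer(seed)),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split>  train %d | validation %d | test %d  (seed %d)\n",
              length(x$train_ids), length(x$validation_ids),
              length(x$test_ids), x$seed))
  invisible(x)
}
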