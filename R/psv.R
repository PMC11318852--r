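#' Construct a per-patient hourly ICU record
#'
#' A `patient_record` holds one patient's hourly time-varying matrix (8 vitals
#' and 26 labs, `NA` marking missing entries), static demographics, the 1-based
#' hour index `ICULOS`, and the per-hour binary sepsis label.
#'
#' @param patient_id Opaque patient identifier string.
#' @param values Numeric matrix, hours x 34, with the canonical
#'   `psv_columns("timevarying")` column names; `NA` marks missing.
#' @param demographics Named numeric vector or list with entries
#'   `Age`, `Gender`, `Unit1`, `Unit2`, `HospAdmTime` (any may be `NA`).
#' @param sepsis_label Integer 0/1 vector, one entry per hour; must be
#'   monotone non-decreasing (sepsis never un-happens).
#' @param iculos Integer hour index; defaults to `1:nrow(values)` and must
#'   start at 1 and increase by exactly 1.
#' @return An object of class `patient_record`.
#' @export
#' @examples
#' vals <- matrix(NA_real_, 2, 34,
#'                dimnames = list(NULL, psv_columns("timevarying")))
#' vals[, "HR"] <- c(80, 82)
#' rec <- patient_record("p1", vals,
#'                       demographics = c(Age = 60, Gender = 1, Unit1 = 1,
#'                                        Unit2 = 0, HospAdmTime = -10),
#'                       sepsis_label = c(0L, 0L))
#' rec
patient_record <- function(patient_id, values, demographics, sepsis_label,
                           iculos = seq_len(nrow(values))) {
  rec <- structure(
    list(
      patient_id = as.character(patient_id),
      values = values,
      demographics = unlist(demographics)[PSV_DEMOGRAPHICS],
      iculos = as.integer(iculos),
      sepsis_label = as.integer(sepsis_label)
    ),
    class = "patient_record"
  )
  names(rec$demographics) <- PSV_DEMOGRAPHICS
  validate_patient_record(rec)
  rec
}

#' Validate a patient record's structural invariants
#'
#' Checks the column layout, the contiguous 1-based `ICULOS` clock, the
#' finiteness of observed entries and the monotone (once 1, stays 1) sepsis
#' label.
#'
#' @param rec A `patient_record`.
#' @return The record, invisibly; errors describe the violated invariant.
#' @export
validate_patient_record <- function(rec) {
  if (!inherits(rec, "patient_record")) stopf("not a patient_record")
  v <- rec$values
  if (!is.matrix(v) || !is.numeric(v))
    stopf("patient %s: values must be a numeric matrix", rec$patient_id)
  if (!identical(colnames(v), PSV_TIMEVARYING))
    stopf("patient %s: values columns must be the canonical 34 vitals+labs",
          rec$patient_id)
  n <- nrow(v)
  if (n < 1L) stopf("patient %s: record has no hours", rec$patient_id)
  if (length(rec$iculos) != n || length(rec$sepsis_label) != n)
    stopf("patient %s: iculos/sepsis_label length mismatch", rec$patient_id)
  if (rec$iculos[1] != 1L || (n > 1L && any(diff(rec$iculos) != 1L)))
    stopf("patient %s: non-contiguous hour index (ICULOS must be 1,2,...)",
          rec$patient_id)
  if (!all(rec$sepsis_label %in% c(0L, 1L)))
    stopf("patient %s: sepsis label must be binary", rec$patient_id)
  if (n > 1L && any(diff(rec$sepsis_label) < 0L))
    stopf("patient %s: sepsis label must be monotone non-decreasing",
          rec$patient_id)
  obs <- v[!is.na(v)]
  if (length(obs) && any(!is.finite(obs)))
    stopf("patient %s: observed values must be finite", rec$patient_id)
  invisible(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  n <- nrow(x$values)
  miss <- mean(is.na(x$values))
  onset <- onset_hour(x)
  cat(sprintf("<patient_record %s>  %d hours, %.0f%% raw cells missing, %s\n",
              x$patient_id, n, 100 * miss,
              if (is.na(onset)) "sepsis-negative"
              else sprintf("sepsis onset at hour %d", onset)))
  invisible(x)
}

#' First hour with a positive sepsis label
#'
#' @param rec A `patient_record`.
#' @return Integer hour of the first positive label, or `NA` for a
#'   sepsis-negative record.
#' @export
onset_hour <- function(rec) {
  w <- which(rec$sepsis_label == 1L)
  if (length(w)) rec$iculos[w[1]] else NA_integer_
}

#' Read one per-patient PSV record file
#'
#' Parses the pipe-separated hourly record dialect: a header row with the
#' canonical 41 columns, one row per ICU hour, the literal string `NaN` for
#' missing entries. Missing columns are tolerated (with a warning) and
#' treated as fully missing; unknown extra columns are rejected.
#'
#' @param path Path to a `<patient_id>.psv` file.
#' @param patient_id Identifier to attach; defaults to the file name without
#'   its extension.
#' @return A [patient_record()].
#' @export
read_psv <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stopf("PSV file not found: %s", path)
  if (is.null(patient_id))
    patient_id <- sub("\\.psv$", "", basename(path))
  lines <- readLines(path)
  if (length(lines) < 2L)
    stopf("malformed PSV %s: need a header and at least one data row", path)
  header <- strsplit(lines[1], "|", fixed = TRUE)[[1]]
  extra <- setdiff(header, PSV_COLUMNS)
  if (length(extra))
    stopf("malformed header in %s: unknown column(s) %s", path,
          paste(extra, collapse = ", "))
  if (anyDuplicated(header))
    stopf("malformed header in %s: duplicated column names", path)
  absent <- setdiff(PSV_COLUMNS, header)
  if (!all(c("ICULOS", "SepsisLabel") %in% header))
    stopf("malformed header in %s: ICULOS and SepsisLabel are required", path)
  if (length(absent))
    warnf("PSV %s lacks column(s) %s; treated as fully missing", path,
          paste(absent, collapse = ", "))

  rows <- strsplit(lines[-1], "|", fixed = TRUE)
  ncell <- lengths(rows)
  if (any(ncell != length(header)))
    stopf("parse error in %s: row %d has %d fields, header has %d", path,
          which(ncell != length(header))[1] + 1L,
          ncell[ncell != length(header)][1], length(header))

  raw <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
                dimnames = list(NULL, header))
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  bad <- is.na(num) & raw != "NaN" & raw != "NA"
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stopf("parse error in %s: non-numeric cell '%s' at row %d, column %s",
          path, raw[bad][1], idx[1] + 1L, header[idx[2]])
  }

  num[is.nan(num)] <- NA_real_  # the literal "NaN" is the missing marker
  values <- matrix(NA_real_, nrow(num), length(PSV_TIMEVARYING),
                   dimnames = list(NULL, PSV_TIMEVARYING))
  for (p in intersect(PSV_TIMEVARYING, header)) values[, p] <- num[, p]
  demo <- setNames(rep(NA_real_, length(PSV_DEMOGRAPHICS)), PSV_DEMOGRAPHICS)
  for (p in intersect(PSV_DEMOGRAPHICS, header)) demo[p] <- num[1, p]

  iculos <- num[, "ICULOS"]
  if (any(is.na(iculos)))
    stopf("parse error in %s: missing ICULOS at row %d", path,
          which(is.na(iculos))[1] + 1L)
  if (iculos[1] != 1 || (length(iculos) > 1 && any(diff(iculos) != 1)))
    stopf("parse error in %s: non-contiguous hour index", path)
  label <- num[, "SepsisLabel"]
  if (any(is.na(label)) || !all(label %in% c(0, 1)))
    stopf("parse error in %s: SepsisLabel must be binary", path)

  patient_record(patient_id, values, demo, as.integer(label),
                 as.integer(iculos))
}

#' Write one per-patient PSV record file
#'
#' Emits the canonical 41-column pipe-separated layout, one row per hour,
#' with `NaN` for missing entries. `write_psv(read_psv(f))` is a fixed point
#' after one round trip (numeric formatting is canonicalized on first write).
#'
#' @param rec A [patient_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psv <- function(rec, path) {
  validate_patient_record(rec)
  n <- nrow(rec$values)
  full <- cbind(
    rec$values,
    matrix(rep(rec$demographics, each = n), nrow = n,
           dimnames = list(NULL, PSV_DEMOGRAPHICS)),
    ICULOS = rec$iculos,
    SepsisLabel = rec$sepsis_label
  )[, PSV_COLUMNS, drop = FALSE]
  cells <- matrix(vapply(full, format_psv_cell, character(1)), nrow = n)
  lines <- c(paste(PSV_COLUMNS, collapse = "|"),
             apply(cells, 1, paste, collapse = "|"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("cannot write PSV file: %s", path)
  invisible(path)
}

# as.character() on a double round-trips exactly through as.numeric(),
# which is what makes write -> read -> write a fixed point.
format_psv_cell <- function(x) {
  if (is.na(x)) "NaN" else as.character(x)
}

#' Write a cohort of records to a directory
#'
#' One `<patient_id>.psv` file per record, plus (optionally) the ground-truth
#' sidecar table `ground_truth.tsv` with columns
#' `patient_id`, `is_septic`, `onset_hour`.
#'
#' @param records List of [patient_record()]s.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth data frame to write alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in records) write_psv(rec, file.path(dir, paste0(rec$patient_id, ".psv")))
  if (!is.null(truth))
    utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory of PSV files
#'
#' @param dir Directory containing `<patient_id>.psv` files.
#' @return Named list of [patient_record()]s, ordered by file name.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.psv$", full.names = TRUE))
  if (!length(files)) stopf("no .psv files found in %s", dir)
  recs <- lapply(files, read_psv)
  names(recs) <- vapply(recs, `[[`, character(1), "patient_id")
  recs
}
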