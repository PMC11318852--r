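# Canonical PhysioNet/CinC 2019 column layout: 8 hourly vitals, 26 labs,
# 6 demographic/administrative fields, then the per-hour sepsis label.
# The PSV dialect is fixed to this single order so that I/O is bit-exact.

PSV_VITALS <- c("HR", "O2Sat", "Temp", "SBP", "MAP", "DBP", "Resp", "EtCO2")

PSV_LABS <- c(
  "BaseExcess", "HCO3", "FiO2", "pH", "PaCO2", "SaO2", "AST", "BUN",
  "Alkalinephos", "Calcium", "Chloride", "Creatinine", "Bilirubin_direct",
  "Glucose", "Lactate", "Magnesium", "Phosphate", "Potassium",
  "Bilirubin_total", "TroponinI", "Hct", "Hgb", "PTT", "WBC",
  "Fibrinogen", "Platelets"
)

PSV_DEMOGRAPHICS <- c("Age", "Gender", "Unit1", "Unit2", "HospAdmTime")

PSV_TIMEVARYING <- c(PSV_VITALS, PSV_LABS)

PSV_COLUMNS <- c(PSV_TIMEVARYING, PSV_DEMOGRAPHICS, "ICULOS", "SepsisLabel")

#' Canonical PSV column names
#'
#' The fixed 41-column header of the per-patient hourly record files:
#' 8 vital signs, 26 laboratory values, 5 static demographic/administrative
#' fields, the 1-based hour index `ICULOS`, and the binary `SepsisLabel`.
#'
#' @param which One of `"all"`, `"vitals"`, `"labs"`, `"demographics"`,
#'   `"timevarying"` (vitals + labs).
#' @return Character vector of column names in canonical order.
#' @export
#' @examples
#' length(psv_columns())        # 41
#' psv_columns("vitals")
psv_columns <- function(which = c("all", "vitals", "labs", "demographics",
                                  "timevarying")) {
  switch(match.arg(which),
    all = PSV_COLUMNS,
    vitals = PSV_VITALS,
    labs = PSV_LABS,
    demographics = PSV_DEMOGRAPHICS,
    timevarying = PSV_TIMEVARYING
  )
}
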