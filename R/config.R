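# Shipped configuration: default feature set, hold limits, normalization
# limits and score band tables live as editable YAML under inst/extdata.

config_cache <- new.env(parent = emptyenv())

read_pkg_yaml <- function(name) {
  path <- system.file("extdata", name, package = "sepsiswatch")
  if (!nzchar(path)) stopf("shipped config '%s' not found", name)
  yaml::read_yaml(path)
}

#' Default preprocessing configuration
#'
#' Reads the shipped feature configuration: the selected raw parameters
#' (7 vitals, 8 labs, 2 demographics), the 4 derived parameters, the
#' sample-and-hold limits (4 h for vitals, 24 h for labs), the 6-hour label
#' lookahead, the 4-hour window, the undersampling ratio, and the per-parameter
#' min-max normalization limits used by the rescale to \[1, 5\].
#'
#' @param path Optional path to an alternative YAML file with the same keys.
#' @return Named list of configuration values; `normalization_limits` is a
#'   named list of `c(min, max)` pairs in native units.
#' @export
#' @examples
#' cfg <- feature_config()
#' cfg$hold_limits
#' cfg$normalization_limits$HR
feature_config <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(config_cache$feature)) {
      config_cache$feature <- prepare_feature_config(read_pkg_yaml("feature_config.yaml"))
    }
    return(config_cache$feature)
  }
  prepare_feature_config(yaml::read_yaml(path))
}

prepare_feature_config <- function(cfg) {
  needed <- c("selected_vitals", "selected_labs", "selected_demographics",
              "derived_parameters", "hold_limits", "label_lookahead",
              "window_hours", "window_stride", "undersample_ratio",
              "max_missing_fraction", "mask_value", "normalization_limits")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) stopf("feature config missing keys: %s",
                             paste(missing, collapse = ", "))
  cfg$normalization_limits <- lapply(cfg$normalization_limits, as.numeric)
  for (p in names(cfg$normalization_limits)) {
    lim <- cfg$normalization_limits[[p]]
    if (length(lim) != 2L || !all(is.finite(lim)) || lim[1] >= lim[2])
      stopf("degenerate normalization limits for '%s'", p)
  }
  cfg$selected_raw <- c(cfg$selected_vitals, cfg$selected_labs,
                        cfg$selected_demographics)
  cfg
}

#' Clinical score band tables
#'
#' Reads the shipped band tables defining MEWS, NEWS, the partial SOFA
#' (MAP, total bilirubin, platelets only) and the SIRS criteria, as ordered
#' interval-to-points rules. Tables are data, not code: hospitals differ in
#' which revision they run, so they are editable without touching the scoring
#' engine. A missing component always contributes 0 points.
#'
#' @param path Optional path to an alternative YAML band file.
#' @return Named list with elements `mews`, `news`, `psofa`
#'   (banded components + `trigger_threshold`) and `sirs` (criteria).
#' @export
#' @examples
#' bands <- score_bands()
#' names(bands)
#' bands$mews$trigger_threshold
score_bands <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(config_cache$bands)) {
      config_cache$bands <- prepare_score_bands(read_pkg_yaml("score_bands.yaml"))
    }
    return(config_cache$bands)
  }
  prepare_score_bands(yaml::read_yaml(path))
}

prepare_score_bands <- function(bands) {
  for (score in setdiff(names(bands), "sirs")) {
    comps <- bands[[score]]$components
    bands[[score]]$components <- lapply(comps, function(rules) {
      m <- do.call(rbind, lapply(rules, function(r) {
        vapply(r, parse_band_bound, numeric(1))
      }))
      colnames(m) <- c("lower", "upper", "points")
      if (any(m[, "points"] < 0) || any(m[, "points"] != round(m[, "points"])))
        stopf("band points must be non-negative integers in score '%s'", score)
      m
    })
  }
  bands
}

parse_band_bound <- function(x) {
  if (is.character(x)) {
    if (x == "inf") return(Inf)
    if (x == "-inf") return(-Inf)
    return(as.numeric(x))
  }
  as.numeric(x)
}
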