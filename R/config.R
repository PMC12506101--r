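#' Study configuration
#'
#' Builds the configuration object that carries every tunable threshold of the
#' harmonisation pipeline: the study window, BMI plausibility bounds, the
#' height-weight pairing window for children, the same-day consistency
#' tolerance, the pregnancy window, the minimum survival requirement, the
#' age ranges of the two cohort branches, adult category cut-points, paediatric
#' percentile thresholds, the source hierarchy and the over-time cleaning
#' allowance.
#'
#' Defaults reproduce the published study conditions: a 23-year window
#' (2000-01-01 to 2022-12-31), BMI kept in \[12, 100\] kg/m2, a 180-day
#' height-weight pairing window for children, a 5\% same-day relative
#' difference tolerance, a +/-294-day pregnancy window, a 31-day minimum
#' survival after study start, children aged 24-228 months, adults aged
#' 19-100 years, adult cut-points 18.5/25/30, and the six-row source
#' hierarchy (see [default_hierarchy()]).
#'
#' @param study_start,study_end study window (coercible to `Date`).
#' @param bmi_min,bmi_max plausible BMI bounds in kg/m2; values strictly below
#'   `bmi_min` or strictly above `bmi_max` are removed (boundary values kept).
#' @param height_bounds_m plausible standing-height range in metres.
#' @param weight_bounds_kg plausible weight range in kg.
#' @param hw_pair_window_days maximum |height date - weight date| for pairing
#'   in the child branch.
#' @param pregnancy_window_days half-width of the window around a baby's birth
#'   date within which records are flagged as pregnancy-related.
#' @param same_day_rel_diff maximum relative difference (relative to the
#'   smaller value) for two same-day BMI values to be consistent.
#' @param min_residency_days persons dying within this many days of study
#'   start are excluded.
#' @param cyp_age_months closed interval of ages, in completed months, mapped
#'   to the child/young-person branch.
#' @param adult_age_years closed interval of ages, in completed years, mapped
#'   to the adult branch.
#' @param adult_cut_points strictly increasing BMI thresholds separating
#'   underweight/normal/overweight/obese for adults.
#' @param cyp_percentiles named percentiles (`under`, `over`, `obese`) whose
#'   normal-quantile z-equivalents categorise children.
#' @param hierarchy tibble with columns `source`, `data_type`, `rank`; ranks
#'   must be a permutation of 1..6.
#' @param overtime_max_annual_delta maximum allowed BMI change, kg/m2 per
#'   365 days, for the adult over-time cleaning rule.
#' @param linkage_status_accept integer codes accepted as reliable linkage.
#' @param adult_height_mode `"carry_forward"` pairs each adult weight with the
#'   most recent height on or before it (earliest later height as fallback);
#'   `"single"` uses one study-wide most recent height per person.
#'
#' @return A validated `bmi_config` list.
#' @export
#' @examples
#' cfg <- bmi_config()
#' cfg$bmi_min
bmi_config <- function(study_start = "2000-01-01",
                       study_end = "2022-12-31",
                       bmi_min = 12,
                       bmi_max = 100,
                       height_bounds_m = c(0.5, 2.5),
                       weight_bounds_kg = c(5, 350),
                       hw_pair_window_days = 180L,
                       pregnancy_window_days = 294L,
                       same_day_rel_diff = 0.05,
                       min_residency_days = 31L,
                       cyp_age_months = c(24L, 228L),
                       adult_age_years = c(19L, 100L),
                       adult_cut_points = c(18.5, 25, 30),
                       cyp_percentiles = c(under = 0.02, over = 0.85, obese = 0.95),
                       hierarchy = default_hierarchy(),
                       overtime_max_annual_delta = 10,
                       linkage_status_accept = c(1L, 4L, 39L),
                       adult_height_mode = c("carry_forward", "single")) {
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    bmi_min = as.numeric(bmi_min),
    bmi_max = as.numeric(bmi_max),
    height_bounds_m = as.numeric(height_bounds_m),
    weight_bounds_kg = as.numeric(weight_bounds_kg),
    hw_pair_window_days = as.integer(hw_pair_window_days),
    pregnancy_window_days = as.integer(pregnancy_window_days),
    same_day_rel_diff = as.numeric(same_day_rel_diff),
    min_residency_days = as.integer(min_residency_days),
    cyp_age_months = as.integer(cyp_age_months),
    adult_age_years = as.integer(adult_age_years),
    adult_cut_points = as.numeric(adult_cut_points),
    cyp_percentiles = cyp_percentiles,
    hierarchy = as_tibble(hierarchy),
    overtime_max_annual_delta = as.numeric(overtime_max_annual_delta),
    linkage_status_accept = as.integer(linkage_status_accept),
    adult_height_mode = match.arg(adult_height_mode)
  )
  class(cfg) <- "bmi_config"
  validate_config(cfg)
}

#' Default source hierarchy
#'
#' The trust ranking over (source, data type) pairs used to resolve multiple
#' same-day entries: directly recorded primary-care BMI values are most
#' trusted (rank 1) and hospital obesity diagnoses least (rank 6).
#'
#' @return Tibble with columns `source`, `data_type`, `rank`.
#' @export
default_hierarchy <- function() {
  tibble(
    source = c("WLGP", "WLGP", "MIDS", "NCCH", "WLGP", "PEDW"),
    data_type = c("bmi_value", "height_weight", "height_weight",
                  "height_weight", "bmi_category", "obese_category"),
    rank = 1:6
  )
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "bmirrda_config_error")
  if (is.na(cfg$study_start) || is.na(cfg$study_end)) {
    stop_cfg("study_start and study_end must be valid dates")
  }
  if (!cfg$study_start < cfg$study_end) {
    stop_cfg("study_start must precede study_end")
  }
  if (!(cfg$bmi_min > 0 && cfg$bmi_min < cfg$bmi_max)) {
    stop_cfg("bmi bounds invalid: need 0 < bmi_min < bmi_max")
  }
  for (fld in c("height_bounds_m", "weight_bounds_kg")) {
    b <- cfg[[fld]]
    if (length(b) != 2 || !(b[1] > 0 && b[1] < b[2])) {
      stop_cfg(paste0(fld, " must be two increasing positive values"))
    }
  }
  for (fld in c("hw_pair_window_days", "pregnancy_window_days",
                "min_residency_days")) {
    if (cfg[[fld]] <= 0) stop_cfg(paste0(fld, " must be positive"))
  }
  if (cfg$same_day_rel_diff <= 0) stop_cfg("same_day_rel_diff must be positive")
  if (cfg$overtime_max_annual_delta <= 0) {
    stop_cfg("overtime_max_annual_delta must be positive")
  }
  if (length(cfg$cyp_age_months) != 2 || diff(cfg$cyp_age_months) <= 0) {
    stop_cfg("cyp_age_months must be an increasing interval")
  }
  if (length(cfg$adult_age_years) != 2 || diff(cfg$adult_age_years) <= 0) {
    stop_cfg("adult_age_years must be an increasing interval")
  }
  if (is.unsorted(cfg$adult_cut_points, strictly = TRUE) ||
      length(cfg$adult_cut_points) != 3) {
    stop_cfg("adult_cut_points must be three strictly increasing thresholds")
  }
  p <- cfg$cyp_percentiles
  if (!all(c("under", "over", "obese") %in% names(p)) ||
      is.unsorted(p[c("under", "over", "obese")], strictly = TRUE) ||
      any(p <= 0) || any(p >= 1)) {
    stop_cfg("cyp_percentiles must name increasing under/over/obese percentiles in (0,1)")
  }
  h <- cfg$hierarchy
  if (!all(c("source", "data_type", "rank") %in% names(h))) {
    stop_cfg("hierarchy needs columns source, data_type, rank")
  }
  if (!setequal(h$rank, seq_len(nrow(h))) || anyDuplicated(h$rank)) {
    stop_cfg("hierarchy ranks must be a permutation of 1..n")
  }
  if (anyDuplicated(paste(h$source, h$data_type))) {
    stop_cfg("hierarchy (source, data_type) pairs must be unique")
  }
  cfg
}

#' Z-score thresholds implied by the configured paediatric percentiles
#'
#' @param cfg a `bmi_config`.
#' @return Named numeric vector `under`, `over`, `obese` of normal quantiles.
#' @export
cyp_z_thresholds <- function(cfg) {
  p <- cfg$cyp_percentiles
  c(under = qnorm(p[["under"]]), over = qnorm(p[["over"]]),
    obese = qnorm(p[["obese"]]))
}

#' Load a study configuration from a flat key-value file
#'
#' The file holds `key = value` lines (`#` comments allowed); absent keys take
#' the documented defaults of [bmi_config()]. Interval-valued keys
#' (`cyp_age_months`, `adult_cut_points`, ...) are comma-separated lists.
#' The hierarchy cannot be expressed in the flat format and always takes
#' [default_hierarchy()]; use [bmi_config()] directly to override it.
#'
#' @param path path to the configuration file.
#' @return A validated `bmi_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path),
          class = "bmirrda_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(paste0("cannot parse configuration line: '", ln, "'"),
            class = "bmirrda_config_error")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  numeric_keys <- c("bmi_min", "bmi_max", "same_day_rel_diff",
                    "overtime_max_annual_delta")
  int_keys <- c("hw_pair_window_days", "pregnancy_window_days",
                "min_residency_days")
  vec_keys <- c("height_bounds_m", "weight_bounds_kg", "cyp_age_months",
                "adult_age_years", "adult_cut_points", "linkage_status_accept")
  date_keys <- c("study_start", "study_end")
  args <- list()
  for (key in names(kv)) {
    val <- kv[[key]]
    if (key %in% date_keys) {
      args[[key]] <- val
    } else if (key %in% numeric_keys) {
      args[[key]] <- as.numeric(val)
    } else if (key %in% int_keys) {
      args[[key]] <- as.integer(val)
    } else if (key %in% vec_keys) {
      args[[key]] <- as.numeric(strsplit(val, ",")[[1]])
    } else if (key == "cyp_percentiles") {
      v <- as.numeric(strsplit(val, ",")[[1]])
      if (length(v) != 3) {
        abort("cyp_percentiles needs three comma-separated values (under,over,obese)",
              class = "bmirrda_config_error")
      }
      args[[key]] <- c(under = v[1], over = v[2], obese = v[3])
    } else if (key == "adult_height_mode") {
      args[[key]] <- val
    } else {
      abort(paste0("unknown configuration key: ", key),
            class = "bmirrda_config_error")
    }
  }
  do.call(bmi_config, args)
}

#' Write a configuration to the flat key-value format
#'
#' Inverse of [load_config()] for all scalar and interval keys.
#'
#' @param cfg a `bmi_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  keys <- c("study_start", "study_end", "bmi_min", "bmi_max",
            "height_bounds_m", "weight_bounds_kg", "hw_pair_window_days",
            "pregnancy_window_days", "same_day_rel_diff",
            "min_residency_days", "cyp_age_months", "adult_age_years",
            "adult_cut_points", "cyp_percentiles",
            "overtime_max_annual_delta", "linkage_status_accept",
            "adult_height_mode")
  lines <- vapply(keys, function(k) paste0(k, " = ", fmt(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.bmi_config <- function(x, ...) {
  cat("<bmi_config>\n")
  cat("  study window : ", format(x$study_start), " to ", format(x$study_end), "\n", sep = "")
  cat("  BMI bounds   : [", x$bmi_min, ", ", x$bmi_max, "] kg/m2\n", sep = "")
  cat("  CYP ages     : ", x$cyp_age_months[1], "-", x$cyp_age_months[2], " months\n", sep = "")
  cat("  adult ages   : ", x$adult_age_years[1], "-", x$adult_age_years[2], " years\n", sep = "")
  cat("  hierarchy    : ", nrow(x$hierarchy), " (source, data type) ranks\n", sep = "")
  invisible(x)
}
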