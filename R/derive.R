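#' Body mass index
#'
#' @param weight_kg weight in kilograms.
#' @param height_m height in metres.
#' @return BMI in kg/m2.
#' @export
#' @examples
#' compute_bmi(70, 1.75)
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
      any(!is.na(height_m) & height_m <= 0)) {
    abort("weight and height must be positive", class = "bmirrda_derive_error")
  }
  weight_kg / height_m^2
}

#' Pair child heights with weights inside a date window
#'
#' Children grow quickly, so a weight may only be paired with a height
#' measured within `hw_pair_window_days` of it. Among eligible heights the one
#' with the smallest absolute date gap is chosen; ties go to the earlier
#' height date. Weights with no eligible height yield nothing.
#'
#' @param heights tibble for one person/source with columns `date`, `value`
#'   (metres) and optionally `record_id`.
#' @param weights same shape, values in kg.
#' @param cfg a [bmi_config()].
#' @return Tibble (`weight_date`, `height_date`, `weight_kg`, `height_m`,
#'   `bmi_value`, `weight_record_id`, `height_record_id`), one row per paired
#'   weight; `bmi_date`
#'   is the weight date by convention.
#' @export
pair_cyp <- function(heights, weights, cfg = bmi_config()) {
  pairs <- vector("list", nrow(weights))
  for (i in seq_len(nrow(weights))) {
    if (nrow(heights) == 0) break
    gap <- abs(as.numeric(heights$date - weights$date[i]))
    ok <- gap <= cfg$hw_pair_window_days
    if (!any(ok)) next
    cand <- which(ok)
    cand <- cand[order(gap[cand], heights$date[cand])]
    j <- cand[1]
    pairs[[i]] <- fast_tbl(
      weight_date = weights$date[i], height_date = heights$date[j],
      weight_kg = weights$value[i], height_m = heights$value[j],
      bmi_value = compute_bmi(weights$value[i], heights$value[j]),
      weight_record_id = weights$record_id[i] %||% NA_character_,
      height_record_id = heights$record_id[j] %||% NA_character_)
  }
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0) empty_pairs() else out
}

#' Pair adult heights with weights by carrying height forward
#'
#' Adult height is near-constant, so each weight is paired with the most
#' recent height dated on or before it; a weight earlier than every height
#' falls back to the earliest later height. With
#' `adult_height_mode = "single"` one study-wide most recent height is used
#' for all weights instead.
#'
#' @inheritParams pair_cyp
#' @return As [pair_cyp()].
#' @export
pair_adult <- function(heights, weights, cfg = bmi_config()) {
  if (nrow(heights) == 0 || nrow(weights) == 0) return(empty_pairs())
  h <- heights[order(heights$date), ]
  pairs <- vector("list", nrow(weights))
  single_idx <- nrow(h)   # most recent height overall
  for (i in seq_len(nrow(weights))) {
    if (cfg$adult_height_mode == "single") {
      j <- single_idx
    } else {
      before <- which(h$date <= weights$date[i])
      j <- if (length(before)) max(before) else 1L
    }
    pairs[[i]] <- fast_tbl(
      weight_date = weights$date[i], height_date = h$date[j],
      weight_kg = weights$value[i], height_m = h$value[j],
      bmi_value = compute_bmi(weights$value[i], h$value[j]),
      weight_record_id = weights$record_id[i] %||% NA_character_,
      height_record_id = h$record_id[j] %||% NA_character_)
  }
  dplyr::bind_rows(pairs)
}

empty_pairs <- function() {
  tibble(weight_date = as.Date(character()), height_date = as.Date(character()),
         weight_kg = numeric(), height_m = numeric(), bmi_value = numeric(),
         weight_record_id = character(), height_record_id = character())
}

#' LMS z-score
#'
#' Standard Box-Cox (LMS) transform of a measurement against an age/sex
#' reference: `z = ((x/M)^L - 1) / (L * S)` when `L != 0`, and
#' `z = log(x/M) / S` at `L = 0`. `L` is the Box-Cox power, `M` the median
#' and `S` the coefficient of variation at the child's age and sex.
#'
#' @param x measurement (kg/m2), positive.
#' @param L,M,S reference parameters; `M > 0`, `S > 0`.
#' @return z-score(s).
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(!is.na(x) & x <= 0) || any(!is.na(M) & M <= 0) ||
      any(!is.na(S) & S <= 0)) {
    abort("lms_zscore needs positive x, M and S",
          class = "bmirrda_derive_error")
  }
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Interpolate growth-reference parameters
#'
#' Linear interpolation of the L, M, S curves at the requested ages; exact at
#' grid knots. Ages outside the reference grid raise an error naming the
#' violated bound.
#'
#' @param ref growth-reference tibble with columns `sex`, `age_months`,
#'   `L`, `M`, `S`.
#' @param sex character vector (`"female"`/`"male"`), recycled against age.
#' @param age_months numeric vector of ages in months.
#' @return Tibble with columns `L`, `M`, `S` aligned to the inputs.
#' @export
reference_lookup <- function(ref, sex, age_months) {
  n <- max(length(sex), length(age_months))
  sex <- rep_len(sex, n)
  age_months <- rep_len(age_months, n)
  out <- tibble(L = rep(NA_real_, n), M = NA_real_, S = NA_real_)
  for (s in unique(sex)) {
    sub <- ref[ref$sex == s, ]
    if (nrow(sub) == 0) {
      abort(paste0("growth reference has no rows for sex '", s, "'"),
            class = "bmirrda_derive_error")
    }
    sub <- sub[order(sub$age_months), ]
    idx <- which(sex == s)
    a <- age_months[idx]
    lo <- min(sub$age_months); hi <- max(sub$age_months)
    if (any(a < lo)) {
      abort(paste0("age ", min(a), " months below reference grid start (",
                   lo, " months)"), class = "bmirrda_derive_error")
    }
    if (any(a > hi)) {
      abort(paste0("age ", max(a), " months above reference grid end (",
                   hi, " months)"), class = "bmirrda_derive_error")
    }
    for (par in c("L", "M", "S")) {
      out[[par]][idx] <- approx(sub$age_months, sub[[par]], xout = a,
                                method = "linear", ties = "ordered")$y
    }
  }
  out
}

#' Categorise a child's BMI z-score
#'
#' @param z z-score(s) from [lms_zscore()].
#' @param thresholds named z thresholds (`under`, `over`, `obese`), by default
#'   the normal quantiles of the configured percentiles (2nd, 85th, 95th).
#' @return Character categories.
#' @export
categorise_cyp <- function(z, thresholds = cyp_z_thresholds(bmi_config())) {
  dplyr::case_when(
    z < thresholds[["under"]] ~ "underweight",
    z >= thresholds[["obese"]] ~ "obese",
    z >= thresholds[["over"]] ~ "overweight",
    .default = "normal"
  )
}

#' Categorise an adult BMI
#'
#' Half-open intervals close the one-decimal gaps of the conventional ranges:
#' underweight below 18.5, normal \[18.5, 25), overweight \[25, 30), obese
#' from 30 upwards.
#'
#' @param bmi BMI value(s) in kg/m2.
#' @param cut_points three increasing thresholds (default 18.5, 25, 30).
#' @return Character categories.
#' @export
categorise_adult <- function(bmi, cut_points = c(18.5, 25, 30)) {
  .categories[findInterval(bmi, cut_points) + 1L]
}

#' Read a growth reference file
#'
#' Delimited columns `sex`, `age_months`, `L`, `M`, `S`; the grid must be
#' strictly increasing within sex with positive `M` and `S`.
#'
#' @param path file path.
#' @return Validated growth-reference tibble.
#' @export
read_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(), age_months = readr::col_double(),
    L = readr::col_double(), M = readr::col_double(),
    S = readr::col_double()), progress = FALSE)
  validate_reference(ref)
}

validate_reference <- function(ref) {
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort("growth reference requires M > 0 and S > 0",
          class = "bmirrda_derive_error")
  }
  for (s in unique(ref$sex)) {
    a <- ref$age_months[ref$sex == s]
    if (is.unsorted(a, strictly = TRUE)) {
      abort(paste0("growth reference ages must be strictly increasing (sex ",
                   s, ")"), class = "bmirrda_derive_error")
    }
  }
  as_tibble(ref)
}
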