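#' Encode and decode BMI categories
#'
#' The fixed numeric scale used for inconsistency detection:
#' underweight = 1, normal = 2, overweight = 3, obese = 4.
#'
#' @param category character vector of categories.
#' @return Integer codes.
#' @export
encode_category <- function(category) {
  code <- match(category, .categories)
  if (any(is.na(code) & !is.na(category))) {
    abort(paste0("unknown BMI category: ",
                 paste(unique(category[is.na(code) & !is.na(category)]),
                       collapse = ", ")),
          class = "bmirrda_harmonise_error")
  }
  code
}

#' @rdname encode_category
#' @param code integer codes 1-4.
#' @export
decode_category <- function(code) {
  if (any(!is.na(code) & !(code %in% 1:4))) {
    abort("category codes must lie in 1..4", class = "bmirrda_harmonise_error")
  }
  .categories[code]
}

empty_decisions <- function() {
  tibble(person_id = character(), bmi_date = as.Date(character()),
         rule = character(), record_id = character(), source = character(),
         data_type = character(), bmi_value = numeric(),
         category_code = integer(), detail = character())
}

# Pairwise same-day consistency for one person-day. Returns logical "removed"
# per row. Value-bearing entries are compared among themselves (consistent iff
# relative difference < tol AND same category); category-only entries are
# compared against the categories of all entries. Any entry in a violating
# pair is marked inconsistent.
same_day_marks <- function(value, code, tol) {
  n <- length(value)
  marked <- rep(FALSE, n)
  if (n < 2) return(marked)
  has_val <- !is.na(value)
  vi <- which(has_val)
  if (length(vi) >= 2) {
    for (a in seq_along(vi)[-length(vi)]) {
      for (b in seq((a + 1), length(vi))) {
        i <- vi[a]; j <- vi[b]
        lo <- min(value[i], value[j]); hi <- max(value[i], value[j])
        rel <- (hi - lo) / lo
        if (rel >= tol || code[i] != code[j]) {
          marked[i] <- TRUE; marked[j] <- TRUE
        }
      }
    }
  }
  ci <- which(!has_val)
  for (i in ci) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (code[i] != code[j]) {
        marked[i] <- TRUE; marked[j] <- TRUE
      }
    }
  }
  marked
}

#' Same-day inconsistency cleaning
#'
#' Within each person-day, entries are ordered by ascending BMI value and
#' category, then checked pairwise. Two value-bearing entries are consistent
#' when their relative difference (relative to the smaller value) is below the
#' configured tolerance and their categories agree; a category-only entry is
#' consistent with the rest of the day only if every other entry shares its
#' category. Both members of any violating pair are removed; a singleton day
#' passes untouched.
#'
#' @param entries harmonised candidate entries (may span many person-days).
#' @param cfg a [bmi_config()].
#' @return List with `kept`, `removed` and `decisions`.
#' @export
same_day_clean <- function(entries, cfg = bmi_config()) {
  if (nrow(entries) == 0) {
    return(list(kept = entries, removed = entries,
                decisions = empty_decisions()))
  }
  x <- entries[order(entries$person_id, entries$bmi_date,
                     xtfrm(entries$bmi_value), entries$category_code,
                     entries$rank, entries$source), ]
  key <- paste(x$person_id, x$bmi_date, sep = "\r")
  removed <- rep(FALSE, nrow(x))
  multi <- names(which(table(key) > 1))
  for (k in multi) {
    idx <- which(key == k)
    removed[idx] <- same_day_marks(x$bmi_value[idx], x$category_code[idx],
                                   cfg$same_day_rel_diff)
  }
  rem <- x[removed, ]
  decisions <- if (nrow(rem)) {
    tibble(person_id = rem$person_id, bmi_date = rem$bmi_date,
           rule = ifelse(is.na(rem$bmi_value), "same_day_category_conflict",
                         "same_day_value_conflict"),
           record_id = rem$record_id, source = rem$source,
           data_type = rem$data_type, bmi_value = rem$bmi_value,
           category_code = rem$category_code,
           detail = "pairwise same-day inconsistency")
  } else empty_decisions()
  list(kept = x[!removed, ], removed = rem, decisions = decisions)
}

#' Over-time inconsistency cleaning (adult branch)
#'
#' Adults only: scanning each person's value-bearing entries chronologically,
#' an entry is removed when its change from the last kept value exceeds the
#' allowance `overtime_max_annual_delta * max(gap_days, 365) / 365` — i.e. up
#' to the configured delta within any one year, pro-rated upwards for longer
#' gaps, so short-interval measurement noise is not over-penalised while an
#' implausible jump inside a week is still caught. Entries within the
#' pregnancy window of a recorded birth are exempt (kept, and not used as the
#' comparison baseline). Category-only entries and the whole child branch pass
#' through unchanged: child BMI changes rapidly by design.
#'
#' @param entries candidate entries surviving same-day cleaning.
#' @param births tibble (`person_id`, `birth_date`) of babies' birth dates
#'   from the maternity source.
#' @param cfg a [bmi_config()].
#' @return List with `kept`, `removed` and `decisions`.
#' @export
over_time_clean <- function(entries, births = NULL, cfg = bmi_config()) {
  if (nrow(entries) == 0) {
    return(list(kept = entries, removed = entries,
                decisions = empty_decisions()))
  }
  x <- entries[order(entries$person_id, entries$bmi_date,
                     xtfrm(entries$bmi_value), entries$rank, entries$source), ]
  scan <- x$branch == "adult" & !is.na(x$bmi_value)
  exempt <- in_pregnancy_window(x$person_id, x$bmi_date, births, cfg)
  removed <- rep(FALSE, nrow(x))
  idx_by_person <- split(which(scan), x$person_id[scan])
  for (rows in idx_by_person) {
    base_date <- as.Date(NA); base_value <- NA_real_
    cur_date <- as.Date(NA); cur_last_kept <- NA_real_
    for (i in rows) {
      if (!is.na(cur_date) && x$bmi_date[i] != cur_date) {
        if (!is.na(cur_last_kept)) {
          base_date <- cur_date; base_value <- cur_last_kept
        }
        cur_last_kept <- NA_real_
      }
      cur_date <- x$bmi_date[i]
      if (exempt[i]) next
      if (!is.na(base_value)) {
        gap <- as.numeric(x$bmi_date[i] - base_date)
        allowed <- cfg$overtime_max_annual_delta * max(gap, 365) / 365
        if (abs(x$bmi_value[i] - base_value) > allowed) {
          removed[i] <- TRUE
          next
        }
      }
      cur_last_kept <- x$bmi_value[i]
    }
  }
  rem <- x[removed, ]
  decisions <- if (nrow(rem)) {
    tibble(person_id = rem$person_id, bmi_date = rem$bmi_date,
           rule = "over_time_conflict", record_id = rem$record_id,
           source = rem$source, data_type = rem$data_type,
           bmi_value = rem$bmi_value, category_code = rem$category_code,
           detail = "change versus last kept value exceeds annual allowance")
  } else empty_decisions()
  list(kept = x[!removed, ], removed = rem, decisions = decisions)
}

in_pregnancy_window <- function(person_id, date, births, cfg) {
  out <- rep(FALSE, length(person_id))
  if (is.null(births) || nrow(births) == 0) return(out)
  b <- split(births$birth_date, births$person_id)
  hit <- person_id %in% names(b)
  for (i in which(hit)) {
    out[i] <- any(abs(as.numeric(date[i] - b[[person_id[i]]])) <=
                    cfg$pregnancy_window_days)
  }
  out
}

#' Select the single daily entry
#'
#' Among the consistent entries of a person-day the entry from the most
#' trusted source (minimum hierarchy rank) is retained; ties break by
#' ascending BMI value (entries without a value last), then by source name,
#' so runs are bit-reproducible.
#'
#' @param entries consistent candidate entries.
#' @return One entry per (person, date).
#' @export
select_daily_entry <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  x <- entries[order(entries$person_id, entries$bmi_date, entries$rank,
                     is.na(entries$bmi_value), xtfrm(entries$bmi_value),
                     entries$source), ]
  x[!duplicated(paste(x$person_id, x$bmi_date, sep = "\r")), ]
}

#' Flag pregnancy-window records
#'
#' Marks every entry falling within `pregnancy_window_days` (default 294
#' days, i.e. 42 weeks) before or after any recorded baby's birth date for
#' that person, to highlight weight changes likely related to pregnancy.
#'
#' @param entries entry tibble with `person_id` and `bmi_date`.
#' @param births tibble (`person_id`, `birth_date`).
#' @param cfg a [bmi_config()].
#' @return `entries` with a logical `pregnancy_flag` column.
#' @export
flag_pregnancy <- function(entries, births = NULL, cfg = bmi_config()) {
  entries$pregnancy_flag <- in_pregnancy_window(entries$person_id,
                                                entries$bmi_date, births, cfg)
  entries
}
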