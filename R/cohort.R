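#' Week-of-birth anchor
#'
#' Birth dates arrive at week granularity for anonymisation; ages are computed
#' from the Monday of the recorded week so that every age is a deterministic
#' function of the stored value.
#'
#' @param week_of_birth `Date` vector.
#' @return `Date` vector of Monday anchors.
#' @export
wob_anchor <- function(week_of_birth) {
  lubridate::floor_date(week_of_birth, unit = "week", week_start = 1)
}

days_in_month <- function(year, month) {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month] +
    as.integer(month == 2L &
                 (year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0)))
}

# Completed calendar months from anchor to date, with end-of-month rollback:
# an anchor on the 31st completes a month on the 28th/29th/30th of shorter
# months (anniversary arithmetic, vectorised without date-period objects).
months_since <- function(anchor, date) {
  a <- as.POSIXlt(anchor)
  d <- as.POSIXlt(date)
  m <- 12L * (d$year - a$year) + (d$mon - a$mon)
  anniversary_day <- pmin(a$mday, days_in_month(d$year + 1900L, d$mon + 1L))
  as.integer(m - (d$mday < anniversary_day))
}

# The date n years after the anchor, rolling 29 February back to 28 February.
add_years_rollback <- function(anchor, n) {
  a <- as.POSIXlt(anchor)
  y <- a$year + 1900L + n
  day <- pmin(a$mday, days_in_month(y, a$mon + 1L))
  as.Date(sprintf("%04d-%02d-%02d", y, a$mon + 1L, day))
}

#' Age in completed months
#'
#' Completed calendar months between the Monday anchor of the week of birth
#' and a record date. Month arithmetic follows calendar anniversaries (the
#' 24-month age starts exactly on the second anniversary of the anchor), with
#' end-of-month rollback for anchors late in the month.
#'
#' @param week_of_birth `Date` vector of recorded weeks of birth.
#' @param date `Date` vector of record dates (recycled).
#' @return Integer vector of completed months.
#' @export
age_at <- function(week_of_birth, date) {
  anchor <- wob_anchor(week_of_birth)
  n <- max(length(anchor), length(date))
  anchor <- rep_len(anchor, n)
  date <- rep_len(date, n)
  if (any(!is.na(anchor) & !is.na(date) & date < anchor)) {
    abort("record date precedes week-of-birth anchor",
          class = "bmirrda_cohort_error")
  }
  months_since(anchor, date)
}

#' Assign a record to the child or adult branch
#'
#' Children and young people are ages 24-228 completed months inclusive;
#' adults are 19-100 completed years. The child test takes precedence where
#' the two closed intervals touch at exactly 19 years. Records under 2 years
#' (category allocation is not routine at that age) or over 100 years map to
#' no branch and leave the pipeline.
#'
#' @param age_months integer vector of completed months at the record date.
#' @param cfg a [bmi_config()].
#' @return Character vector: `"CYP"`, `"adult"` or `NA`.
#' @export
assign_branch <- function(age_months, cfg = bmi_config()) {
  yrs <- age_months %/% 12L
  out <- rep(NA_character_, length(age_months))
  out[age_months >= cfg$cyp_age_months[1] &
        age_months <= cfg$cyp_age_months[2]] <- "CYP"
  adult <- is.na(out) & yrs >= cfg$adult_age_years[1] &
    yrs <= cfg$adult_age_years[2]
  out[adult] <- "adult"
  out
}

#' Apply demographic exclusions
#'
#' Removes persons in a fixed order — unreliable linkage status, missing week
#' of birth, invalid sex code, death before the study start, death within the
#' minimum survival window after study start — and records each step of the
#' exclusion flow.
#'
#' @param persons demographics tibble.
#' @param cfg a [bmi_config()].
#' @return List with `persons` (eligible) and `flow`, a tibble of
#'   (`step`, `label`, `removed`, `remaining`) whose counts telescope.
#' @export
apply_exclusions <- function(persons, cfg = bmi_config()) {
  steps <- list(
    linkage_status = function(p) !(p$linkage_status %in% cfg$linkage_status_accept),
    missing_wob = function(p) is.na(p$week_of_birth),
    invalid_sex = function(p) is.na(p$sex) | !(p$sex %in% c("female", "male")),
    dod_before_study = function(p) !is.na(p$date_of_death) &
      p$date_of_death < cfg$study_start,
    dod_within_min_residency = function(p) !is.na(p$date_of_death) &
      p$date_of_death < cfg$study_start + cfg$min_residency_days
  )
  flow <- list(tibble(step = 0L, label = "assessed", removed = 0L,
                      remaining = nrow(persons)))
  current <- persons
  for (i in seq_along(steps)) {
    drop <- steps[[i]](current)
    flow[[i + 1]] <- tibble(step = i, label = names(steps)[i],
                            removed = sum(drop),
                            remaining = nrow(current) - sum(drop))
    current <- current[!drop, ]
  }
  list(persons = current, flow = dplyr::bind_rows(flow))
}

#' Impute and clip residency episodes
#'
#' Missing episode start dates are set to the study start, missing end dates
#' to the study end; episodes are then clipped to the study window. Episodes
#' empty after clipping (entirely outside the study) are rejected to the
#' audit log.
#'
#' @param episodes residency tibble.
#' @param cfg a [bmi_config()].
#' @return List with `episodes` (complete, clipped) and `audit`.
#' @export
impute_residency <- function(episodes, cfg = bmi_config()) {
  x <- episodes
  x$start_date[is.na(x$start_date)] <- cfg$study_start
  x$end_date[is.na(x$end_date)] <- cfg$study_end
  x$start_date <- pmax(x$start_date, cfg$study_start)
  x$end_date <- pmin(x$end_date, cfg$study_end)
  bad <- x$start_date > x$end_date
  audit <- if (any(bad)) {
    audit_rows("cohort", "residency_outside_study",
               x$person_id[bad], x$start_date[bad])
  } else empty_audit()
  list(episodes = x[!bad, ], audit = audit)
}

#' Derive contribution windows
#'
#' A person's contribution to a branch starts at the later of the study start
#' and their earliest residency episode, and ends at the earliest binding
#' censor: death, the end of their last residency episode (moving away), the
#' day before the 19th birthday (child branch only), or the study end. A
#' person with imputed full-study residency and no death contributes the whole
#' study. Persons whose window is empty contribute no person-time and are
#' omitted.
#'
#' @param persons eligible demographics tibble.
#' @param episodes imputed residency episodes (see [impute_residency()]).
#' @param branch `"CYP"` or `"adult"`.
#' @param cfg a [bmi_config()].
#' @return Tibble (`person_id`, `entry_date`, `exit_date`, `exit_reason`).
#' @export
contribution_windows <- function(persons, episodes, branch = c("adult", "CYP"),
                                 cfg = bmi_config()) {
  branch <- match.arg(branch)
  if (nrow(persons) == 0) {
    return(tibble(person_id = character(), entry_date = as.Date(character()),
                  exit_date = as.Date(character()), exit_reason = character()))
  }
  eps <- episodes |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(first_start = min(.data$start_date),
                     last_end = max(.data$end_date), .groups = "drop")
  p <- dplyr::left_join(persons, eps, by = "person_id")
  # Persons with no residency episode at all: treat as resident throughout
  # (both dates imputed to the study bounds).
  p$first_start[is.na(p$first_start)] <- cfg$study_start
  p$last_end[is.na(p$last_end)] <- cfg$study_end

  entry <- pmax(cfg$study_start, p$first_start)
  anchor <- wob_anchor(p$week_of_birth)
  nineteenth <- add_years_rollback(anchor, 19L)
  if (branch == "CYP") {
    # Enter no earlier than the second birthday (24 months).
    entry <- pmax(entry, add_years_rollback(anchor, 2L))
    aged_out <- nineteenth - 1
  } else {
    # Adults contribute from their 19th birthday to the end of age 100.
    entry <- pmax(entry, nineteenth)
    aged_out <- add_years_rollback(anchor, 101L) - 1
  }
  cand <- tibble(
    death = dplyr::coalesce(p$date_of_death, as.Date("9999-12-31")),
    turned_19 = aged_out,
    moved_out = p$last_end,
    study_end = cfg$study_end
  )
  exit <- pmin(cand$death, cand$turned_19, cand$moved_out, cand$study_end)
  # tie priority: death, then ageing out, then the study end, then a recorded
  # move — so an imputed residency end on the final study day reads study_end
  reason_order <- c("death", if (branch == "CYP") "turned_19" else "aged_out",
                    "study_end", "moved_out")
  gaps <- cbind(as.numeric(cand$death - exit),
                as.numeric(cand$turned_19 - exit),
                as.numeric(cand$study_end - exit),
                as.numeric(cand$moved_out - exit))
  reason <- reason_order[max.col(-gaps, ties.method = "first")]
  keep <- entry <= exit
  tibble(person_id = p$person_id, entry_date = entry, exit_date = exit,
         exit_reason = reason)[keep, ]
}
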