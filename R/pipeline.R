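#' Attach stable record identifiers to the raw input tables
#'
#' Record identifiers are positional (`WLGP-3`, `NCCH-7`), assigned in file
#' order, and are the unit of the pipeline's record accounting. Maternity and
#' child-measurement rows split into height (`:h`) and weight (`:w`)
#' components downstream.
#'
#' @param inputs named list of the six input tibbles.
#' @return The list with a `record_id` column added to the event tables.
#' @keywords internal
add_record_ids <- function(inputs) {
  for (nm in c("wlgp_events", "pedw_episodes", "mids_records", "ncch_records")) {
    tbl <- inputs[[nm]]
    prefix <- c(wlgp_events = "WLGP", pedw_episodes = "PEDW",
                mids_records = "MIDS", ncch_records = "NCCH")[[nm]]
    tbl$record_id <- if (nrow(tbl)) paste0(prefix, "-", seq_len(nrow(tbl)))
                     else character(0)
    inputs[[nm]] <- tbl
  }
  inputs
}

events_from_inputs <- function(inputs) {
  wlgp <- inputs$wlgp_events
  pedw <- inputs$pedw_episodes
  dplyr::bind_rows(
    tibble(record_id = wlgp$record_id, person_id = wlgp$person_id,
           event_date = wlgp$event_date, source = "WLGP", code = wlgp$code,
           code_system = "ReadV2", numeric_value = wlgp$numeric_value,
           unit = wlgp$unit),
    tibble(record_id = pedw$record_id, person_id = pedw$person_id,
           event_date = pedw$admission_date, source = "PEDW", code = pedw$code,
           code_system = "ICD10", numeric_value = NA_real_,
           unit = NA_character_)
  )
}

mids_births <- function(mids_records) {
  b <- mids_records[!is.na(mids_records$baby_birth_date),
                    c("person_id", "baby_birth_date")]
  names(b) <- c("person_id", "birth_date")
  dplyr::distinct(b)
}

empty_entries <- function() {
  tibble(record_id = character(), person_id = character(),
         bmi_date = as.Date(character()), bmi_value = numeric(),
         category = character(), category_code = integer(),
         source = character(), data_type = character(), rank = integer(),
         branch = character(), age_months = integer(),
         height_date = as.Date(character()), weight_date = as.Date(character()))
}

#' Build the research-ready data asset
#'
#' Runs the full staged pipeline: code-list extraction and unit
#' standardisation, plausibility filtering and deduplication (stage 1),
#' demographic exclusions and censoring windows (stage 2), height-weight
#' pairing, BMI derivation and category allocation (stage 3), same-day and
#' over-time inconsistency cleaning (stage 4), and hierarchy-based daily
#' selection with pregnancy flags (stage 5). Every raw record is accounted
#' for as kept, removed with a reason, or out of branch.
#'
#' @param inputs named list with tibbles `demographics`, `residency`,
#'   `wlgp_events`, `pedw_episodes`, `mids_records`, `ncch_records` (as read
#'   by [read_table()]).
#' @param reference growth-reference tibble spanning the configured child age
#'   range (see [read_reference()]).
#' @param codelists code list tibble (see [load_codelists()]).
#' @param cfg a [bmi_config()].
#' @return List of class `bmi_rrda_run` with elements `rrda`, `audit`,
#'   `decisions`, `flow`, `windows` (per-branch contribution windows),
#'   `accounting` and `persons` (the eligible demographics).
#' @export
build_rrda <- function(inputs, reference, codelists = example_codelist(),
                       cfg = bmi_config()) {
  required <- c("demographics", "residency", "wlgp_events", "pedw_episodes",
                "mids_records", "ncch_records")
  missing <- setdiff(required, names(inputs))
  if (length(missing)) {
    abort(paste0("missing input table(s): ", paste(missing, collapse = ", ")),
          class = "bmirrda_pipeline_error")
  }
  reference <- validate_reference(reference)
  rng <- range(reference$age_months)
  if (rng[1] > cfg$cyp_age_months[1] || rng[2] < cfg$cyp_age_months[2]) {
    abort("growth reference grid must span the configured child age range",
          class = "bmirrda_pipeline_error")
  }
  inputs <- add_record_ids(inputs)
  audit <- list()
  ledger <- list()
  note <- function(ids, outcome, reason) {
    if (length(ids)) {
      ledger[[length(ledger) + 1]] <<- tibble(record_id = ids,
                                              outcome = outcome,
                                              reason = reason)
    }
  }

  ## Stage 1: extraction, standardisation, plausibility, collation -----------
  events <- events_from_inputs(inputs)
  m <- match_events(events, codelists)
  audit$match <- m$audit
  note(setdiff(events$record_id, m$components$record_id),
       "removed", "unmatched_code")
  comp <- dplyr::bind_rows(
    m$components,
    measurements_to_components(inputs$mids_records, "MIDS"),
    measurements_to_components(inputs$ncch_records, "NCCH")
  )

  in_study <- comp$date >= cfg$study_start & comp$date <= cfg$study_end
  note(comp$record_id[!in_study], "removed", "outside_study")
  if (any(!in_study)) {
    audit$window <- audit_rows("extract", "outside_study",
                               comp$person_id[!in_study], comp$date[!in_study],
                               comp$source[!in_study])
  }
  comp <- comp[in_study, ]

  s <- standardise_units(comp)
  audit$standardise <- s$audit
  note(setdiff(comp$record_id, s$components$record_id),
       "removed", "unit_rejected")
  f <- filter_extremes(s$components, cfg)
  audit$extremes <- f$audit
  note(f$removed$record_id, "removed", "extreme_value")
  col <- collate(f$kept, cfg)
  audit$collate <- col$audit
  note(setdiff(f$kept$record_id, col$components$record_id),
       "removed", "exact_duplicate")
  comp <- col$components

  ## Stage 2: cohort ---------------------------------------------------------
  ex <- apply_exclusions(inputs$demographics, cfg)
  persons <- ex$persons
  eligible <- comp$person_id %in% persons$person_id
  note(comp$record_id[!eligible], "removed", "ineligible_person")
  if (any(!eligible)) {
    audit$ineligible <- audit_rows("cohort", "ineligible_person",
                                   comp$person_id[!eligible],
                                   comp$date[!eligible],
                                   comp$source[!eligible])
  }
  comp <- comp[eligible, ]
  res <- impute_residency(inputs$residency, cfg)
  audit$residency <- res$audit
  windows <- list(
    CYP = contribution_windows(persons, res$episodes, "CYP", cfg),
    adult = contribution_windows(persons, res$episodes, "adult", cfg)
  )
  wob <- setNames(persons$week_of_birth, persons$person_id)
  sex <- setNames(persons$sex, persons$person_id)

  ## Stage 3: entries --------------------------------------------------------
  entries <- list()

  direct <- comp[comp$component == "bmi_value", ]
  if (nrow(direct)) {
    entries$direct <- tibble(
      record_id = direct$record_id, person_id = direct$person_id,
      bmi_date = direct$date, bmi_value = direct$value,
      category = NA_character_, category_code = NA_integer_,
      source = direct$source, data_type = direct$data_type,
      rank = direct$rank, branch = NA_character_, age_months = NA_integer_,
      height_date = as.Date(NA), weight_date = as.Date(NA))
  }
  catonly <- comp[comp$component %in% c("bmi_category", "obesity_dx"), ]
  if (nrow(catonly)) {
    entries$catonly <- tibble(
      record_id = catonly$record_id, person_id = catonly$person_id,
      bmi_date = catonly$date, bmi_value = NA_real_,
      category = catonly$category, category_code = NA_integer_,
      source = catonly$source, data_type = catonly$data_type,
      rank = catonly$rank, branch = NA_character_, age_months = NA_integer_,
      height_date = as.Date(NA), weight_date = as.Date(NA))
  }

  hw <- comp[comp$component %in% c("height", "weight"), ]
  used_heights <- character(0)
  all_heights <- hw$record_id[hw$component == "height"]
  if (nrow(hw)) {
    pair_rows <- list()
    for (grp in split(hw, paste(hw$person_id, hw$source, sep = "\r"))) {
      pid <- grp$person_id[1]
      h <- grp[grp$component == "height", ]
      w <- grp[grp$component == "weight", ]
      if (nrow(w) == 0) next
      ages <- age_at(rep(wob[[pid]], nrow(w)), w$date)
      branch <- assign_branch(ages, cfg)
      note(w$record_id[is.na(branch)], "out_of_branch", "age_out_of_branch")
      for (br in c("CYP", "adult")) {
        wb <- w[!is.na(branch) & branch == br, ]
        if (nrow(wb) == 0) next
        pr <- if (br == "CYP") pair_cyp(h, wb, cfg) else pair_adult(h, wb, cfg)
        note(setdiff(wb$record_id, pr$weight_record_id),
             "removed", "unpaired_weight")
        if (nrow(pr) == 0) next
        used_heights <- c(used_heights, pr$height_record_id)
        pair_rows[[length(pair_rows) + 1]] <- fast_tbl(
          record_id = pr$weight_record_id, person_id = pid,
          bmi_date = pr$weight_date, bmi_value = pr$bmi_value,
          category = NA_character_, category_code = NA_integer_,
          source = grp$source[1], data_type = "height_weight",
          rank = assign_rank(grp$source[1], "height_weight", cfg$hierarchy),
          branch = br, age_months = NA_integer_,
          height_date = pr$height_date, weight_date = pr$weight_date)
      }
    }
    entries$paired <- dplyr::bind_rows(pair_rows)
  }
  note(intersect(all_heights, unique(used_heights)), "kept", "height_used")
  note(setdiff(all_heights, used_heights), "removed", "unpaired_height")

  e <- dplyr::bind_rows(entries)
  if (nrow(e) == 0) e <- empty_entries()

  if (nrow(e)) {
    e$age_months <- age_at(wob[e$person_id], e$bmi_date)
    need_branch <- is.na(e$branch)
    e$branch[need_branch] <- assign_branch(e$age_months[need_branch], cfg)
    note(e$record_id[is.na(e$branch)], "out_of_branch", "age_out_of_branch")
    e <- e[!is.na(e$branch), ]
  }

  # Harmonised categories: adult cut-points; child LMS z-scores.
  if (nrow(e)) {
    val <- !is.na(e$bmi_value)
    ad <- val & e$branch == "adult"
    e$category[ad] <- categorise_adult(e$bmi_value[ad], cfg$adult_cut_points)
    cy <- val & e$branch == "CYP"
    if (any(cy)) {
      lms <- reference_lookup(reference, sex[e$person_id[cy]], e$age_months[cy])
      z <- lms_zscore(e$bmi_value[cy], lms$L, lms$M, lms$S)
      e$category[cy] <- categorise_cyp(z, cyp_z_thresholds(cfg))
    }
    e$category_code <- encode_category(e$category)
  }

  ## Stage 4: two-stage cleaning ---------------------------------------------
  births <- mids_births(inputs$mids_records)
  sd <- same_day_clean(e, cfg)
  note(sd$removed$record_id, "removed", "same_day_conflict")
  ot <- over_time_clean(sd$kept, births, cfg)
  note(ot$removed$record_id, "removed", "over_time_conflict")
  decisions <- dplyr::bind_rows(sd$decisions, ot$decisions)

  ## Stage 5: daily selection and pregnancy flags ----------------------------
  daily <- select_daily_entry(ot$kept)
  note(setdiff(ot$kept$record_id, daily$record_id), "removed",
       "rank_not_selected")
  note(daily$record_id, "kept", "rrda_entry")
  daily <- flag_pregnancy(daily, births, cfg)

  rrda <- tibble(
    person_id = daily$person_id, bmi_date = daily$bmi_date,
    bmi_value = daily$bmi_value, category = daily$category,
    category_code = daily$category_code, source = daily$source,
    data_type = daily$data_type, rank = daily$rank, branch = daily$branch,
    age_months = daily$age_months, pregnancy_flag = daily$pregnancy_flag,
    height_date = daily$height_date, weight_date = daily$weight_date)
  rrda <- rrda[order(rrda$person_id, rrda$bmi_date), ]

  accounting <- dplyr::bind_rows(ledger)
  if (nrow(accounting) == 0) {
    accounting <- tibble(record_id = character(), outcome = character(),
                         reason = character())
  }
  out <- list(rrda = rrda,
              audit = dplyr::bind_rows(audit) %||% empty_audit(),
              decisions = decisions, flow = ex$flow, windows = windows,
              accounting = accounting, persons = persons)
  if (nrow(out$audit) == 0) out$audit <- empty_audit()
  class(out) <- "bmi_rrda_run"
  out
}

#' @export
print.bmi_rrda_run <- function(x, ...) {
  cat("<bmi_rrda_run>\n")
  cat("  RRDA entries :", nrow(x$rrda), "\n")
  cat("  persons      :", length(unique(x$rrda$person_id)), "with entries /",
      nrow(x$persons), "eligible\n")
  cat("  removed      :", sum(x$accounting$outcome == "removed"),
      "records;", nrow(x$decisions), "cleaning decisions\n")
  invisible(x)
}
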