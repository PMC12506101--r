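#' Match raw coded events against a code list
#'
#' Turns coded source events into BMI component records. Events whose
#' (`code`, `code_system`) pair appears in the code list become component
#' records typed by the list (`bmi_value`, `height`, `weight`,
#' `bmi_category`, `obesity_dx`); everything else is dropped and counted in
#' the audit log — an unlisted code is routine, not an error. Obesity
#' diagnoses and category codes receive the category implied by the list.
#'
#' @param events tibble with columns `record_id`, `person_id`, `event_date`,
#'   `source`, `code`, `code_system`, `numeric_value`, `unit`.
#' @param codelists validated code list (see [load_codelists()]).
#' @return List with `components` (pre-standardisation component records,
#'   keeping the raw `value`/`unit`) and `audit`.
#' @export
match_events <- function(events, codelists) {
  if (nrow(events) == 0) {
    return(list(components = empty_components(raw = TRUE), audit = empty_audit()))
  }
  matched <- dplyr::left_join(
    events, codelists, by = c("code", "code_system"))
  hit <- !is.na(matched$component)
  audit <- empty_audit()
  if (any(!hit)) {
    unmatched <- matched[!hit, ]
    audit <- audit_rows("extract", "unmatched_code",
                        person_id = unmatched$person_id,
                        date = unmatched$event_date,
                        source = unmatched$source)
  }
  comp <- matched[hit, ]
  components <- tibble(
    record_id = comp$record_id,
    person_id = comp$person_id,
    date = comp$event_date,
    component = comp$component,
    value = ifelse(comp$component %in% c("bmi_value", "height", "weight"),
                   comp$numeric_value, NA_real_),
    unit = comp$unit,
    category = comp$category_map,
    source = comp$source
  )
  list(components = components, audit = audit)
}

empty_components <- function(raw = FALSE) {
  base <- tibble(record_id = character(), person_id = character(),
                 date = as.Date(character()), component = character(),
                 value = numeric(), unit = character(), category = character(),
                 source = character())
  if (raw) return(base)
  base$unit <- NULL
  base$data_type <- character()
  base$rank <- integer()
  base
}

#' Convert structured measurement rows to component records
#'
#' Maternity and child-measurement tables record height and weight as
#' structured columns rather than coded events; each row yields up to two
#' component records (height, weight) sharing the row's date.
#'
#' @param records tibble in the `mids_records` or `ncch_records` schema with a
#'   `record_id` column.
#' @param source `"MIDS"` or `"NCCH"`.
#' @return Pre-standardisation component records.
#' @export
measurements_to_components <- function(records, source) {
  if (nrow(records) == 0) return(empty_components(raw = TRUE))
  pieces <- list()
  for (comp in c("height", "weight")) {
    vcol <- paste0(comp, "_value")
    ucol <- paste0(comp, "_unit")
    keep <- !is.na(records[[vcol]])
    if (!any(keep)) next
    r <- records[keep, ]
    pieces[[comp]] <- tibble(
      record_id = paste0(r$record_id, ":", substr(comp, 1, 1)),
      person_id = r$person_id,
      date = r$record_date,
      component = comp,
      value = r[[vcol]],
      unit = r[[ucol]],
      category = NA_character_,
      source = source
    )
  }
  if (length(pieces) == 0) return(empty_components(raw = TRUE))
  dplyr::bind_rows(pieces)
}

#' Standardise height and weight units
#'
#' Heights are expressed in metres and weights in kilograms. Explicit unit
#' strings are converted (`cm`, `mm` to metres; `g`, `lb`, `stone` to kg).
#' When the unit is absent a magnitude heuristic applies: a height above 3 is
#' read as centimetres (no standing height is ambiguous around 3 m), weights
#' pass through as kilograms. Applied heuristics, unknown units and
#' non-positive values are logged; the latter two reject the record.
#'
#' @param components pre-standardisation component records.
#' @return List with `components` (SI values, `unit` column dropped) and
#'   `audit`.
#' @export
standardise_units <- function(components) {
  if (nrow(components) == 0) {
    return(list(components = drop_unit(components), audit = empty_audit()))
  }
  x <- components
  audit <- list()
  is_meas <- x$component %in% c("height", "weight")
  reject <- rep(FALSE, nrow(x))

  nonpos <- is_meas & !is.na(x$value) & x$value <= 0
  if (any(nonpos)) {
    audit$nonpos <- audit_rows("standardise", "non_positive_value",
                               x$person_id[nonpos], x$date[nonpos],
                               x$source[nonpos])
    reject <- reject | nonpos
  }

  unit <- tolower(trimws(ifelse(is.na(x$unit), "", x$unit)))
  v <- x$value
  ok_h <- is_meas & x$component == "height" & !reject
  ok_w <- is_meas & x$component == "weight" & !reject

  conv <- rep(NA_real_, nrow(x))
  conv[ok_h & unit %in% c("", "m")] <- 1
  conv[ok_h & unit == "cm"] <- 1 / 100
  conv[ok_h & unit == "mm"] <- 1 / 1000
  conv[ok_w & unit %in% c("", "kg")] <- 1
  conv[ok_w & unit == "g"] <- 1 / 1000
  conv[ok_w & unit == "lb"] <- 0.45359237
  conv[ok_w & unit %in% c("st", "stone")] <- 6.35029318

  heur <- ok_h & unit == "" & !is.na(v) & v > 3
  conv[heur] <- 1 / 100
  if (any(heur)) {
    audit$heur <- audit_rows("standardise", "height_cm_heuristic",
                             x$person_id[heur], x$date[heur], x$source[heur])
  }

  unknown <- is_meas & !reject & is.na(conv)
  if (any(unknown)) {
    audit$unknown <- audit_rows("standardise", "unknown_unit",
                                x$person_id[unknown], x$date[unknown],
                                x$source[unknown])
    reject <- reject | unknown
  }

  x$value[is_meas & !reject] <- v[is_meas & !reject] * conv[is_meas & !reject]
  out <- drop_unit(x[!reject, ])
  audit <- if (length(audit)) dplyr::bind_rows(audit) else empty_audit()
  list(components = out, audit = audit)
}

drop_unit <- function(x) x[setdiff(names(x), "unit")]

#' Remove implausible values
#'
#' BMI values strictly below `bmi_min` or strictly above `bmi_max` are
#' removed (boundary values are kept); heights and weights outside the
#' configured plausibility bounds are removed. The input partitions exactly
#' into `kept` and `removed`.
#'
#' @param components standardised component records.
#' @param cfg a [bmi_config()].
#' @return List with `kept`, `removed` and `audit`.
#' @export
filter_extremes <- function(components, cfg) {
  x <- components
  bad <- rep(FALSE, nrow(x))
  v <- x$value
  bad[x$component == "bmi_value" & !is.na(v) &
        (v < cfg$bmi_min | v > cfg$bmi_max)] <- TRUE
  hb <- cfg$height_bounds_m
  bad[x$component == "height" & !is.na(v) & (v < hb[1] | v > hb[2])] <- TRUE
  wb <- cfg$weight_bounds_kg
  bad[x$component == "weight" & !is.na(v) & (v < wb[1] | v > wb[2])] <- TRUE
  bad[x$component %in% c("bmi_value", "height", "weight") & is.na(v)] <- TRUE
  removed <- x[bad, ]
  audit <- if (nrow(removed)) {
    audit_rows("extract", "extreme_value", removed$person_id, removed$date,
               removed$source)
  } else empty_audit()
  list(kept = x[!bad, ], removed = removed, audit = audit)
}

#' Look up hierarchy ranks
#'
#' @param source,data_type character vectors (recycled to common length).
#' @param hierarchy hierarchy table (see [default_hierarchy()]).
#' @return Integer ranks.
#' @export
assign_rank <- function(source, data_type, hierarchy = default_hierarchy()) {
  key <- paste(source, data_type, sep = "/")
  hkey <- paste(hierarchy$source, hierarchy$data_type, sep = "/")
  idx <- match(key, hkey)
  if (anyNA(idx)) {
    abort(paste0("no hierarchy rank for (source, data_type) pair(s): ",
                 paste(unique(key[is.na(idx)]), collapse = ", ")),
          class = "bmirrda_rank_error")
  }
  as.integer(hierarchy$rank[idx])
}

component_data_type <- function(component) {
  dplyr::case_match(component,
    "bmi_value" ~ "bmi_value",
    c("height", "weight") ~ "height_weight",
    "bmi_category" ~ "bmi_category",
    "obesity_dx" ~ "obese_category"
  )
}

#' Collate component records into one longitudinal table
#'
#' Attaches the hierarchy rank to every record, sorts by person, date and
#' rank, and collapses exact duplicates (all fields equal apart from the
#' record identifier) to a single record, keeping the first in input order
#' and recording the multiplicity in the audit log. Same-day records from
#' different sources are deliberately retained.
#'
#' @param components standardised, filtered component records.
#' @param cfg a [bmi_config()].
#' @return List with `components` (ranked, deduplicated, sorted) and `audit`.
#' @export
collate <- function(components, cfg = bmi_config()) {
  if (nrow(components) == 0) {
    return(list(components = empty_components(), audit = empty_audit()))
  }
  x <- components
  x$data_type <- component_data_type(x$component)
  x$rank <- assign_rank(x$source, x$data_type, cfg$hierarchy)
  key <- paste(x$person_id, x$date, x$component,
               format(x$value, digits = 17), x$category, x$source, sep = "\r")
  dup <- duplicated(key)
  audit <- empty_audit()
  if (any(dup)) {
    tab <- table(key)
    multi <- tab[tab > 1]
    idx_first <- match(names(multi), key)
    audit <- audit_rows("extract", "exact_duplicate",
                        person_id = x$person_id[idx_first],
                        date = x$date[idx_first],
                        source = x$source[idx_first],
                        count = as.integer(multi))
  }
  x <- x[!dup, ]
  x <- x[order(x$person_id, x$date, x$rank, x$component,
               xtfrm(x$value)), ]
  list(components = x, audit = audit)
}
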