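#' @keywords internal
#' Declared input/output schemas: column name -> type tag.
#' Types: c = character, d = double, i = integer, D = ISO date, l = logical.
.schemas <- list(
  demographics = c(person_id = "c", sex = "c", week_of_birth = "D",
                   date_of_death = "D", linkage_status = "i"),
  residency = c(person_id = "c", start_date = "D", end_date = "D"),
  wlgp_events = c(person_id = "c", event_date = "D", code = "c",
                  numeric_value = "d", unit = "c"),
  pedw_episodes = c(person_id = "c", admission_date = "D", code = "c"),
  mids_records = c(person_id = "c", record_date = "D", height_value = "d",
                   height_unit = "c", weight_value = "d", weight_unit = "c",
                   baby_birth_date = "D"),
  ncch_records = c(person_id = "c", record_date = "D", height_value = "d",
                   height_unit = "c", weight_value = "d", weight_unit = "c"),
  rrda = c(person_id = "c", bmi_date = "D", bmi_value = "d", category = "c",
           category_code = "i", source = "c", data_type = "c", rank = "i",
           branch = "c", age_months = "i", pregnancy_flag = "l",
           height_date = "D", weight_date = "D")
)

parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & nzchar(x)
  well_formed <- ok & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[well_formed] <- as.Date(x[well_formed], format = "%Y-%m-%d")
  bad <- ok & (!well_formed | (well_formed & is.na(parsed)))
  attr(out, "bad_rows") <- which(bad)
  out[well_formed] <- parsed[well_formed]
  out
}

#' Read one of the declared input tables
#'
#' Parses a header-bearing comma-delimited file against one of the declared
#' schemas (`demographics`, `residency`, `wlgp_events`, `pedw_episodes`,
#' `mids_records`, `ncch_records`, `rrda`). Dates must be ISO-8601 calendar
#' dates (`YYYY-MM-DD`); rows with unparseable dates or numbers are collected
#' and reported with their row numbers rather than silently dropped.
#'
#' @param path file path.
#' @param schema_name one of the schema names above.
#' @return Tibble with typed columns in schema order.
#' @export
read_table <- function(path, schema_name) {
  schema <- .schemas[[schema_name]]
  if (is.null(schema)) {
    abort(paste0("unknown schema: ", schema_name), class = "bmirrda_io_error")
  }
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "bmirrda_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    abort(paste0("table '", schema_name, "' missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "bmirrda_io_error")
  }
  problems <- character(0)
  out <- vector("list", length(schema))
  names(out) <- names(schema)
  for (col in names(schema)) {
    x <- raw[[col]]
    x[!is.na(x) & x == ""] <- NA_character_
    out[[col]] <- switch(
      schema[[col]],
      c = x,
      d = {
        v <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & is.na(v))
        if (length(bad)) {
          problems <- c(problems, paste0(
            "column '", col, "': non-numeric value at row(s) ",
            paste(bad, collapse = ", ")))
        }
        v
      },
      i = {
        v <- suppressWarnings(as.integer(x))
        bad <- which(!is.na(x) & is.na(v))
        if (length(bad)) {
          problems <- c(problems, paste0(
            "column '", col, "': non-integer value at row(s) ",
            paste(bad, collapse = ", ")))
        }
        v
      },
      D = {
        v <- parse_iso_date(x)
        bad <- attr(v, "bad_rows")
        if (length(bad)) {
          problems <- c(problems, paste0(
            "column '", col, "': invalid ISO date at row(s) ",
            paste(bad, collapse = ", ")))
        }
        attr(v, "bad_rows") <- NULL
        v
      },
      l = {
        v <- as.logical(x)
        bad <- which(!is.na(x) & is.na(v))
        if (length(bad)) {
          problems <- c(problems, paste0(
            "column '", col, "': non-logical value at row(s) ",
            paste(bad, collapse = ", ")))
        }
        v
      }
    )
  }
  if (length(problems)) {
    abort(paste0("parse errors in '", path, "' (schema ", schema_name, "):\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "bmirrda_io_error")
  }
  tbl <- as_tibble(out)
  if (schema_name == "demographics" && anyDuplicated(tbl$person_id)) {
    dups <- unique(tbl$person_id[duplicated(tbl$person_id)])
    abort(paste0("duplicate person_id in demographics: ",
                 paste(head(dups, 5), collapse = ", ")),
          class = "bmirrda_io_error")
  }
  tbl
}

#' Write one of the declared tables
#'
#' @param tbl tibble matching the named schema.
#' @param path output path.
#' @param schema_name schema the table claims to follow.
#' @export
write_table <- function(tbl, path, schema_name) {
  schema <- .schemas[[schema_name]]
  if (is.null(schema)) {
    abort(paste0("unknown schema: ", schema_name), class = "bmirrda_io_error")
  }
  missing <- setdiff(names(schema), names(tbl))
  if (length(missing)) {
    abort(paste0("cannot write '", schema_name, "': missing column(s) ",
                 paste(missing, collapse = ", ")),
          class = "bmirrda_io_error")
  }
  readr::write_csv(tbl[names(schema)], path, progress = FALSE)
  invisible(path)
}

#' Write a research-ready data asset
#'
#' Serialises the harmonised one-entry-per-person-per-day table. The
#' single-entry contract is enforced: two rows sharing (`person_id`,
#' `bmi_date`) are refused. Column order is stable and part of the public
#' contract; [read_rrda()] reproduces the table exactly.
#'
#' @param entries RRDA tibble (see the `rrda` schema).
#' @param path output path.
#' @export
write_rrda <- function(entries, path) {
  if (nrow(entries) > 0) {
    key <- paste(entries$person_id, entries$bmi_date, sep = "\r")
    if (anyDuplicated(key)) {
      dups <- entries[duplicated(key), c("person_id", "bmi_date")]
      abort(paste0("RRDA must hold a single entry per person per day; duplicated: ",
                   paste(head(paste(dups$person_id, dups$bmi_date), 3),
                         collapse = "; ")),
            class = "bmirrda_io_error")
    }
  }
  write_table(entries, path, "rrda")
}

#' Read a research-ready data asset
#'
#' @param path path written by [write_rrda()].
#' @return RRDA tibble.
#' @export
read_rrda <- function(path) {
  tbl <- read_table(path, "rrda")
  key <- paste(tbl$person_id, tbl$bmi_date, sep = "\r")
  if (anyDuplicated(key)) {
    abort("invalid RRDA: duplicate (person_id, bmi_date) rows",
          class = "bmirrda_io_error")
  }
  tbl
}

# Empty audit-log scaffold; audit rows accumulate as (stage, reason, person_id,
# date, source, count).
empty_audit <- function() {
  tibble(stage = character(), reason = character(), person_id = character(),
         date = as.Date(character()), source = character(), count = integer())
}

audit_rows <- function(stage, reason, person_id = NA_character_,
                       date = as.Date(NA), source = NA_character_,
                       count = 1L) {
  if (length(person_id) == 0) return(empty_audit())
  tibble(stage = stage, reason = reason, person_id = person_id,
         date = as.Date(date), source = source, count = as.integer(count))
}

#' Write an audit log
#'
#' @param audit audit tibble accumulated by the pipeline stages.
#' @param path output path.
#' @export
write_audit <- function(audit, path) {
  readr::write_csv(audit, path, progress = FALSE)
  invisible(path)
}
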