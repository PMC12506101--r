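year_bounds <- function(year) {
  list(start = as.Date(paste0(year, "-01-01")),
       end = as.Date(paste0(year, "-12-31")))
}

#' Annual coverage of BMI records
#'
#' For each study year and branch: the number of persons whose contribution
#' window intersects the year (denominator), the number with at least one
#' harmonised entry dated in that year, the resulting proportion and
#' missingness, and the category tally of each covered person's most recent
#' entry of the year.
#'
#' @param rrda harmonised RRDA tibble.
#' @param windows list with `CYP` and `adult` contribution-window tibbles
#'   (see [contribution_windows()]).
#' @param years integer vector of years to report; must lie inside the study.
#' @param cfg a [bmi_config()].
#' @return Tibble with one row per (year, branch), category counts in
#'   columns `n_underweight` .. `n_obese`.
#' @export
annual_coverage <- function(rrda, windows, years = NULL, cfg = bmi_config()) {
  study_years <- seq(lubridate::year(cfg$study_start),
                     lubridate::year(cfg$study_end))
  years <- years %||% study_years
  if (any(!(years %in% study_years))) {
    abort("requested year outside the study period",
          class = "bmirrda_metrics_error")
  }
  rows <- list()
  for (br in c("CYP", "adult")) {
    w <- windows[[br]]
    e <- rrda[rrda$branch == br, ]
    for (y in years) {
      yb <- year_bounds(y)
      denom <- sum(w$entry_date <= yb$end & w$exit_date >= yb$start)
      ey <- e[e$bmi_date >= yb$start & e$bmi_date <= yb$end, ]
      ey <- ey[order(ey$person_id, ey$bmi_date), ]
      latest <- ey[!duplicated(ey$person_id, fromLast = TRUE), ]
      ncov <- nrow(latest)
      tally <- table(factor(latest$category, levels = .categories))
      rows[[length(rows) + 1]] <- tibble(
        year = y, branch = br, denominator = denom, covered = ncov,
        proportion = if (denom > 0) ncov / denom else 0,
        missingness = if (denom > 0) 1 - ncov / denom else 1,
        n_underweight = as.integer(tally[["underweight"]]),
        n_normal = as.integer(tally[["normal"]]),
        n_overweight = as.integer(tally[["overweight"]]),
        n_obese = as.integer(tally[["obese"]]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Preservation-window coverage
#'
#' Fixes the denominator to the persons present at the anchor date (by
#' default the study end) and asks, for each look-back window, how many of
#' them have at least one entry dated inside the window — i.e. how much
#' coverage survives when only records from the last year, the last five
#' years, or the whole study are preserved.
#'
#' @param rrda harmonised RRDA tibble.
#' @param windows per-branch contribution windows.
#' @param window_starts `Date` vector of window start dates (default: one
#'   year back, five years back, and the study start).
#' @param anchor anchor date (default study end).
#' @param cfg a [bmi_config()].
#' @return Tibble (`branch`, `window_label`, `window_start`, `anchor`,
#'   `denominator`, `covered`, `proportion`).
#' @export
preservation_coverage <- function(rrda, windows, window_starts = NULL,
                                  anchor = NULL, cfg = bmi_config()) {
  anchor <- as.Date(anchor %||% cfg$study_end)
  window_starts <- as.Date(window_starts %||% c(
    anchor - lubridate::years(1) + 1, anchor - lubridate::years(5) + 1,
    cfg$study_start))
  if (any(window_starts > anchor)) {
    abort("preservation window start after the anchor date",
          class = "bmirrda_metrics_error")
  }
  labels <- names(window_starts) %||%
    paste0(round(as.numeric(anchor - window_starts) / 365.25, 1), "y")
  rows <- list()
  for (br in c("CYP", "adult")) {
    w <- windows[[br]]
    denom_ids <- w$person_id[w$entry_date <= anchor & w$exit_date >= anchor]
    e <- rrda[rrda$branch == br & rrda$person_id %in% denom_ids, ]
    for (k in seq_along(window_starts)) {
      ids <- unique(e$person_id[e$bmi_date >= window_starts[k] &
                                  e$bmi_date <= anchor])
      rows[[length(rows) + 1]] <- tibble(
        branch = br, window_label = labels[k], window_start = window_starts[k],
        anchor = anchor, denominator = length(denom_ids),
        covered = length(ids),
        proportion = if (length(denom_ids) > 0) {
          length(ids) / length(denom_ids)
        } else 0)
    }
  }
  dplyr::bind_rows(rows)
}

#' Repeat-measurement statistics
#'
#' Distribution, per branch, of the number of distinct calendar years in
#' which each person has at least one harmonised entry, with a summary count
#' of persons recorded in five or more distinct years.
#'
#' @param rrda harmonised RRDA tibble.
#' @return List with `histogram` (tibble `branch`, `n_years`, `persons`) and
#'   `five_plus` (named integer per branch).
#' @export
repeat_measurement_stats <- function(rrda) {
  if (nrow(rrda) == 0) {
    return(list(histogram = tibble(branch = character(), n_years = integer(),
                                   persons = integer()),
                five_plus = c(CYP = 0L, adult = 0L)))
  }
  x <- tibble(person_id = rrda$person_id, branch = rrda$branch,
              year = lubridate::year(rrda$bmi_date))
  per_person <- x |>
    dplyr::distinct() |>
    dplyr::count(.data$branch, .data$person_id, name = "n_years")
  hist <- per_person |>
    dplyr::count(.data$branch, .data$n_years, name = "persons") |>
    dplyr::arrange(.data$branch, .data$n_years)
  fp <- vapply(c(CYP = "CYP", adult = "adult"), function(br) {
    sum(per_person$n_years[per_person$branch == br] >= 5L)
  }, integer(1))
  list(histogram = hist, five_plus = fp)
}

#' Source-overlap counts
#'
#' Assigns every person with at least one entry to the exact subset of
#' sources their entries come from (the disjoint combination counts of an
#' upset plot), together with unconditional per-source marginal counts.
#'
#' @param rrda harmonised RRDA tibble.
#' @return List with `subsets` (tibble `subset`, `persons`; subsets sum to
#'   the covered population) and `marginals` (named integer per source).
#' @export
source_overlap_counts <- function(rrda) {
  if (nrow(rrda) == 0) {
    return(list(subsets = tibble(subset = character(), persons = integer()),
                marginals = setNames(integer(length(.sources)), .sources)))
  }
  per_person <- split(rrda$source, rrda$person_id)
  subset_of <- vapply(per_person, function(s) {
    paste(sort(unique(s)), collapse = "+")
  }, character(1))
  tab <- sort(table(subset_of), decreasing = TRUE)
  marginals <- vapply(setNames(.sources, .sources), function(src) {
    sum(vapply(per_person, function(s) src %in% s, logical(1)))
  }, integer(1))
  list(subsets = tibble(subset = names(tab), persons = as.integer(tab)),
       marginals = marginals)
}
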