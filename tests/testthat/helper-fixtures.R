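# Shared fixture builders: everything is generated in code, no stored data.

# A scenario small enough for per-test pipeline runs.
small_scenario <- function(seed = 1L, n = 60L, rates = list()) {
  scenario_config(n_persons = n, seed = seed, study_start = "2013-01-01",
                  study_end = "2022-12-31", rates = rates)
}

# Candidate-entry tibble in the shape stage 4 consumes.
make_entries <- function(bmi_value, category = NULL, person_id = "P1",
                         bmi_date = as.Date("2010-06-01"), source = "WLGP",
                         data_type = NULL, rank = NULL, branch = "adult",
                         age_months = 480L) {
  n <- max(length(bmi_value), length(category), length(bmi_date))
  bmi_value <- rep_len(bmi_value, n)
  if (is.null(category)) {
    category <- categorise_adult(bmi_value)
    category[is.na(bmi_value)] <- NA
  } else {
    category <- rep_len(category, n)
  }
  if (is.null(data_type)) {
    data_type <- ifelse(is.na(bmi_value), "bmi_category", "bmi_value")
  }
  if (is.null(rank)) rank <- ifelse(data_type == "bmi_value", 1L, 5L)
  tibble::tibble(
    record_id = paste0("R", seq_len(n)),
    person_id = rep_len(person_id, n),
    bmi_date = rep(bmi_date, length.out = n),
    bmi_value = bmi_value,
    category = category,
    category_code = encode_category(category),
    source = rep_len(source, n),
    data_type = rep_len(data_type, n),
    rank = rep_len(as.integer(rank), n),
    branch = rep_len(branch, n),
    age_months = rep_len(as.integer(age_months), n),
    height_date = rep(as.Date(NA), n),
    weight_date = rep(as.Date(NA), n)
  )
}

# Minimal empty input tables in the declared schemas.
empty_inputs <- function() {
  list(
    demographics = tibble::tibble(person_id = character(), sex = character(),
                                  week_of_birth = as.Date(character()),
                                  date_of_death = as.Date(character()),
                                  linkage_status = integer()),
    residency = tibble::tibble(person_id = character(),
                               start_date = as.Date(character()),
                               end_date = as.Date(character())),
    wlgp_events = tibble::tibble(person_id = character(),
                                 event_date = as.Date(character()),
                                 code = character(), numeric_value = numeric(),
                                 unit = character()),
    pedw_episodes = tibble::tibble(person_id = character(),
                                   admission_date = as.Date(character()),
                                   code = character()),
    mids_records = tibble::tibble(person_id = character(),
                                  record_date = as.Date(character()),
                                  height_value = numeric(),
                                  height_unit = character(),
                                  weight_value = numeric(),
                                  weight_unit = character(),
                                  baby_birth_date = as.Date(character())),
    ncch_records = tibble::tibble(person_id = character(),
                                  record_date = as.Date(character()),
                                  height_value = numeric(),
                                  height_unit = character(),
                                  weight_value = numeric(),
                                  weight_unit = character())
  )
}

# One eligible adult with a single clean primary-care BMI value.
one_person_inputs <- function(bmi = 27.3, event_date = "2015-06-01") {
  inp <- empty_inputs()
  inp$demographics <- tibble::tibble(
    person_id = "P1", sex = "female", week_of_birth = as.Date("1980-01-07"),
    date_of_death = as.Date(NA), linkage_status = 1L)
  inp$residency <- tibble::tibble(person_id = "P1",
                                  start_date = as.Date(NA),
                                  end_date = as.Date(NA))
  inp$wlgp_events <- tibble::tibble(
    person_id = "P1", event_date = as.Date(event_date), code = "22K..",
    numeric_value = bmi, unit = NA_character_)
  inp
}

# Exhaustive pairwise same-day oracle, written independently of the package
# implementation: marks every entry participating in a violating pair.
oracle_same_day <- function(values, codes, tol = 0.05) {
  n <- length(values)
  bad <- rep(FALSE, n)
  if (n < 2) return(bad)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      vi <- values[i]; vj <- values[j]
      if (!is.na(vi) && !is.na(vj)) {
        violate <- (abs(vi - vj) / min(vi, vj)) >= tol || codes[i] != codes[j]
      } else {
        violate <- codes[i] != codes[j]
      }
      if (violate) bad[c(i, j)] <- TRUE
    }
  }
  bad
}

expect_same_rrda <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
}
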