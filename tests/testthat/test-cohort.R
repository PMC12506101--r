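test_that("ages count completed months from the Monday anchor", {
  # 2000-01-03 is a Monday
  expect_equal(age_at(as.Date("2000-01-03"), as.Date("2002-01-03")), 24L)
  expect_equal(age_at(as.Date("2000-01-03"), as.Date("2002-01-02")), 23L)
  expect_error(age_at(as.Date("2000-01-03"), as.Date("1999-12-01")),
               class = "bmirrda_cohort_error")
  # anchoring: any day of the week maps to its Monday
  expect_equal(age_at(as.Date("2000-01-06"), as.Date("2002-01-03")), 24L)
})

test_that("branch assignment is closed on both age intervals, child first", {
  cfg <- bmi_config()
  expect_equal(assign_branch(30L, cfg), "CYP")
  expect_equal(assign_branch(18L, cfg), NA_character_)
  expect_equal(assign_branch(45L * 12L, cfg), "adult")
  expect_equal(assign_branch(c(24L, 228L), cfg), c("CYP", "CYP"))
  expect_equal(assign_branch(229L, cfg), "adult")
  expect_equal(assign_branch(101L * 12L, cfg), NA_character_)
  expect_equal(assign_branch(100L * 12L + 11L, cfg), "adult")
})

random_demographics <- function(n, cfg) {
  tibble::tibble(
    person_id = sprintf("R%03d", seq_len(n)),
    sex = sample(c("female", "male", "9", NA), n, TRUE,
                 prob = c(0.45, 0.45, 0.05, 0.05)),
    week_of_birth = cfg$study_start -
      sample(c(NA, 1000:20000), n, TRUE),
    date_of_death = cfg$study_start +
      sample(c(rep(NA, 5), -100:8000), n, TRUE),
    linkage_status = sample(c(1L, 4L, 39L, 99L), n, TRUE,
                            prob = c(0.4, 0.3, 0.2, 0.1))
  )
}

test_that("exclusions follow the fixed order and examples", {
  cfg <- bmi_config()
  persons <- tibble::tibble(
    person_id = c("ok", "no_wob", "early_dod", "late_enough"),
    sex = "female",
    week_of_birth = as.Date(c("1980-01-07", NA, "1980-01-07", "1980-01-07")),
    date_of_death = c(as.Date(NA), as.Date(NA),
                      cfg$study_start + 10, cfg$study_start + 60),
    linkage_status = 1L)
  ex <- apply_exclusions(persons, cfg)
  expect_setequal(ex$persons$person_id, c("ok", "late_enough"))
  expect_equal(ex$flow$removed[ex$flow$label == "missing_wob"], 1L)
  expect_equal(ex$flow$removed[ex$flow$label == "dod_within_min_residency"], 1L)
})

test_that("exclusion flow telescopes on random cohorts", {
  cfg <- bmi_config()
  set.seed(5)
  for (i in 1:40) {
    ex <- apply_exclusions(random_demographics(sample(1:80, 1), cfg), cfg)
    fl <- ex$flow
    expect_equal(fl$remaining[1] - sum(fl$removed), nrow(ex$persons))
    expect_true(all(diff(fl$remaining) <= 0))
    expect_equal(fl$removed[-1] + fl$remaining[-1], fl$remaining[-nrow(fl)])
  }
})

test_that("residency imputation fills missing dates with the study bounds", {
  cfg <- bmi_config()
  eps <- tibble::tibble(
    person_id = c("a", "b", "c"),
    start_date = as.Date(c(NA, NA, "2023-06-01")),
    end_date = as.Date(c("2010-05-01", NA, "2023-12-01")))
  imp <- impute_residency(eps, cfg)
  expect_equal(imp$episodes$start_date[1], cfg$study_start)
  expect_equal(imp$episodes$end_date[1], as.Date("2010-05-01"))
  expect_equal(imp$episodes$end_date[2], cfg$study_end)
  expect_false("c" %in% imp$episodes$person_id)  # entirely after the study
  expect_equal(imp$audit$reason, "residency_outside_study")
})

test_that("contribution windows censor at the binding constraint", {
  cfg <- bmi_config()
  persons <- tibble::tibble(
    person_id = c("adult_full", "adult_dies", "child_turns19"),
    sex = "male",
    week_of_birth = as.Date(c("1960-02-01", "1960-02-01", "1992-05-04")),
    date_of_death = as.Date(c(NA, "2011-08-15", NA)),
    linkage_status = 1L)
  eps <- impute_residency(
    tibble::tibble(person_id = persons$person_id,
                   start_date = as.Date(NA), end_date = as.Date(NA)),
    cfg)$episodes
  w <- contribution_windows(persons, eps, "adult", cfg)
  expect_equal(w$entry_date[w$person_id == "adult_full"], cfg$study_start)
  expect_equal(w$exit_date[w$person_id == "adult_full"], cfg$study_end)
  expect_equal(w$exit_reason[w$person_id == "adult_full"], "study_end")
  expect_equal(w$exit_date[w$person_id == "adult_dies"],
               as.Date("2011-08-15"))
  expect_equal(w$exit_reason[w$person_id == "adult_dies"], "death")

  wc <- contribution_windows(persons, eps, "CYP", cfg)
  # born 1992-05-04 (a Monday): 19th birthday 2011-05-04, exit the day before
  expect_equal(wc$exit_date[wc$person_id == "child_turns19"],
               as.Date("2011-05-03"))
  expect_equal(wc$exit_reason[wc$person_id == "child_turns19"], "turned_19")
  # the two adults were already over 18 at study start: their CYP window is empty
  expect_setequal(wc$person_id, "child_turns19")
})

test_that("person-time is non-negative and bounded by the study length", {
  cfg <- bmi_config()
  set.seed(9)
  study_len <- as.numeric(cfg$study_end - cfg$study_start)
  for (i in 1:20) {
    demo <- random_demographics(30, cfg)
    demo <- apply_exclusions(demo, cfg)$persons
    eps <- impute_residency(
      tibble::tibble(person_id = demo$person_id,
                     start_date = cfg$study_start +
                       sample(c(NA, 0:5000), nrow(demo), TRUE),
                     end_date = cfg$study_start +
                       sample(c(NA, 3000:9000), nrow(demo), TRUE)),
      cfg)$episodes
    for (br in c("CYP", "adult")) {
      w <- contribution_windows(demo, eps, br, cfg)
      pt <- as.numeric(w$exit_date - w$entry_date)
      expect_true(all(pt >= 0))
      expect_true(all(pt <= study_len))
      expect_true(all(w$entry_date >= cfg$study_start))
      expect_true(all(w$exit_date <= cfg$study_end))
    }
  }
})
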