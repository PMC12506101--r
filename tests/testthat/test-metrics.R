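# A small deterministic asset and matching windows, built directly.
metrics_fixture <- function() {
  cfg <- bmi_config(study_start = "2015-01-01", study_end = "2022-12-31")
  rrda <- tibble::tibble(
    person_id = c("A", "A", "A", "B", "C", "C"),
    bmi_date = as.Date(c("2018-03-01", "2018-11-05", "2020-06-01",
                          "2019-12-31", "2018-05-05", "2022-02-01")),
    bmi_value = c(24, 26, 27, 23, NA, 31),
    category = c("normal", "overweight", "overweight", "normal",
                 "obese", "obese"),
    category_code = c(2L, 3L, 3L, 2L, 4L, 4L),
    source = c("WLGP", "NCCH", "WLGP", "WLGP", "PEDW", "WLGP"),
    data_type = c("bmi_value", "height_weight", "bmi_value", "bmi_value",
                  "obese_category", "bmi_value"),
    rank = c(1L, 4L, 1L, 1L, 6L, 1L),
    branch = "adult",
    age_months = 480L,
    pregnancy_flag = FALSE,
    height_date = as.Date(NA), weight_date = as.Date(NA))
  windows <- list(
    CYP = tibble::tibble(person_id = character(),
                         entry_date = as.Date(character()),
                         exit_date = as.Date(character()),
                         exit_reason = character()),
    adult = tibble::tibble(
      person_id = c("A", "B", "C", "D"),
      entry_date = as.Date(c("2015-01-01", "2015-01-01", "2015-01-01",
                              "2015-01-01")),
      exit_date = as.Date(c("2022-12-31", "2019-06-30", "2022-12-31",
                             "2022-12-31")),
      exit_reason = c("study_end", "moved_out", "study_end", "study_end")))
  list(cfg = cfg, rrda = rrda, windows = windows)
}

test_that("annual coverage counts persons once, by their latest record", {
  fx <- metrics_fixture()
  cov <- annual_coverage(fx$rrda, fx$windows, years = 2018, cfg = fx$cfg)
  adult <- cov[cov$branch == "adult", ]
  expect_equal(adult$denominator, 4L)     # D is resident but recordless
  expect_equal(adult$covered, 2L)         # A (twice, counted once) and C
  expect_equal(adult$proportion, 0.5)
  expect_equal(adult$missingness, 0.5)
  # A's latest 2018 record is the November overweight one
  expect_equal(adult$n_overweight, 1L)
  expect_equal(adult$n_obese, 1L)
  expect_equal(adult$n_normal, 0L)
  expect_equal(adult$n_underweight +  adult$n_normal + adult$n_overweight +
                 adult$n_obese, adult$covered)

  expect_error(annual_coverage(fx$rrda, fx$windows, years = 1999,
                               cfg = fx$cfg),
               class = "bmirrda_metrics_error")

  empty <- annual_coverage(fx$rrda[0, ], fx$windows, years = 2018,
                           cfg = fx$cfg)
  expect_true(all(empty$covered == 0))
  expect_true(all(empty$proportion == 0))
})

test_that("denominators track the contribution windows", {
  fx <- metrics_fixture()
  cov <- annual_coverage(fx$rrda, fx$windows, years = 2020, cfg = fx$cfg)
  adult <- cov[cov$branch == "adult", ]
  expect_equal(adult$denominator, 3L)  # B exited mid-2019
})

test_that("preservation windows nest and widen monotonically", {
  fx <- metrics_fixture()
  pres <- preservation_coverage(fx$rrda, fx$windows, cfg = fx$cfg)
  adult <- pres[pres$branch == "adult", ]
  # denominator: persons present at the anchor (A, C, D)
  expect_true(all(adult$denominator == 3L))
  # C's 2022 entry is in all three windows; A's 2020 entry only in the
  # five-year and full windows
  expect_equal(adult$covered, c(1L, 2L, 2L))
  expect_true(all(diff(adult$proportion) >= 0))

  expect_error(
    preservation_coverage(fx$rrda, fx$windows,
                          window_starts = as.Date("2023-06-01"),
                          cfg = fx$cfg),
    class = "bmirrda_metrics_error")
})

test_that("preservation monotonicity holds on random assets", {
  fx <- metrics_fixture()
  set.seed(71)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    rr <- tibble::tibble(
      person_id = sample(LETTERS[1:8], n, TRUE),
      bmi_date = fx$cfg$study_start +
        sample.int(as.numeric(fx$cfg$study_end - fx$cfg$study_start), n),
      bmi_value = runif(n, 15, 45), category = "normal", category_code = 2L,
      source = "WLGP", data_type = "bmi_value", rank = 1L, branch = "adult",
      age_months = 480L, pregnancy_flag = FALSE,
      height_date = as.Date(NA), weight_date = as.Date(NA))
    rr <- rr[!duplicated(paste(rr$person_id, rr$bmi_date)), ]
    w <- list(CYP = fx$windows$CYP,
              adult = tibble::tibble(person_id = LETTERS[1:8],
                                     entry_date = fx$cfg$study_start,
                                     exit_date = fx$cfg$study_end,
                                     exit_reason = "study_end"))
    pres <- preservation_coverage(rr, w, cfg = fx$cfg)
    for (br in unique(pres$branch)) {
      expect_true(all(diff(pres$proportion[pres$branch == br]) >= 0))
    }
  }
})

test_that("repeat-measurement statistics count distinct years", {
  fx <- metrics_fixture()
  st <- repeat_measurement_stats(fx$rrda)
  ha <- st$histogram[st$histogram$branch == "adult", ]
  expect_equal(ha$persons[ha$n_years == 2], 2L)  # A (2018, 2020), C (2018, 2022)
  expect_equal(ha$persons[ha$n_years == 1], 1L)  # B
  expect_equal(unname(st$five_plus["adult"]), 0L)

  many <- tibble::tibble(
    person_id = "Z", bmi_date = as.Date(paste0(2010:2016, "-06-01")),
    bmi_value = 25, category = "overweight", category_code = 3L,
    source = "WLGP", data_type = "bmi_value", rank = 1L, branch = "adult",
    age_months = 480L, pregnancy_flag = FALSE,
    height_date = as.Date(NA), weight_date = as.Date(NA))
  expect_equal(unname(repeat_measurement_stats(many)$five_plus["adult"]), 1L)

  empty <- repeat_measurement_stats(fx$rrda[0, ])
  expect_equal(nrow(empty$histogram), 0)
})

test_that("source overlaps partition the covered population", {
  fx <- metrics_fixture()
  ov <- source_overlap_counts(fx$rrda)
  expect_equal(sum(ov$subsets$persons), 3L)
  expect_equal(ov$subsets$persons[ov$subsets$subset == "NCCH+WLGP"], 1L)
  expect_equal(ov$subsets$persons[ov$subsets$subset == "PEDW+WLGP"], 1L)
  expect_equal(ov$subsets$persons[ov$subsets$subset == "WLGP"], 1L)
  expect_equal(unname(ov$marginals["WLGP"]), 3L)
  expect_equal(unname(ov$marginals["NCCH"]), 1L)
  expect_equal(unname(ov$marginals["MIDS"]), 0L)
  # marginal equals the sum over subsets containing the source
  for (src in names(ov$marginals)) {
    contains <- grepl(src, ov$subsets$subset, fixed = TRUE)
    expect_equal(unname(ov$marginals[src]),
                 sum(ov$subsets$persons[contains]))
  }
})
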