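test_that("category encoding is the fixed bijection", {
  expect_equal(encode_category("underweight"), 1L)
  expect_equal(encode_category("normal"), 2L)
  expect_equal(encode_category("overweight"), 3L)
  expect_equal(encode_category("obese"), 4L)
  cats <- c("underweight", "normal", "overweight", "obese")
  expect_equal(decode_category(encode_category(cats)), cats)
  expect_error(encode_category("chunky"), class = "bmirrda_harmonise_error")
  expect_error(decode_category(5L), class = "bmirrda_harmonise_error")
})

test_that("same-day cleaning follows the pairwise consistency rules", {
  cfg <- bmi_config()
  # category-only pair one category apart: both removed
  e <- make_entries(c(NA, NA), category = c("normal", "overweight"))
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$kept), 0)
  expect_equal(nrow(r$removed), 2)
  expect_true(all(r$decisions$rule == "same_day_category_conflict"))

  # two values, same category, under 5 percent apart: both kept
  e <- make_entries(c(24.0, 24.5))
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$kept), 2)

  # same category but 5 percent or more apart: both removed
  e <- make_entries(c(30.0, 31.6))
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$removed), 2)

  # categories differ (normal vs overweight) despite close values: removed
  e <- make_entries(c(24.0, 25.0))
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$removed), 2)
  expect_true(all(r$decisions$rule == "same_day_value_conflict"))

  # a singleton passes untouched
  e <- make_entries(27.3)
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$kept), 1)
  expect_equal(nrow(r$decisions), 0)

  # category-only entry against a value-bearing day: compared by category
  e <- make_entries(c(24.0, NA), category = c("normal", "obese"))
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$removed), 2)
  e <- make_entries(c(24.0, NA), category = c("normal", "normal"))
  r <- same_day_clean(e, cfg)
  expect_equal(nrow(r$kept), 2)
})

test_that("same-day cleaning equals the exhaustive pairwise oracle", {
  cfg <- bmi_config()
  set.seed(61)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    vals <- round(runif(n, 16, 40), 1)
    vals[runif(n) < 0.3] <- NA  # category-only entries
    cats <- categorise_adult(ifelse(is.na(vals), runif(n, 16, 40), vals))
    e <- make_entries(vals, category = cats)
    r <- same_day_clean(e, cfg)
    # oracle works on the same multiset sorted as the implementation sorts
    ord <- order(xtfrm(e$bmi_value), e$category_code, e$rank, e$source)
    bad <- oracle_same_day(e$bmi_value[ord], e$category_code[ord])
    expect_equal(nrow(r$removed), sum(bad))
    expect_setequal(r$removed$record_id, e$record_id[ord][bad])
    expect_equal(nrow(r$kept) + nrow(r$removed), n)
  }
})

overtime_entries <- function(values, days, branch = "adult") {
  e <- make_entries(values, branch = branch,
                    bmi_date = as.Date("2010-01-01") + days)
  e
}

test_that("over-time cleaning removes implausible adult jumps only", {
  cfg <- bmi_config()
  # 1 kg/m2 over a year: well under the allowance
  e <- overtime_entries(c(25, 26), c(0, 365))
  r <- over_time_clean(e, cfg = cfg)
  expect_equal(nrow(r$kept), 2)

  # +20 within thirty days: removed
  e <- overtime_entries(c(25, 45), c(0, 30))
  r <- over_time_clean(e, cfg = cfg)
  expect_equal(r$removed$bmi_value, 45)
  expect_equal(r$decisions$rule, "over_time_conflict")

  # after a removal the baseline stays: a later plausible value survives
  e <- overtime_entries(c(25, 45, 25.5), c(0, 30, 90))
  r <- over_time_clean(e, cfg = cfg)
  expect_setequal(r$kept$bmi_value, c(25, 25.5))

  # long gaps pro-rate the allowance upwards: +15 over three years is kept
  e <- overtime_entries(c(25, 40), c(0, 3 * 365))
  r <- over_time_clean(e, cfg = cfg)
  expect_equal(nrow(r$kept), 2)

  # the child branch passes through unchanged
  e <- overtime_entries(c(18, 38), c(0, 30), branch = "CYP")
  r <- over_time_clean(e, cfg = cfg)
  expect_equal(nrow(r$kept), 2)
  expect_equal(nrow(r$removed), 0)
})

test_that("pregnancy-window entries are exempt from over-time cleaning", {
  cfg <- bmi_config()
  # birth 2010-12-01; entries at days 0/100/650 from 2010-01-01 sit at
  # 334 days before, 234 days before (inside the window) and 316 days after
  births <- tibble::tibble(person_id = "P1",
                           birth_date = as.Date("2010-12-01"))
  e <- overtime_entries(c(25, 37, 25.5), c(0, 100, 650))
  r <- over_time_clean(e, births, cfg)
  expect_equal(nrow(r$removed), 0)
  expect_setequal(r$kept$bmi_value, c(25, 37, 25.5))
  # the exempt entry does not become the comparison baseline: the day-650
  # value is judged against 25 (allowance 17.8), not against 37
  e2 <- overtime_entries(c(25, 37, 44), c(0, 100, 650))
  r2 <- over_time_clean(e2, births, cfg)
  expect_equal(r2$removed$bmi_value, 44)
})

test_that("daily selection keeps the lowest rank with deterministic ties", {
  e <- make_entries(c(27.0, 27.2), rank = c(4L, 1L),
                    data_type = c("height_weight", "bmi_value"))
  e$source <- c("NCCH", "WLGP")
  sel <- select_daily_entry(e)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$rank, 1L)

  single <- make_entries(24)
  expect_equal(select_daily_entry(single)$record_id, single$record_id)

  tie <- make_entries(c(24.8, 24.1), rank = 2L, data_type = "height_weight")
  sel <- select_daily_entry(tie)
  expect_equal(sel$bmi_value, 24.1)

  expect_equal(nrow(select_daily_entry(make_entries(24)[0, ])), 0)
})

test_that("pregnancy flags mark the 294-day window on both sides", {
  cfg <- bmi_config()
  births <- tibble::tibble(person_id = "P1",
                           birth_date = as.Date("2012-01-01"))
  e <- make_entries(c(24, 24, 24, 24),
                    bmi_date = as.Date("2012-01-01") + c(-200, 294, 295, -1000))
  f <- flag_pregnancy(e, births, cfg)
  expect_equal(f$pregnancy_flag, c(TRUE, TRUE, FALSE, FALSE))

  f2 <- flag_pregnancy(e, births = NULL, cfg)
  expect_false(any(f2$pregnancy_flag))
})
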