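test_that("BMI arithmetic and guards", {
  expect_equal(compute_bmi(70, 1.75), 70 / 1.75^2, tolerance = 1e-12)
  expect_equal(round(compute_bmi(70, 1.75), 3), 22.857)
  expect_equal(compute_bmi(100, 1.0), 100)
  expect_error(compute_bmi(0, 1.7), class = "bmirrda_derive_error")
  expect_error(compute_bmi(70, -1), class = "bmirrda_derive_error")
})

hw_tbl <- function(dates, values) {
  tibble::tibble(record_id = paste0("r", seq_along(dates)),
                 date = as.Date("2015-01-01") + dates, value = values)
}

test_that("child pairing selects the nearest height inside the window", {
  cfg <- bmi_config()
  heights <- hw_tbl(c(-200, -30), c(1.30, 1.31))
  weights <- hw_tbl(0, 32)
  p <- pair_cyp(heights, weights, cfg)
  expect_equal(nrow(p), 1)
  expect_equal(p$height_m, 1.31)
  expect_equal(p$bmi_value, 32 / 1.31^2)
  expect_equal(p$weight_date, weights$date)

  # 181 days away: no eligible height
  expect_equal(nrow(pair_cyp(hw_tbl(181, 1.3), hw_tbl(0, 30), cfg)), 0)
  # exactly 180 days away: eligible
  expect_equal(nrow(pair_cyp(hw_tbl(180, 1.3), hw_tbl(0, 30), cfg)), 1)
  # same day: gap zero
  p0 <- pair_cyp(hw_tbl(0, 1.3), hw_tbl(0, 30), cfg)
  expect_equal(p0$height_date, p0$weight_date)
  # tie in gap: earlier height date wins
  pt <- pair_cyp(hw_tbl(c(-10, 10), c(1.20, 1.40)), hw_tbl(0, 30), cfg)
  expect_equal(pt$height_m, 1.20)
})

test_that("child pairing equals a brute-force oracle on random inputs", {
  cfg <- bmi_config()
  set.seed(31)
  for (rep in 1:40) {
    nh <- sample(0:6, 1); nw <- sample(1:6, 1)
    heights <- hw_tbl(sample(-400:400, nh), round(runif(nh, 0.9, 1.8), 3))
    weights <- hw_tbl(sample(-400:400, nw), round(runif(nw, 15, 80), 2))
    got <- pair_cyp(heights, weights, cfg)
    # oracle: filter all pairs to the window, argmin gap with earlier-date tie
    expected <- 0L
    for (i in seq_len(nw)) {
      gaps <- abs(as.numeric(heights$date - weights$date[i]))
      elig <- which(gaps <= 180)
      if (length(elig) == 0) next
      expected <- expected + 1L
      best <- elig[order(gaps[elig], heights$date[elig])][1]
      row <- got[got$weight_date == weights$date[i], ]
      expect_equal(row$height_date, heights$date[best])
      expect_equal(row$bmi_value, weights$value[i] / heights$value[best]^2)
    }
    expect_equal(nrow(got), expected)
  }
})

test_that("adult pairing carries the most recent height forward with fallback", {
  cfg <- bmi_config()
  heights <- tibble::tibble(record_id = c("h1", "h2"),
                            date = as.Date(c("2005-03-01", "2015-03-01")),
                            value = c(1.70, 1.68))
  w12 <- tibble::tibble(record_id = "w", date = as.Date("2012-06-01"),
                        value = 75)
  p <- pair_adult(heights, w12, cfg)
  expect_equal(p$height_m, 1.70)  # most recent on or before 2012

  w03 <- tibble::tibble(record_id = "w", date = as.Date("2003-01-01"),
                        value = 75)
  p2 <- pair_adult(heights, w03, cfg)
  expect_equal(p2$height_m, 1.70)  # earliest later height as fallback
  expect_equal(p2$height_date, as.Date("2005-03-01"))

  expect_equal(nrow(pair_adult(heights[0, ], w12, cfg)), 0)

  cfg_single <- bmi_config(adult_height_mode = "single")
  ps <- pair_adult(heights, w12, cfg_single)
  expect_equal(ps$height_m, 1.68)  # one study-wide most recent height
})

test_that("the LMS transform matches its closed forms", {
  expect_equal(lms_zscore(16, L = -1.6, M = 16, S = 0.11), 0)
  expect_equal(lms_zscore(16, L = 0, M = 16, S = 0.11), 0)
  expect_equal(lms_zscore(16 * exp(0.1), L = 0, M = 16, S = 0.1), 1)
  # frozen value, recomputed independently: ((20/16)^-1.6 - 1)/(-1.6 * 0.11)
  expect_equal(lms_zscore(20, L = -1.6, M = 16, S = 0.11), 1.70595609475,
               tolerance = 1e-9)
  expect_error(lms_zscore(-1, 1, 16, 0.1), class = "bmirrda_derive_error")
  expect_error(lms_zscore(20, 1, -16, 0.1), class = "bmirrda_derive_error")

  # strictly increasing in the measurement for fixed parameters
  set.seed(41)
  for (i in 1:20) {
    L <- runif(1, -2.5, 1); M <- runif(1, 14, 20); S <- runif(1, 0.08, 0.15)
    x <- sort(runif(50, 10, 40))
    z <- lms_zscore(x, L, M, S)
    expect_true(all(diff(z) > 0))
  }
})

test_that("reference lookup interpolates linearly and is exact at knots", {
  ref <- generate_reference()
  knot <- ref[ref$sex == "male" & ref$age_months == 60, ]
  got <- reference_lookup(ref, "male", 60)
  expect_equal(got$L, knot$L)
  expect_equal(got$M, knot$M)
  expect_equal(got$S, knot$S)

  lo <- ref[ref$sex == "female" & ref$age_months == 24, ]
  hi <- ref[ref$sex == "female" & ref$age_months == 30, ]
  mid <- reference_lookup(ref, "female", 27)
  expect_equal(mid$M, (lo$M + hi$M) / 2)
  expect_equal(mid$L, (lo$L + hi$L) / 2)
  expect_equal(mid$S, (lo$S + hi$S) / 2)

  expect_error(reference_lookup(ref, "male", 12), "below",
               class = "bmirrda_derive_error")
  expect_error(reference_lookup(ref, "male", 300), "above",
               class = "bmirrda_derive_error")
})

test_that("child categorisation uses the percentile z thresholds", {
  thr <- cyp_z_thresholds(bmi_config())
  expect_equal(categorise_cyp(0, thr), "normal")
  expect_equal(categorise_cyp(2.0, thr), "obese")     # above qnorm(0.95)
  expect_equal(categorise_cyp(-3, thr), "underweight")
  expect_equal(categorise_cyp(1.2, thr), "overweight")
  expect_equal(categorise_cyp(thr[["obese"]], thr), "obese")   # closed above
  expect_equal(categorise_cyp(thr[["over"]], thr), "overweight")
})

test_that("adult categorisation implements half-open conventional intervals", {
  expect_equal(categorise_adult(18.5), "normal")
  expect_equal(categorise_adult(25.0), "overweight")
  expect_equal(categorise_adult(32.1), "obese")
  expect_equal(categorise_adult(30.0), "obese")
  expect_equal(categorise_adult(18.49), "underweight")
  expect_equal(categorise_adult(29.9), "overweight")
})

test_that("categorisation is monotone along the BMI axis", {
  set.seed(51)
  x <- sort(runif(1000, 12, 100))
  codes <- encode_category(categorise_adult(x))
  expect_true(all(diff(codes) >= 0))

  thr <- cyp_z_thresholds(bmi_config())
  z <- sort(runif(1000, -5, 5))
  zc <- encode_category(categorise_cyp(z, thr))
  expect_true(all(diff(zc) >= 0))
})
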