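make_events <- function(code, code_system = "ReadV2", value = NA_real_,
                        unit = NA_character_, source = "WLGP",
                        date = as.Date("2010-06-01"), person = "P1") {
  n <- length(code)
  tibble::tibble(record_id = paste0("E", seq_len(n)), person_id = person,
                 event_date = rep(date, length.out = n), source = source,
                 code = code, code_system = rep_len(code_system, n),
                 numeric_value = rep_len(value, n), unit = rep_len(unit, n))
}

test_that("events match against the code list; unlisted codes audit out", {
  cl <- example_codelist()
  ev <- make_events(c("E66", "Z999"), code_system = "ICD10", source = "PEDW")
  m <- match_events(ev, cl)
  expect_equal(nrow(m$components), 1)
  expect_equal(m$components$component, "obesity_dx")
  expect_equal(m$components$category, "obese")
  expect_equal(sum(m$audit$reason == "unmatched_code"), 1)

  hv <- match_events(make_events("229..", value = 175, unit = "cm"), cl)
  expect_equal(hv$components$component, "height")
  expect_equal(hv$components$value, 175)
})

test_that("units standardise to SI with a magnitude heuristic for heights", {
  cl <- example_codelist()
  ev <- make_events(rep("229..", 4), value = c(175, 1.75, 180, -5),
                    unit = c("cm", NA, NA, "cm"))
  comp <- match_events(ev, cl)$components
  s <- standardise_units(comp)
  expect_equal(s$components$value, c(1.75, 1.75, 1.80))
  expect_equal(sum(s$audit$reason == "height_cm_heuristic"), 1)
  expect_equal(sum(s$audit$reason == "non_positive_value"), 1)

  wv <- match_events(make_events("22A..", value = 154.5, unit = "lb"), cl)
  sw <- standardise_units(wv$components)
  expect_equal(sw$components$value, 154.5 * 0.45359237)

  uk <- match_events(make_events("22A..", value = 70, unit = "bushel"), cl)
  su <- standardise_units(uk$components)
  expect_equal(nrow(su$components), 0)
  expect_equal(su$audit$reason, "unknown_unit")
})

test_that("extreme-value boundaries keep exactly 12 and 100", {
  cl <- example_codelist()
  ev <- make_events(rep("22K..", 5), value = c(11.9, 12, 55, 100, 100.5))
  comp <- standardise_units(match_events(ev, cl)$components)$components
  f <- filter_extremes(comp, bmi_config())
  expect_equal(sort(f$kept$value), c(12, 55, 100))
  expect_equal(sort(f$removed$value), c(11.9, 100.5))
})

test_that("kept and removed partition the input on random components", {
  cl <- example_codelist()
  cfg <- bmi_config()
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    ev <- make_events(sample(c("22K..", "229..", "22A.."), n, replace = TRUE),
                      value = runif(n, -10, 400))
    comp <- standardise_units(match_events(ev, cl)$components)$components
    f <- filter_extremes(comp, cfg)
    expect_equal(nrow(f$kept) + nrow(f$removed), nrow(comp))
    expect_length(intersect(f$kept$record_id, f$removed$record_id), 0)
  }
})

test_that("the rank function is total on the six hierarchy pairs and injective", {
  h <- default_hierarchy()
  expect_equal(assign_rank("WLGP", "bmi_value", h), 1L)
  expect_equal(assign_rank("WLGP", "height_weight", h), 2L)
  expect_equal(assign_rank("MIDS", "height_weight", h), 3L)
  expect_equal(assign_rank("NCCH", "height_weight", h), 4L)
  expect_equal(assign_rank("WLGP", "bmi_category", h), 5L)
  expect_equal(assign_rank("PEDW", "obese_category", h), 6L)
  expect_setequal(assign_rank(h$source, h$data_type, h), 1:6)
  expect_error(assign_rank("PEDW", "bmi_value", h), "PEDW/bmi_value",
               class = "bmirrda_rank_error")
})

test_that("collation collapses exact duplicates and keeps cross-source days", {
  cl <- example_codelist()
  cfg <- bmi_config()
  ev <- make_events(rep("22K..", 3), value = c(24.0, 24.0, 24.0))
  comp <- standardise_units(match_events(ev, cl)$components)$components
  # two identical WLGP rows plus one NCCH-equivalent on the same day
  comp$source[3] <- "NCCH"
  comp$component[3] <- "weight"
  comp$value[3] <- 70
  col <- collate(comp, cfg)
  expect_equal(nrow(col$components), 2)
  expect_equal(col$audit$reason, "exact_duplicate")
  expect_equal(col$audit$count, 2L)

  again <- collate(col$components, cfg)
  expect_equal(as.data.frame(again$components[names(col$components)]),
               as.data.frame(col$components))

  expect_equal(nrow(collate(comp[0, ], cfg)$components), 0)
})

test_that("collation is idempotent on random inputs", {
  cl <- example_codelist()
  cfg <- bmi_config()
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:30, 1)
    ev <- make_events(sample(c("22K..", "229.."), n, replace = TRUE),
                      value = round(runif(n, 15, 90), 1),
                      date = as.Date("2010-01-01") + sample(0:3, n, TRUE),
                      person = sample(c("A", "B"), n, TRUE))
    comp <- standardise_units(match_events(ev, cl)$components)$components
    once <- collate(comp, cfg)$components
    twice <- collate(once, cfg)$components
    expect_equal(as.data.frame(twice[names(once)]), as.data.frame(once))
  }
})
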