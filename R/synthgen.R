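#' Scenario configuration for the synthetic linked-EHR generator
#'
#' Describes a synthetic population and its recording behaviour: per-source
#' recording rates (events per person-year), child growth parameters (children
#' track the synthetic growth reference at a person-specific z-score), adult
#' trajectory parameters (start BMI distribution plus a slow annual drift),
#' error-injection rates (extreme outliers, unit errors, same-day conflicting
#' duplicates, category-only conflicts, over-time jumps), demographic-exclusion
#' injections, pregnancy, migration and mortality rates. A fixed `seed` makes
#' the whole generator reproducible.
#'
#' Injected same-day conflicts are constructed with wide margins (30\%
#' relative difference) on otherwise unused dates, and natural events are
#' given distinct dates per person, so the deterministic cleaning rules remove
#' exactly the injected records; consistent same-day duplicates
#' (`duplicate_rate`) exercise multi-source days and rank selection without
#' triggering removal.
#'
#' @param n_persons population size.
#' @param seed integer RNG seed.
#' @param study_start,study_end study window emulated by the generator.
#' @param rates named list of recording, injection and demographic rates;
#'   any subset may be supplied to override the defaults.
#' @return A `bmi_scenario` list.
#' @export
scenario_config <- function(n_persons = 200L, seed = 1L,
                            study_start = "2000-01-01",
                            study_end = "2022-12-31",
                            rates = list()) {
  if (n_persons <= 0) {
    abort("n_persons must be positive", class = "bmirrda_synth_error")
  }
  defaults <- list(
    # recording rates, events per person-year in the relevant age interval
    wlgp_bmi_rate = 0.25, wlgp_hw_rate = 0.10, wlgp_weight_rate = 0.05,
    wlgp_height_rate = 0.03, wlgp_cat_rate = 0.05,
    ncch_rate = 0.40, pedw_rate = 0.08, pregnancy_rate = 0.08,
    # error injections
    duplicate_rate = 0.05, outlier_rate = 0.02, unit_error_rate = 0.02,
    same_day_conflict_rate = 0.02, category_conflict_rate = 0.01,
    overtime_conflict_rate = 0.02, under2_rate = 0.05,
    # demographic-exclusion injections
    missing_wob_rate = 0.02, invalid_sex_rate = 0.01, bad_linkage_rate = 0.03,
    dod_before_study_rate = 0.01, early_dod_rate = 0.01,
    # vital and migration dynamics
    mortality_rate = 0.015, migration_out_rate = 0.01, migration_in_rate = 0.05,
    # trajectory parameters
    child_z_sd = 1.0, adult_bmi_mean = 26, adult_bmi_sd = 3.5,
    adult_drift_sd = 0.3, height_rel_noise = 0.003, weight_rel_noise = 0.004
  )
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown scenario rate(s): ", paste(unknown, collapse = ", ")),
          class = "bmirrda_synth_error")
  }
  defaults[names(rates)] <- rates
  if (any(unlist(defaults) < 0)) {
    abort("all scenario rates must be non-negative",
          class = "bmirrda_synth_error")
  }
  sc <- list(n_persons = as.integer(n_persons), seed = as.integer(seed),
             study_start = as.Date(study_start), study_end = as.Date(study_end),
             rates = defaults)
  class(sc) <- "bmi_scenario"
  sc
}

#' Synthetic growth reference
#'
#' Smooth L, M, S curves over ages 24-228 months for both sexes: the median
#' BMI rises from about 15 to 19 kg/m2, the coefficient of variation from
#' 0.10 to 0.13, and the Box-Cox power from -1.5 to -1.0, with a small sex
#' offset. A synthetic stand-in for a national growth reference, shipped so
#' tests need no third-party reference tables.
#'
#' @param ages integer grid of ages in months.
#' @return Growth-reference tibble (`sex`, `age_months`, `L`, `M`, `S`).
#' @export
generate_reference <- function(ages = seq(24L, 228L, by = 6L)) {
  t <- (ages - 24) / 204
  one_sex <- function(sex, m_off) {
    tibble(sex = sex, age_months = as.numeric(ages),
           L = -1.5 + 0.5 * t,
           M = 15.0 + 4.0 * t^1.5 + m_off,
           S = 0.10 + 0.03 * t)
  }
  validate_reference(dplyr::bind_rows(one_sex("female", 0.2),
                                      one_sex("male", 0)))
}

# Interpolated reference parameters (generator-side truth).
ref_lms_at <- function(ref, sex, age_months) {
  reference_lookup(ref, sex, age_months)
}

# Inverse LMS transform: BMI at a given z for reference parameters.
lms_inverse <- function(z, L, M, S) {
  ifelse(L == 0, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Generate a synthetic population
#'
#' Persons with weeks of birth spread across ages 0-100 at study start,
#' balanced sexes, deaths and out/in-migration at the configured rates, and a
#' configured fraction given a missing week of birth, an invalid sex code, an
#' unaccepted linkage status or an early death, to exercise the demographic
#' exclusions.
#'
#' @param sc a [scenario_config()].
#' @return List with `demographics` and `residency` tibbles (plus hidden
#'   truth columns prefixed `.` used downstream by the generator).
#' @export
generate_population <- function(sc) {
  r <- sc$rates
  n <- sc$n_persons
  study_days <- as.numeric(sc$study_end - sc$study_start)
  pid <- sprintf("P%04d", seq_len(n))
  age0 <- runif(n, 0, 95)
  birth <- sc$study_start - round(age0 * 365.25)
  # a slice of the population is born during the study
  born_in_study <- runif(n) < 0.15
  birth[born_in_study] <- sc$study_start +
    round(runif(sum(born_in_study), 0, study_days - 365))
  wob <- wob_anchor(birth)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  linkage <- sample(c(1L, 4L, 39L), n, replace = TRUE)
  linkage[runif(n) < r$bad_linkage_rate] <- 99L

  # deaths: exponential residual lifetime at the annual mortality rate
  dod <- rep(as.Date(NA), n)
  death_draw <- stats::rexp(n, rate = max(r$mortality_rate, 1e-12))
  dies <- r$mortality_rate > 0 & death_draw * 365.25 < study_days
  dod[dies] <- sc$study_start + round(death_draw[dies] * 365.25)
  early <- runif(n) < r$early_dod_rate
  dod[early] <- sc$study_start + sample(0:30, sum(early), replace = TRUE)
  before <- runif(n) < r$dod_before_study_rate
  dod[before] <- sc$study_start - sample(1:400, sum(before), replace = TRUE)
  dod <- pmax(dod, birth, na.rm = FALSE)

  wob_out <- wob
  wob_out[runif(n) < r$missing_wob_rate] <- as.Date(NA)
  sex_out <- sex
  sex_out[runif(n) < r$invalid_sex_rate] <- "9"

  demographics <- tibble(person_id = pid, sex = sex_out,
                         week_of_birth = wob_out, date_of_death = dod,
                         linkage_status = linkage)

  res_start <- rep(as.Date(NA), n)
  res_end <- rep(as.Date(NA), n)
  moves_in <- runif(n) < r$migration_in_rate
  res_start[moves_in] <- sc$study_start +
    round(runif(sum(moves_in), 30, study_days - 30))
  moves_out <- runif(n) < r$migration_out_rate * study_days / 365.25
  res_end[moves_out] <- sc$study_start +
    round(runif(sum(moves_out), 60, study_days - 1))
  swap <- !is.na(res_start) & !is.na(res_end) & res_start > res_end
  res_start[swap] <- NA
  residency <- tibble(person_id = pid, start_date = res_start,
                      end_date = res_end)

  truth_persons <- tibble(person_id = pid, true_birth = birth, true_wob = wob,
                          true_sex = sex)
  list(demographics = demographics, residency = residency,
       truth_persons = truth_persons)
}

# -- per-person event machinery ----------------------------------------------

# sample k distinct unused day offsets within [0, len); updates the registry
take_dates <- function(registry, len, k) {
  if (k <= 0 || len <= 0) return(list(offs = integer(0), registry = registry))
  avail <- setdiff(seq_len(len) - 1L, registry)
  k <- min(k, length(avail))
  offs <- if (k > 0) sort(resample(avail, k)) else integer(0)
  list(offs = offs, registry = c(registry, offs))
}

# sample() without the length-1 surprise
resample <- function(x, k) x[sample.int(length(x), k)]

round_m <- function(h) round(h, 3)
round_cm <- function(h) round(h * 100, 1)
std_height <- function(value, unit) {
  ifelse(!is.na(unit) & unit == "cm", value * (1 / 100),
         ifelse(is.na(unit) & value > 3, value * (1 / 100), value))
}

#' Generate source events with ground truth
#'
#' Emits the four event tables (primary-care coded events, hospital obesity
#' episodes, maternity records, child measurements) for a generated
#' population, together with a per-record truth label: `clean`,
#' `extreme_outlier`, `unit_error`, `same_day_conflict`, `over_time_conflict`
#' or `under_2`. Children follow the synthetic growth reference at a
#' person-specific z-score; adults follow a slowly drifting trajectory;
#' injected errors use wide decision margins so the deterministic cleaning
#' rules remove exactly the labelled records.
#'
#' @param pop output of [generate_population()].
#' @param reference growth reference from [generate_reference()].
#' @param sc a [scenario_config()].
#' @return List of `wlgp_events`, `pedw_episodes`, `mids_records`,
#'   `ncch_records` tibbles and `truth`, a tibble (`record_id`, `label`)
#'   aligned with the positional record identifiers the pipeline assigns.
#' @export
generate_events <- function(pop, reference, sc) {
  r <- sc$rates
  demo <- pop$demographics
  tp <- pop$truth_persons
  study_days <- as.numeric(sc$study_end - sc$study_start)

  wlgp <- list(); pedw <- list(); mids <- list(); ncch <- list()
  uid <- 0L
  new_uid <- function() {
    uid <<- uid + 1L
    uid
  }

  for (i in seq_len(nrow(demo))) {
    pid <- demo$person_id[i]
    birth <- tp$true_birth[i]
    anchor <- wob_anchor(tp$true_wob[i])
    sex <- tp$true_sex[i]
    dod <- demo$date_of_death[i]
    res <- pop$residency[pop$residency$person_id == pid, ]
    active_start <- max(sc$study_start, birth,
                        if (!is.na(res$start_date[1])) res$start_date[1] else sc$study_start)
    active_end <- min(sc$study_end,
                      if (!is.na(dod)) dod else sc$study_end,
                      if (!is.na(res$end_date[1])) res$end_date[1] else sc$study_end)
    if (active_start > active_end) next

    # person-level trajectory parameters
    z_i <- max(-3, min(3, rnorm(1, 0, r$child_z_sd)))
    h_factor <- rnorm(1, 1, 0.03)
    adult_h <- max(1.45, min(2.05,
      rnorm(1, if (sex == "male") 1.77 else 1.63, 0.06)))
    bmi0 <- max(17, min(45, rnorm(1, r$adult_bmi_mean, r$adult_bmi_sd)))
    drift <- rnorm(1, 0, r$adult_drift_sd)

    true_bmi <- function(dates) {
      am <- as.numeric(months_since(anchor, dates))
      out <- numeric(length(dates))
      child <- am >= 24 & am <= 228
      if (any(child)) {
        lms <- ref_lms_at(reference, sex, am[child])
        out[child] <- lms_inverse(z_i, lms$L, lms$M, lms$S)
      }
      if (any(!child)) {
        yrs <- as.numeric(dates[!child] - sc$study_start) / 365.25
        out[!child] <- pmax(14, pmin(60, bmi0 + drift * yrs))
      }
      out
    }
    true_height <- function(dates) {
      am <- as.numeric(months_since(anchor, dates))
      h <- ifelse(am >= 228, adult_h,
                  (0.84 + 0.91 * pmax(0, (am - 24) / 204)^0.75) *
                    (if (sex == "male") 1.02 else 0.99) * h_factor)
      pmin(h, adult_h)
    }

    # branch intervals clipped to activity
    nineteenth <- add_years_rollback(anchor, 19L)
    second <- add_years_rollback(anchor, 2L)
    child_lo <- max(active_start, second)
    child_hi <- min(active_end, nineteenth - 1)
    adult_lo <- max(active_start, nineteenth)
    adult_hi <- active_end
    child_len <- max(0, as.numeric(child_hi - child_lo) + 1)
    adult_len <- max(0, as.numeric(adult_hi - adult_lo) + 1)

    registry_child <- integer(0)
    registry_adult <- integer(0)
    # offsets of adult dates that surely carry a kept BMI value (over-time
    # injection anchors)
    adult_value_offsets <- integer(0)

    draw <- function(interval, rate) {
      len <- if (interval == "child") child_len else adult_len
      lo <- if (interval == "child") child_lo else adult_lo
      reg <- if (interval == "child") registry_child else registry_adult
      k <- rpois(1, rate * len / 365.25)
      got <- take_dates(reg, len, k)
      if (interval == "child") registry_child <<- got$registry
      else registry_adult <<- got$registry
      lo + got$offs
    }

    noise <- function(n, sd) 1 + rnorm(n, 0, sd)

    ## --- natural events ----------------------------------------------------
    # direct primary-care BMI values (both branches)
    for (interval in c("child", "adult")) {
      d <- draw(interval, r$wlgp_bmi_rate * if (interval == "child") 0.4 else 1)
      if (length(d)) {
        v <- round(true_bmi(d) * noise(length(d), r$weight_rel_noise), 2)
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = d,
                                    code = "22K..", numeric_value = v,
                                    unit = NA_character_, label = "clean")
        if (interval == "adult") {
          adult_value_offsets <- c(adult_value_offsets,
                                   as.integer(d - adult_lo))
        }
      }
    }
    # primary-care height+weight pairs (adults; metres and kilograms)
    d <- draw("adult", r$wlgp_hw_rate)
    adult_value_offsets <- c(adult_value_offsets, as.integer(d - adult_lo))
    for (dd in as.list(d)) {
      h <- round_m(true_height(dd) * noise(1, r$height_rel_noise))
      w <- round(true_bmi(dd) * true_height(dd)^2 * noise(1, r$weight_rel_noise), 2)
      wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                  code = "229..", numeric_value = h,
                                  unit = "m", label = "clean")
      wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                  code = "22A..", numeric_value = w,
                                  unit = "kg", label = "clean")
      # consistent same-day duplicate: direct BMI equal to the derived pair
      if (runif(1) < r$duplicate_rate) {
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                    code = "22K..",
                                    numeric_value = w / h^2,
                                    unit = NA_character_, label = "clean")
      }
    }
    # standalone adult weights and heights (carry-forward exercise)
    d <- draw("adult", r$wlgp_weight_rate)
    if (length(d)) {
      w <- round(true_bmi(d) * true_height(d)^2 * noise(length(d), r$weight_rel_noise), 2)
      wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = d,
                                  code = "22A..", numeric_value = w,
                                  unit = "kg", label = "clean")
    }
    d <- draw("adult", r$wlgp_height_rate)
    if (length(d)) {
      h <- round_m(true_height(d) * noise(length(d), r$height_rel_noise))
      wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = d,
                                  code = "229..", numeric_value = h,
                                  unit = NA_character_, label = "clean")
    }
    # primary-care category codes (adults)
    d <- draw("adult", r$wlgp_cat_rate)
    if (length(d)) {
      cat <- categorise_adult(true_bmi(d))
      code <- c(underweight = "22K1.", normal = "22K2.",
                overweight = "22K4.", obese = "22K5.")[cat]
      wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = d,
                                  code = unname(code),
                                  numeric_value = NA_real_,
                                  unit = NA_character_, label = "clean")
    }
    # child measurement programme: same-row height (cm) and weight
    d <- draw("child", r$ncch_rate)
    for (dd in as.list(d)) {
      h <- true_height(dd) * noise(1, r$height_rel_noise)
      w <- round(true_bmi(dd) * true_height(dd)^2 * noise(1, r$weight_rel_noise), 2)
      hcm <- round_cm(h)
      no_unit <- runif(1) < 0.3   # exercise the magnitude heuristic
      ncch[[new_uid()]] <- fast_tbl(person_id = pid, record_date = dd,
                                  height_value = hcm,
                                  height_unit = if (no_unit) NA_character_ else "cm",
                                  weight_value = w, weight_unit = "kg",
                                  label = "clean")
      if (runif(1) < r$duplicate_rate) {
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                    code = "22K..",
                                    numeric_value = w / (hcm * (1 / 100))^2,
                                    unit = NA_character_, label = "clean")
      }
    }
    # hospital obesity episodes where the person is truly obese
    d <- draw("adult", r$pedw_rate)
    if (length(d)) {
      obese <- true_bmi(d) >= 30
      d <- d[obese]
      if (length(d)) {
        pedw[[new_uid()]] <- fast_tbl(person_id = pid, admission_date = d,
                                    code = sample(c("E66", "E669"), length(d),
                                                  replace = TRUE),
                                    label = "clean")
      }
    }
    # maternity bookings around each baby's birth
    if (sex == "female") {
      lo <- max(active_start, add_years_rollback(anchor, 18L))
      hi <- min(active_end, add_years_rollback(anchor, 42L))
      len <- max(0, as.numeric(hi - lo) + 1)
      k <- rpois(1, r$pregnancy_rate * len / 365.25)
      if (k > 0 && len > 240) {
        births <- lo + sort(resample(seq(240, len - 1), min(k, 3)))
        for (b in as.list(births)) {
          dd <- b - 210
          am <- as.numeric(months_since(anchor, dd))
          reg <- if (am <= 228) "child" else "adult"
          off <- as.numeric(dd - (if (reg == "child") child_lo else adult_lo))
          in_reg <- if (reg == "child") child_len else adult_len
          if (off < 0 || off >= in_reg) next
          if (off %in% (if (reg == "child") registry_child else registry_adult)) next
          if (reg == "child") registry_child <- c(registry_child, off)
          else registry_adult <- c(registry_adult, off)
          h <- round_m(adult_h * noise(1, r$height_rel_noise))
          w <- round((true_bmi(dd) + 1.2) * adult_h^2 * noise(1, r$weight_rel_noise), 2)
          mids[[new_uid()]] <- fast_tbl(person_id = pid, record_date = dd,
                                      height_value = h, height_unit = "m",
                                      weight_value = w, weight_unit = "kg",
                                      baby_birth_date = b, label = "clean")
        }
      }
    }

    ## --- injections --------------------------------------------------------
    n_days <- length(registry_child) + length(registry_adult)

    # extreme outliers: implausible direct BMI values
    k <- rpois(1, r$outlier_rate * n_days)
    if (k > 0 && adult_len > 0) {
      got <- take_dates(registry_adult, adult_len, k)
      registry_adult <- got$registry
      d <- adult_lo + got$offs
      if (length(d)) {
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = d,
                                    code = "22K..",
                                    numeric_value = sample(c(8, 150), length(d),
                                                           replace = TRUE),
                                    unit = NA_character_,
                                    label = "extreme_outlier")
      }
    }
    # unit errors: height in centimetres mislabelled as metres (quarantined
    # by the plausibility filter) and pound weights mislabelled as kilograms
    k <- rpois(1, r$unit_error_rate * n_days)
    if (k > 0 && adult_len > 0) {
      got <- take_dates(registry_adult, adult_len, k)
      registry_adult <- got$registry
      d <- adult_lo + got$offs
      for (dd in as.list(d)) {
        if (runif(1) < 0.5) {
          wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                      code = "229..",
                                      numeric_value = round_cm(adult_h),
                                      unit = "m", label = "unit_error")
        } else {
          wlb <- round(true_bmi(dd) * adult_h^2 / 0.45359237, 2)
          wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                      code = "22A..", numeric_value = wlb,
                                      unit = "kg", label = "unit_error")
        }
      }
    }
    # same-day conflicting value pairs: two direct BMI values 30% apart
    for (interval in c("child", "adult")) {
      len <- if (interval == "child") child_len else adult_len
      n_reg <- length(if (interval == "child") registry_child else registry_adult)
      k <- rpois(1, r$same_day_conflict_rate * n_reg)
      if (k == 0 || len == 0) next
      reg <- if (interval == "child") registry_child else registry_adult
      got <- take_dates(reg, len, k)
      if (interval == "child") registry_child <- got$registry
      else registry_adult <- got$registry
      d <- (if (interval == "child") child_lo else adult_lo) + got$offs
      for (dd in as.list(d)) {
        base <- max(15, min(70, true_bmi(dd)))
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                    code = "22K..", numeric_value = round(base, 2),
                                    unit = NA_character_,
                                    label = "same_day_conflict")
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                    code = "22K..",
                                    numeric_value = round(base * 1.3, 2),
                                    unit = NA_character_,
                                    label = "same_day_conflict")
      }
    }
    # same-day category-only conflicts: adjacent category codes
    k <- rpois(1, r$category_conflict_rate *
                 (length(registry_adult) + length(registry_child)))
    if (k > 0 && adult_len > 0) {
      got <- take_dates(registry_adult, adult_len, k)
      registry_adult <- got$registry
      d <- adult_lo + got$offs
      for (dd in as.list(d)) {
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                    code = "22K2.", numeric_value = NA_real_,
                                    unit = NA_character_,
                                    label = "same_day_conflict")
        wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                    code = "22K4.", numeric_value = NA_real_,
                                    unit = NA_character_,
                                    label = "same_day_conflict")
      }
    }
    # over-time jumps: +15 kg/m2 within ~6 months of an existing adult value,
    # only for non-mothers with an earlier natural adult BMI on record
    if (sex != "female" || r$pregnancy_rate == 0) {
      k <- rpois(1, r$overtime_conflict_rate * length(adult_value_offsets))
      if (k > 0 && length(adult_value_offsets) > 0 && adult_len > 0) {
        anchors <- resample(adult_value_offsets,
                            min(k, length(adult_value_offsets)))
        for (a in anchors) {
          off <- a + resample(30:180, 1)
          if (off >= adult_len || off %in% registry_adult) next
          registry_adult <- c(registry_adult, off)
          dd <- adult_lo + off
          v <- min(95, true_bmi(dd) + 15)
          wlgp[[new_uid()]] <- fast_tbl(person_id = pid, event_date = dd,
                                      code = "22K..",
                                      numeric_value = round(v, 2),
                                      unit = NA_character_,
                                      label = "over_time_conflict")
        }
      }
    }
    # measurements under two years of age (excluded branch)
    if (birth >= sc$study_start && runif(1) < r$under2_rate) {
      dd <- anchor + resample(360:700, 1)
      if (dd <= active_end && dd >= active_start) {
        ncch[[new_uid()]] <- fast_tbl(person_id = pid, record_date = dd,
                                    height_value = 78.0, height_unit = "cm",
                                    weight_value = 10.5, weight_unit = "kg",
                                    label = "under_2")
      }
    }
  }

  assemble <- function(rows, date_col, order_cols) {
    if (length(rows) == 0) {
      out <- switch(date_col,
        event_date = tibble(person_id = character(),
                            event_date = as.Date(character()),
                            code = character(), numeric_value = numeric(),
                            unit = character(), label = character()),
        admission_date = tibble(person_id = character(),
                                admission_date = as.Date(character()),
                                code = character(), label = character()),
        record_date = tibble(person_id = character(),
                             record_date = as.Date(character()),
                             height_value = numeric(), height_unit = character(),
                             weight_value = numeric(), weight_unit = character(),
                             label = character())
      )
      return(out)
    }
    out <- dplyr::bind_rows(rows)
    out[do.call(order, unname(as.list(out[order_cols]))), ]
  }
  wlgp_tbl <- assemble(wlgp, "event_date",
                       c("person_id", "event_date", "code", "numeric_value"))
  pedw_tbl <- assemble(pedw, "admission_date",
                       c("person_id", "admission_date", "code"))
  mids_tbl <- assemble(mids, "record_date", c("person_id", "record_date"))
  if (!"baby_birth_date" %in% names(mids_tbl)) {
    mids_tbl$baby_birth_date <- as.Date(character(nrow(mids_tbl)))
  }
  ncch_tbl <- assemble(ncch, "record_date", c("person_id", "record_date"))

  truth <- dplyr::bind_rows(
    tibble(record_id = paste0("WLGP-", seq_len(nrow(wlgp_tbl))),
           label = wlgp_tbl$label),
    tibble(record_id = paste0("PEDW-", seq_len(nrow(pedw_tbl))),
           label = pedw_tbl$label),
    tibble(record_id = rep(paste0("MIDS-", seq_len(nrow(mids_tbl))), each = 2),
           label = rep(mids_tbl$label, each = 2)) |>
      dplyr::mutate(record_id = paste0(.data$record_id,
                                       rep(c(":h", ":w"), nrow(mids_tbl)))),
    tibble(record_id = rep(paste0("NCCH-", seq_len(nrow(ncch_tbl))), each = 2),
           label = rep(ncch_tbl$label, each = 2)) |>
      dplyr::mutate(record_id = paste0(.data$record_id,
                                       rep(c(":h", ":w"), nrow(ncch_tbl))))
  )
  drop_label <- function(x) x[setdiff(names(x), "label")]
  list(wlgp_events = drop_label(wlgp_tbl), pedw_episodes = drop_label(pedw_tbl),
       mids_records = drop_label(mids_tbl), ncch_records = drop_label(ncch_tbl),
       truth = truth)
}

#' Generate a complete synthetic scenario
#'
#' Seeds the RNG from the scenario, generates the population, growth
#' reference and all source tables, and returns the six pipeline inputs plus
#' the truth labels. Two calls with the same scenario produce identical
#' output.
#'
#' @param sc a [scenario_config()].
#' @return List with `inputs` (the six tables), `reference`, `truth` and
#'   `config` (a [bmi_config()] matching the scenario window).
#' @export
generate_scenario <- function(sc = scenario_config()) {
  set.seed(sc$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  reference <- generate_reference()
  pop <- generate_population(sc)
  ev <- generate_events(pop, reference, sc)
  inputs <- list(demographics = pop$demographics, residency = pop$residency,
                 wlgp_events = ev$wlgp_events, pedw_episodes = ev$pedw_episodes,
                 mids_records = ev$mids_records, ncch_records = ev$ncch_records)
  cfg <- bmi_config(study_start = sc$study_start, study_end = sc$study_end)
  list(inputs = inputs, reference = reference, truth = ev$truth, config = cfg)
}
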