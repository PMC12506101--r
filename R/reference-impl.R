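#' Naive reference implementation of the harmonisation rules
#'
#' A deliberately simple, loop-based re-implementation of the whole pipeline,
#' kept on a separate code path from the staged implementation so the two can
#' be compared record-for-record (differential testing). It favours obvious
#' nested loops over vectorised code and shares no intermediate logic with
#' [build_rrda()]; agreement between the two is evidence that both implement
#' the declared rules.
#'
#' @inheritParams build_rrda
#' @return An RRDA tibble in the same schema and sort order as
#'   `build_rrda(...)$rrda`.
#' @export
reference_rrda <- function(inputs, reference, codelists = example_codelist(),
                           cfg = bmi_config()) {
  inputs <- add_record_ids(inputs)
  codekey <- paste(codelists$code, codelists$code_system)

  ## 1. components, one row at a time -----------------------------------------
  comps <- list()
  push <- function(record_id, person_id, date, component, value, category,
                   source) {
    comps[[length(comps) + 1]] <<- list(
      record_id = record_id, person_id = person_id, date = date,
      component = component, value = value, category = category,
      source = source)
  }
  wl <- inputs$wlgp_events
  for (i in seq_len(nrow(wl))) {
    j <- match(paste(wl$code[i], "ReadV2"), codekey)
    if (is.na(j)) next
    push(wl$record_id[i], wl$person_id[i], wl$event_date[i],
         codelists$component[j], wl$numeric_value[i],
         codelists$category_map[j], "WLGP")
  }
  pe <- inputs$pedw_episodes
  for (i in seq_len(nrow(pe))) {
    j <- match(paste(pe$code[i], "ICD10"), codekey)
    if (is.na(j)) next
    push(pe$record_id[i], pe$person_id[i], pe$admission_date[i],
         codelists$component[j], NA_real_, codelists$category_map[j], "PEDW")
  }
  for (src in c("MIDS", "NCCH")) {
    tb <- inputs[[if (src == "MIDS") "mids_records" else "ncch_records"]]
    for (i in seq_len(nrow(tb))) {
      if (!is.na(tb$height_value[i])) {
        push(paste0(tb$record_id[i], ":h"), tb$person_id[i], tb$record_date[i],
             "height", tb$height_value[i], NA_character_, src)
      }
      if (!is.na(tb$weight_value[i])) {
        push(paste0(tb$record_id[i], ":w"), tb$person_id[i], tb$record_date[i],
             "weight", tb$weight_value[i], NA_character_, src)
      }
    }
  }
  # units: re-standardise each measurement; attach unit strings back
  unit_of <- c(setNames(wl$unit, wl$record_id),
               setNames(inputs$mids_records$height_unit,
                        paste0(inputs$mids_records$record_id, ":h")),
               setNames(inputs$mids_records$weight_unit,
                        paste0(inputs$mids_records$record_id, ":w")),
               setNames(inputs$ncch_records$height_unit,
                        paste0(inputs$ncch_records$record_id, ":h")),
               setNames(inputs$ncch_records$weight_unit,
                        paste0(inputs$ncch_records$record_id, ":w")))
  keep <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (cp in comps) {
    if (cp$date < cfg$study_start || cp$date > cfg$study_end) next
    if (cp$component %in% c("height", "weight")) {
      if (is.na(cp$value) || cp$value <= 0) next
      u <- unit_of[[cp$record_id]]
      u <- if (is.null(u) || is.na(u)) "" else tolower(trimws(u))
      if (cp$component == "height") {
        if (u == "cm") cp$value <- cp$value * (1 / 100)
        else if (u == "mm") cp$value <- cp$value * (1 / 1000)
        else if (u %in% c("", "m")) {
          if (u == "" && cp$value > 3) cp$value <- cp$value * (1 / 100)
        } else next
        if (cp$value < cfg$height_bounds_m[1] ||
            cp$value > cfg$height_bounds_m[2]) next
      } else {
        if (u == "g") cp$value <- cp$value * (1 / 1000)
        else if (u == "lb") cp$value <- cp$value * 0.45359237
        else if (u %in% c("st", "stone")) cp$value <- cp$value * 6.35029318
        else if (!(u %in% c("", "kg"))) next
        if (cp$value < cfg$weight_bounds_kg[1] ||
            cp$value > cfg$weight_bounds_kg[2]) next
      }
    }
    if (cp$component == "bmi_value") {
      if (is.na(cp$value) || cp$value < cfg$bmi_min || cp$value > cfg$bmi_max) next
    }
    key <- paste(cp$person_id, cp$date, cp$component,
                 format(cp$value, digits = 17), cp$category, cp$source)
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    keep[[length(keep) + 1]] <- cp
  }
  comps <- keep

  ## 2. eligible persons -------------------------------------------------------
  demo <- inputs$demographics
  ok <- rep(TRUE, nrow(demo))
  ok <- ok & demo$linkage_status %in% cfg$linkage_status_accept
  ok <- ok & !is.na(demo$week_of_birth)
  ok <- ok & !is.na(demo$sex) & demo$sex %in% c("female", "male")
  ok <- ok & !(!is.na(demo$date_of_death) &
                 demo$date_of_death < cfg$study_start + cfg$min_residency_days)
  demo <- demo[ok, ]
  comps <- Filter(function(cp) cp$person_id %in% demo$person_id, comps)

  ## 3. candidate entries per person -------------------------------------------
  rank_of <- function(source, data_type) {
    h <- cfg$hierarchy
    h$rank[h$source == source & h$data_type == data_type]
  }
  zthr <- cyp_z_thresholds(cfg)
  by_person <- split(comps, vapply(comps, function(cp) cp$person_id,
                                   character(1)))
  entries <- list()
  for (pi in seq_len(nrow(demo))) {
    pid <- demo$person_id[pi]
    anchor <- lubridate::floor_date(demo$week_of_birth[pi], "week",
                                    week_start = 1)
    sex <- demo$sex[pi]
    mine <- by_person[[pid]]
    if (is.null(mine) || length(mine) == 0) next
    months_at <- function(d) months_since(anchor, d)
    branch_of <- function(am) {
      if (am >= cfg$cyp_age_months[1] && am <= cfg$cyp_age_months[2]) "CYP"
      else if (am %/% 12 >= cfg$adult_age_years[1] &&
               am %/% 12 <= cfg$adult_age_years[2]) "adult"
      else NA_character_
    }
    cat_of <- function(bmi, branch, am) {
      if (branch == "adult") {
        if (bmi < cfg$adult_cut_points[1]) "underweight"
        else if (bmi < cfg$adult_cut_points[2]) "normal"
        else if (bmi < cfg$adult_cut_points[3]) "overweight"
        else "obese"
      } else {
        sub <- reference[reference$sex == sex, ]
        L <- approx(sub$age_months, sub$L, am, ties = "ordered")$y
        M <- approx(sub$age_months, sub$M, am, ties = "ordered")$y
        S <- approx(sub$age_months, sub$S, am, ties = "ordered")$y
        z <- if (L == 0) log(bmi / M) / S else ((bmi / M)^L - 1) / (L * S)
        if (z < zthr[["under"]]) "underweight"
        else if (z >= zthr[["obese"]]) "obese"
        else if (z >= zthr[["over"]]) "overweight"
        else "normal"
      }
    }
    add_entry <- function(record_id, date, bmi, category, source, data_type,
                          hdate, wdate) {
      am <- months_at(date)
      br <- branch_of(am)
      if (is.na(br)) return(invisible(NULL))
      if (!is.na(bmi) && is.na(category)) category <- cat_of(bmi, br, am)
      entries[[length(entries) + 1]] <<- list(
        record_id = record_id, person_id = pid, bmi_date = date,
        bmi_value = bmi, category = category,
        category_code = match(category, .categories), source = source,
        data_type = data_type, rank = rank_of(source, data_type), branch = br,
        age_months = am, height_date = hdate, weight_date = wdate)
    }
    for (cp in mine) {
      if (cp$component == "bmi_value") {
        add_entry(cp$record_id, cp$date, cp$value, NA_character_, cp$source,
                  "bmi_value", as.Date(NA), as.Date(NA))
      } else if (cp$component == "bmi_category") {
        add_entry(cp$record_id, cp$date, NA_real_, cp$category, cp$source,
                  "bmi_category", as.Date(NA), as.Date(NA))
      } else if (cp$component == "obesity_dx") {
        add_entry(cp$record_id, cp$date, NA_real_, cp$category, cp$source,
                  "obese_category", as.Date(NA), as.Date(NA))
      }
    }
    for (src in unique(vapply(mine, function(cp) cp$source, character(1)))) {
      hs <- Filter(function(cp) cp$source == src && cp$component == "height",
                   mine)
      ws <- Filter(function(cp) cp$source == src && cp$component == "weight",
                   mine)
      for (w in ws) {
        am <- months_at(w$date)
        br <- branch_of(am)
        if (is.na(br) || length(hs) == 0) next
        hj <- NULL
        if (br == "CYP") {
          best <- Inf; best_date <- as.Date(NA)
          for (h in hs) {
            gap <- abs(as.numeric(h$date - w$date))
            if (gap > cfg$hw_pair_window_days) next
            if (gap < best || (gap == best && h$date < best_date)) {
              best <- gap; best_date <- h$date; hj <- h
            }
          }
        } else {
          on_before <- as.Date(NA); after <- as.Date(NA)
          for (h in hs) {
            if (h$date <= w$date &&
                (is.na(on_before) || h$date > on_before)) on_before <- h$date
            if (h$date > w$date &&
                (is.na(after) || h$date < after)) after <- h$date
          }
          target <- if (cfg$adult_height_mode == "single") {
            max(vapply(hs, function(h) h$date, as.Date(NA)))
          } else if (!is.na(on_before)) on_before else after
          for (h in hs) if (h$date == target && is.null(hj)) hj <- h
        }
        if (is.null(hj)) next
        add_entry(w$record_id, w$date, w$value / hj$value^2, NA_character_,
                  src, "height_weight", hj$date, w$date)
      }
    }
  }
  if (length(entries) == 0) return(reference_empty_rrda())

  e <- dplyr::bind_rows(lapply(entries, as_tibble))
  e <- e[order(e$person_id, e$bmi_date, xtfrm(e$bmi_value), e$category_code,
               e$rank, e$source), ]

  ## 4a. same-day cleaning ------------------------------------------------------
  drop <- rep(FALSE, nrow(e))
  groups <- split(seq_len(nrow(e)), paste(e$person_id, e$bmi_date))
  for (g in groups) {
    if (length(g) < 2) next
    for (a in g) {
      for (b in g) {
        if (a >= b) next
        va <- e$bmi_value[a]; vb <- e$bmi_value[b]
        ca <- e$category_code[a]; cb <- e$category_code[b]
        if (!is.na(va) && !is.na(vb)) {
          rel <- (max(va, vb) - min(va, vb)) / min(va, vb)
          if (rel >= cfg$same_day_rel_diff || ca != cb) {
            drop[a] <- TRUE; drop[b] <- TRUE
          }
        } else if (is.na(va) || is.na(vb)) {
          if (ca != cb) {
            drop[a] <- TRUE; drop[b] <- TRUE
          }
        }
      }
    }
  }
  e <- e[!drop, ]

  ## 4b. over-time cleaning (adults) --------------------------------------------
  births <- mids_births(inputs$mids_records)
  preg <- function(pid, d) {
    b <- births$birth_date[births$person_id == pid]
    length(b) > 0 && any(abs(as.numeric(d - b)) <= cfg$pregnancy_window_days)
  }
  drop <- rep(FALSE, nrow(e))
  for (pid in unique(e$person_id)) {
    idx <- which(e$person_id == pid & e$branch == "adult" &
                   !is.na(e$bmi_value))
    if (length(idx) < 2) next
    base_date <- as.Date(NA); base_value <- NA_real_
    cur_date <- as.Date(NA); last_kept <- NA_real_
    for (i in idx) {
      if (!is.na(cur_date) && e$bmi_date[i] != cur_date) {
        if (!is.na(last_kept)) {
          base_date <- cur_date; base_value <- last_kept
        }
        last_kept <- NA_real_
      }
      cur_date <- e$bmi_date[i]
      if (preg(pid, e$bmi_date[i])) next
      if (!is.na(base_value)) {
        gap <- as.numeric(e$bmi_date[i] - base_date)
        allowed <- cfg$overtime_max_annual_delta * max(gap, 365) / 365
        if (abs(e$bmi_value[i] - base_value) > allowed) {
          drop[i] <- TRUE
          next
        }
      }
      last_kept <- e$bmi_value[i]
    }
  }
  e <- e[!drop, ]

  ## 5. lowest rank per day, pregnancy flag --------------------------------------
  sel <- integer(0)
  for (g in split(seq_len(nrow(e)), paste(e$person_id, e$bmi_date))) {
    ord <- order(e$rank[g], is.na(e$bmi_value[g]), xtfrm(e$bmi_value[g]),
                 e$source[g])
    sel <- c(sel, g[ord[1]])
  }
  res <- e[sort(sel), ]
  res$pregnancy_flag <- vapply(seq_len(nrow(res)), function(i) {
    preg(res$person_id[i], res$bmi_date[i])
  }, logical(1))
  res <- res[order(res$person_id, res$bmi_date),
             c("person_id", "bmi_date", "bmi_value", "category",
               "category_code", "source", "data_type", "rank", "branch",
               "age_months", "pregnancy_flag", "height_date", "weight_date")]
  as_tibble(res)
}

reference_empty_rrda <- function() {
  tibble(person_id = character(), bmi_date = as.Date(character()),
         bmi_value = numeric(), category = character(),
         category_code = integer(), source = character(),
         data_type = character(), rank = integer(), branch = character(),
         age_months = integer(), pregnancy_flag = logical(),
         height_date = as.Date(character()), weight_date = as.Date(character()))
}
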