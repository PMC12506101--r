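#' Load a clinical code list
#'
#' Reads the delimited code list mapping Read Version 2 and ICD-10 codes to
#' the BMI component they record. A code either carries a numeric measurement
#' (`bmi_value`, `height`, `weight`) or implies a category directly
#' (`bmi_category` with a `category_map`, or an ICD-10 `obesity_dx` which
#' always maps to obese).
#'
#' Columns: `code`, `code_system` (`ReadV2` or `ICD10`), `component`,
#' `category_map` (empty unless the component is category-bearing).
#'
#' @param path delimited file path.
#' @return Tibble of validated code-list rows.
#' @export
load_codelists <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("code list file not found: ", path),
          class = "bmirrda_codelist_error")
  }
  cl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_codelists(cl)
}

validate_codelists <- function(cl) {
  stop_cl <- function(msg) abort(msg, class = "bmirrda_codelist_error")
  required <- c("code", "code_system", "component")
  missing <- setdiff(required, names(cl))
  if (length(missing)) {
    stop_cl(paste0("code list missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"category_map" %in% names(cl)) cl$category_map <- NA_character_
  cl <- as_tibble(cl[c("code", "code_system", "component", "category_map")])
  cl$category_map[!is.na(cl$category_map) & cl$category_map == ""] <- NA_character_
  dup <- duplicated(paste(cl$code, cl$code_system, sep = "\r"))
  if (any(dup)) {
    stop_cl(paste0("duplicate (code, code_system) pairs: ",
                   paste(unique(cl$code[dup]), collapse = ", ")))
  }
  bad_sys <- setdiff(unique(cl$code_system), c("ReadV2", "ICD10"))
  if (length(bad_sys)) {
    stop_cl(paste0("unknown code_system: ", paste(bad_sys, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(cl$component), .components)
  if (length(bad_comp)) {
    stop_cl(paste0("unknown component kind: ", paste(bad_comp, collapse = ", ")))
  }
  if (any(cl$component == "obesity_dx" & cl$code_system != "ICD10")) {
    stop_cl("obesity_dx codes must be ICD10")
  }
  needs_cat <- cl$component %in% c("bmi_category", "obesity_dx")
  if (any(needs_cat & is.na(cl$category_map))) {
    stop_cl("category-bearing codes (bmi_category, obesity_dx) need a category_map")
  }
  if (any(!needs_cat & !is.na(cl$category_map))) {
    stop_cl("category_map only allowed for bmi_category and obesity_dx codes")
  }
  bad_cat <- setdiff(stats::na.omit(cl$category_map), .categories)
  if (length(bad_cat)) {
    stop_cl(paste0("unknown category_map value: ", paste(bad_cat, collapse = ", ")))
  }
  cl
}

#' Illustrative code list
#'
#' A small, non-authoritative code list shipped for examples and synthetic
#' data: it follows the shape of Read Version 2 BMI-component codes and
#' ICD-10 obesity codes but is not a clinically validated extraction list.
#' Real analyses should supply their own governed code list via
#' [load_codelists()].
#'
#' @return Tibble in the [load_codelists()] schema.
#' @export
example_codelist <- function() {
  validate_codelists(tibble(
    code = c("22K..", "229..", "22A..",
             "22K1.", "22K2.", "22K4.", "22K5.",
             "E66", "E660", "E661", "E668", "E669"),
    code_system = c(rep("ReadV2", 7), rep("ICD10", 5)),
    component = c("bmi_value", "height", "weight",
                  rep("bmi_category", 4), rep("obesity_dx", 5)),
    category_map = c(NA, NA, NA,
                     "underweight", "normal", "overweight", "obese",
                     rep("obese", 5))
  ))
}
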