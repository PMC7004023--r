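# The canonical 100-person demonstration cohort: 50 people with unmet need,
# 50 wearing distance correction of whom 20 see 6/12 or better uncorrected
# (no need), 5 are corrected but still impaired though pinhole clears them
# (under-met) and 25 achieve 6/12 or better with their correction (met).
# At 6/12 thresholds this classifies to a=25, b=5, c=50 and gives
# eREC = 25/80 = 31.25%, REC = 30/80 = 37.5%, quality gap = 16.7%.

#' The 100-person worked-example cohort
#'
#' Builds the demonstration survey used throughout the documentation and
#' tests, deterministically (no randomness): 50 non-wearers impaired by
#' uncorrected refractive error, 20 wearers with no need, 5 wearers with
#' under-met need and 25 wearers with met need. Acuity lines vary across
#' standard chart lines within each group; classification depends only on
#' which side of the thresholds they fall.
#'
#' @return A person-record tibble of 100 rows with a `residence` stratum
#'   column (alternating urban/rural).
#' @examples
#' recs <- worked_example_records()
#' summary <- tabulate_need(classify_records(recs, quiet = TRUE))
#' erec(summary)$value_pct  # 31.25
#' @export
worked_example_records <- function() {
  cycle <- function(lines, n) rep_len(lines, n)
  unmet <- person_records(
    person_id = sprintf("u%03d", 1:50),
    wears_correction = FALSE,
    ucva_left = cycle(c("6/18", "6/24", "6/36", "6/60"), 50),
    ucva_right = cycle(c("6/24", "6/36", "6/60", "6/18"), 50),
    pinhole_left = cycle(c("6/9", "6/12", "6/6"), 50),
    pinhole_right = cycle(c("6/12", "6/9", "6/9"), 50),
    age_years = cycle(c(34L, 48L, 61L, 55L, 72L), 50),
    sex = cycle(c("female", "male"), 50))
  no_need <- person_records(
    person_id = sprintf("n%03d", 1:20),
    wears_correction = TRUE,
    ucva_left = cycle(c("6/6", "6/9", "6/12"), 20),
    ucva_right = cycle(c("6/9", "6/6", "6/12"), 20),
    cva_left = "6/6", cva_right = "6/6",
    age_years = cycle(c(28L, 41L, 50L), 20),
    sex = cycle(c("male", "female"), 20))
  under_met <- person_records(
    person_id = sprintf("b%03d", 1:5),
    wears_correction = TRUE,
    ucva_left = cycle(c("6/36", "6/60"), 5),
    ucva_right = cycle(c("6/60", "6/36"), 5),
    cva_left = cycle(c("6/18", "6/24"), 5),
    cva_right = cycle(c("6/24", "6/18"), 5),
    pinhole_left = "6/9", pinhole_right = "6/12",
    age_years = cycle(c(58L, 66L), 5),
    sex = cycle(c("female", "male"), 5))
  met <- person_records(
    person_id = sprintf("a%03d", 1:25),
    wears_correction = TRUE,
    ucva_left = cycle(c("6/18", "6/24", "6/36"), 25),
    ucva_right = cycle(c("6/24", "6/18", "6/60"), 25),
    cva_left = cycle(c("6/6", "6/9", "6/12"), 25),
    cva_right = cycle(c("6/9", "6/6", "6/12"), 25),
    age_years = cycle(c(45L, 52L, 38L, 63L), 25),
    sex = cycle(c("male", "female"), 25))
  out <- dplyr::bind_rows(unmet, no_need, under_met, met)
  out$residence <- rep_len(c("urban", "rural"), nrow(out))
  out
}

.lm_to_text <- function(lm) {
  out <- format_acuity(lm)
  out[is.na(lm)] <- ""
  out
}

#' Write the worked-example survey files
#'
#' Writes the cohort of [worked_example_records()] as a survey CSV plus its
#' YAML column mapping, ready for [read_survey()] or the `compute` CLI
#' subcommand. Copies of both files also ship with the package under
#' `system.file("extdata", package = "erec")`.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_worked_example <- function(dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- worked_example_records()
  df <- data.frame(
    id = recs$person_id,
    glasses = ifelse(recs$wears_correction, "yes", "no"),
    va_unc_l = .lm_to_text(recs$ucva_left),
    va_unc_r = .lm_to_text(recs$ucva_right),
    va_cor_l = .lm_to_text(recs$cva_left),
    va_cor_r = .lm_to_text(recs$cva_right),
    va_ph_l = .lm_to_text(recs$pinhole_left),
    va_ph_r = .lm_to_text(recs$pinhole_right),
    age = recs$age_years,
    sex = recs$sex,
    residence = recs$residence,
    check.names = FALSE)
  csv_path <- file.path(dir, "worked_example.csv")
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  map_path <- file.path(dir, "worked_example_mapping.yaml")
  yaml::write_yaml(worked_example_mapping_list(), map_path)
  invisible(c(csv_path, map_path))
}

worked_example_mapping_list <- function() {
  list(
    columns = list(
      person_id = "id",
      wears_correction = "glasses",
      ucva_left = "va_unc_l", ucva_right = "va_unc_r",
      cva_left = "va_cor_l", cva_right = "va_cor_r",
      pinhole_left = "va_ph_l", pinhole_right = "va_ph_r",
      age_years = "age", sex = "sex"),
    acuity_dialect = "metric_6",
    strata = list(residence = "residence"),
    correction_definition = "spectacles or contact lenses")
}
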