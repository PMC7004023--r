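# Person-level need classification for refractive error correction.
#
# Each survey participant is assigned exactly one category from the
# measurement flowchart: better-eye uncorrected acuity (UCVA) establishes
# need; corrected acuity (CVA, habitual correction) establishes the visual
# outcome for correction wearers; pinhole acuity (over correction for
# wearers) or best-corrected acuity after new refraction establishes whether
# residual impairment is refractive.

#' Need categories
#'
#' The six mutually exclusive person-level categories: `NO_NEED` (better-eye
#' UCVA at or better than the need threshold), `MET` (wearer whose corrected
#' acuity achieves the outcome threshold), `UNDER_MET` (wearer still impaired
#' with correction but refraction/pinhole reaches the need threshold),
#' `UNMET` (impaired non-wearer whose impairment is refractive), `OTHER_VI`
#' (impairment not resolved by pinhole/refraction, e.g. cataract) and
#' `INDETERMINATE` (the deciding measurement is missing). `OTHER_VI` and
#' `INDETERMINATE` are excluded from coverage numerators and denominators
#' but always reported.
#'
#' @return Character vector of category levels, in reporting order.
#' @export
need_categories <- function() {
  c("NO_NEED", "MET", "UNDER_MET", "UNMET", "OTHER_VI", "INDETERMINATE")
}

#' Assemble a person-record table
#'
#' Builds the canonical participant table the pipeline operates on: one row
#' per person, acuities as numeric logMAR (`NA` = not measured). Most
#' columns are optional; anything not supplied is filled with a sensible
#' default (`weight = 1`). Extra columns (strata such as residence or
#' socioeconomic position) are carried through untouched.
#'
#' @param person_id Identifier vector (coerced to character).
#' @param wears_correction Logical: does the person habitually wear distance
#'   spectacles or contact lenses?
#' @param ucva_left,ucva_right Uncorrected VA per eye (acuity/character/logMAR).
#' @param cva_left,cva_right VA with the person's own correction (wearers only).
#' @param pinhole_left,pinhole_right Pinhole VA (over correction for wearers).
#' @param bcva_left,bcva_right Best-corrected VA after new refraction, if done.
#' @param age_years,sex,weight,cluster_id Demographics and survey design
#'   variables.
#' @param ... Further per-person columns (strata), recycled to length.
#' @return A tibble with one row per person.
#' @export
person_records <- function(person_id,
                           wears_correction,
                           ucva_left = NA, ucva_right = NA,
                           cva_left = NA, cva_right = NA,
                           pinhole_left = NA, pinhole_right = NA,
                           bcva_left = NA, bcva_right = NA,
                           age_years = NA_integer_, sex = NA_character_,
                           weight = 1, cluster_id = NA_character_, ...) {
  n <- length(person_id)
  lm <- function(x) rep_len(acuity_logmar(x), n)
  out <- tibble::tibble(
    person_id = as.character(person_id),
    wears_correction = rep_len(as.logical(wears_correction), n),
    ucva_left = lm(ucva_left), ucva_right = lm(ucva_right),
    cva_left = lm(cva_left), cva_right = lm(cva_right),
    pinhole_left = lm(pinhole_left), pinhole_right = lm(pinhole_right),
    bcva_left = lm(bcva_left), bcva_right = lm(bcva_right),
    age_years = rep_len(as.integer(age_years), n),
    sex = rep_len(as.character(sex), n),
    weight = rep_len(as.numeric(weight), n),
    cluster_id = rep_len(as.character(cluster_id), n))
  extras <- list(...)
  for (nm in names(extras)) out[[nm]] <- rep_len(extras[[nm]], n)
  validate_records(out)
}

#' Validate a person-record table
#'
#' Checks the structural invariants: required columns present, positive
#' weights, non-negative ages. A wearer flag of `FALSE` combined with
#' recorded corrected acuity raises a data-quality warning (the corrected
#' values are ignored by the flowchart for non-wearers but kept in the
#' table).
#'
#' @param records Person-record tibble.
#' @return The validated tibble, invisibly modified only by column checks.
#' @export
validate_records <- function(records) {
  required <- c("person_id", "wears_correction", "ucva_left", "ucva_right")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("person records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("cva_left", "cva_right", "pinhole_left", "pinhole_right",
                "bcva_left", "bcva_right")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  if (!"weight" %in% names(records)) records$weight <- 1
  if (any(!is.na(records$weight) & records$weight <= 0)) {
    stop("sampling weights must be strictly positive", call. = FALSE)
  }
  if ("age_years" %in% names(records) &&
      any(!is.na(records$age_years) & records$age_years < 0)) {
    stop("age_years must be non-negative", call. = FALSE)
  }
  nonwearer_cva <- !is.na(records$wears_correction) & !records$wears_correction &
    (!is.na(records$cva_left) | !is.na(records$cva_right))
  if (any(nonwearer_cva)) {
    warning(sum(nonwearer_cva),
            " non-wearer(s) have corrected acuity recorded; ",
            "these values are ignored by the classification", call. = FALSE)
  }
  records
}

#' Classify participants into need categories
#'
#' Applies the measurement flowchart to every row at a given pair of
#' thresholds. Writing U, C, P, B for the better-eye uncorrected, corrected,
#' pinhole and best-corrected acuities, and using B as the improvement
#' measure when available (new refraction is more definitive) else P:
#'
#' * `NO_NEED` if U meets the need threshold, regardless of correction
#'   possession;
#' * non-wearers with U worse than need: `UNMET` if the improvement acuity
#'   meets the need threshold, `OTHER_VI` if it does not, `INDETERMINATE`
#'   if it is missing;
#' * wearers with U worse than need: `MET` if C meets the outcome threshold;
#'   otherwise `UNDER_MET` if the improvement acuity meets the need
#'   threshold, `OTHER_VI` if it does not, `INDETERMINATE` when the deciding
#'   measurement (C, or the improvement acuity) is missing;
#' * missing U is always `INDETERMINATE` — never silently dropped.
#'
#' Contradictory measurements (e.g. a wearer whose corrected acuity is worse
#' than uncorrected) are classified strictly by the flowchart; a count of
#' such records is attached as the `"quality_flags"` attribute.
#'
#' @param records Person-record tibble (see [person_records()]).
#' @param need Need threshold (impairment cut-off); default 6/12.
#' @param outcome Outcome threshold (good visual outcome with own
#'   correction); default 6/12.
#' @param quiet Suppress the per-category tally message.
#' @return `records` with a `need_category` factor column added; attributes
#'   `"thresholds"` (list with `need`, `outcome`) and `"quality_flags"`.
#' @examples
#' recs <- person_records(person_id = c("w1", "n1"),
#'                        wears_correction = c(TRUE, FALSE),
#'                        ucva_left = c("6/18", "6/9"),
#'                        cva_left = c("6/9", NA))
#' classify_records(recs, quiet = TRUE)$need_category
#' @export
classify_records <- function(records, need = acuity_threshold("6/12", "need"),
                             outcome = acuity_threshold("6/12", "outcome"),
                             quiet = FALSE) {
  # data-quality warnings are raised once, at record construction/reading;
  # structural errors still propagate
  records <- suppressWarnings(validate_records(records))
  if (!inherits(need, "acuity_threshold")) need <- acuity_threshold(need, "need")
  if (!inherits(outcome, "acuity_threshold")) outcome <- acuity_threshold(outcome, "outcome")

  U <- better_eye(records$ucva_left, records$ucva_right)
  C <- better_eye(records$cva_left, records$cva_right)
  P <- better_eye(records$pinhole_left, records$pinhole_right)
  B <- better_eye(records$bcva_left, records$bcva_right)
  improve <- ifelse(is.na(B), P, B)
  wears <- records$wears_correction

  u_ok <- meets_threshold(U, need)
  c_ok <- meets_threshold(C, outcome)
  i_ok <- meets_threshold(improve, need)

  cat_out <- dplyr::case_when(
    is.na(U) | is.na(wears) ~ "INDETERMINATE",
    u_ok ~ "NO_NEED",
    !wears & is.na(improve) ~ "INDETERMINATE",
    !wears & i_ok ~ "UNMET",
    !wears ~ "OTHER_VI",
    is.na(C) ~ "INDETERMINATE",
    c_ok ~ "MET",
    is.na(improve) ~ "INDETERMINATE",
    i_ok ~ "UNDER_MET",
    .default = "OTHER_VI")

  records$need_category <- factor(cat_out, levels = need_categories())

  contradictions <- sum(!is.na(U) & !is.na(C) & !is.na(wears) & wears &
                          C > U + .LOGMAR_TOL)
  if (!quiet) {
    tally <- table(records$need_category)
    message("classified ", nrow(records), " records: ",
            paste(names(tally), tally, sep = "=", collapse = " "),
            sprintf(" (indeterminate fraction %.3f)",
                    mean(cat_out == "INDETERMINATE")))
  }
  attr(records, "thresholds") <- list(need = need, outcome = outcome)
  attr(records, "quality_flags") <- c(wearer_cva_worse_than_ucva = contradictions)
  records
}

#' Classify a single participant
#'
#' Convenience wrapper around [classify_records()] for one person.
#'
#' @param person A one-row person-record tibble.
#' @inheritParams classify_records
#' @return A single need-category string.
#' @export
classify_person <- function(person, need = acuity_threshold("6/12", "need"),
                            outcome = acuity_threshold("6/12", "outcome")) {
  stopifnot(nrow(person) == 1)
  as.character(classify_records(person, need, outcome, quiet = TRUE)$need_category)
}
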