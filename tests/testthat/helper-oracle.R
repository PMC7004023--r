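# Independent straight-line re-implementation of the need-classification
# flowchart, used as the oracle for equivalence testing. Deliberately
# written as per-record if/else on raw logMAR numbers, sharing no code with
# the vectorised implementation.
oracle_classify <- function(rec, need_lm = log10(2), outcome_lm = log10(2)) {
  tol <- 1e-6
  be <- function(l, r) if (is.na(l) && is.na(r)) NA_real_ else min(l, r, na.rm = TRUE)
  U <- be(rec$ucva_left, rec$ucva_right)
  if (is.na(rec$wears_correction) || is.na(U)) return("INDETERMINATE")
  if (U <= need_lm + tol) return("NO_NEED")
  B <- be(rec$bcva_left, rec$bcva_right)
  P <- be(rec$pinhole_left, rec$pinhole_right)
  improvement <- if (!is.na(B)) B else P
  if (!rec$wears_correction) {
    if (is.na(improvement)) return("INDETERMINATE")
    return(if (improvement <= need_lm + tol) "UNMET" else "OTHER_VI")
  }
  C <- be(rec$cva_left, rec$cva_right)
  if (is.na(C)) return("INDETERMINATE")
  if (C <= outcome_lm + tol) return("MET")
  if (is.na(improvement)) return("INDETERMINATE")
  if (improvement <= need_lm + tol) return("UNDER_MET")
  "OTHER_VI"
}

# Randomised person records exercising every flowchart branch: each acuity
# field is an arbitrary chart line or missing, with no consistency imposed.
random_person_records <- function(n, seed = 1, p_missing = 0.3) {
  lines <- c(log10(1), log10(1.5), log10(2), log10(3), log10(4), log10(6),
             log10(10), log10(20), 2.0, 2.3, 2.6, 3.0)
  set.seed(seed)
  draw <- function() {
    v <- sample(lines, n, replace = TRUE)
    v[runif(n) < p_missing] <- NA_real_
    v
  }
  suppressWarnings(person_records(
    person_id = sprintf("r%06d", seq_len(n)),
    wears_correction = sample(c(TRUE, FALSE), n, replace = TRUE),
    ucva_left = draw(), ucva_right = draw(),
    cva_left = draw(), cva_right = draw(),
    pinhole_left = draw(), pinhole_right = draw(),
    bcva_left = draw(), bcva_right = draw(),
    weight = round(runif(n, 0.5, 3), 3),
    sex = sample(c("female", "male"), n, replace = TRUE)))
}
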