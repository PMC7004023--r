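fixture_summary <- function() {
  tabulate_need(classify_records(worked_example_records(), quiet = TRUE))
}

summary_from_counts <- function(a, b, c, no_need = 0, other = 0, indet = 0) {
  s <- tibble::tibble(stratum = "overall", n = a + b + c + no_need + other + indet,
                      n_met = a, n_under_met = b, n_unmet = c,
                      n_no_need = no_need, n_other_vi = other,
                      n_indeterminate = indet,
                      w_met = a, w_under_met = b, w_unmet = c,
                      denominator_n = a + b + c, denominator_w = a + b + c)
  class(s) <- c("need_summary", class(s))
  s
}

test_that("the demonstration cohort tabulates to a=25, b=5, c=50 with 20 no-need", {
  s <- fixture_summary()
  expect_equal(s$n_met, 25)
  expect_equal(s$n_under_met, 5)
  expect_equal(s$n_unmet, 50)
  expect_equal(s$n_no_need, 20)
  expect_equal(s$denominator_n, 80)
})

test_that("eREC and REC follow their defining ratios", {
  s <- fixture_summary()
  expect_equal(erec(s)$value_pct, 31.25)
  expect_equal(rec(s)$value_pct, 37.5)
  expect_equal(erec(summary_from_counts(10, 0, 0))$value_pct, 100)
  expect_equal(erec(summary_from_counts(0, 5, 5))$value_pct, 0)
  expect_equal(rec(summary_from_counts(0, 0, 10))$value_pct, 0)
  expect_equal(rec(summary_from_counts(3, 1, 0))$value_pct, 100)
})

test_that("a zero denominator is flagged undefined, never silently NaN", {
  s <- summary_from_counts(0, 0, 0, no_need = 10)
  e <- erec(s)
  expect_true(e$undefined)
  expect_true(is.na(e$value_pct))
  expect_equal(e$denominator, 0)
})

test_that("the quality gap is one minus eREC/REC on unrounded values", {
  s <- fixture_summary()
  gap <- quality_gap(erec(s), rec(s))
  expect_equal(gap$value_pct, 100 * (1 - 31.25 / 37.5))
  expect_equal(round_half_up(gap$value_pct), 17)
  expect_equal(round_half_up(quality_gap(15.1, 22.7), 1), 33.5)
  expect_equal(quality_gap(40, 40), 0)
  expect_true(is.na(quality_gap(0, 0)))
})

test_that("eREC never exceeds REC so the gap lies in [0, 100]", {
  set.seed(21)
  for (i in 1:200) {
    k <- rpois(3, lambda = sample(c(2, 20, 200), 1))
    if (sum(k) == 0) next
    s <- summary_from_counts(k[1], k[2], k[3])
    e <- erec(s)$value_pct; r <- rec(s)$value_pct
    expect_true(e <= r + 1e-12)
    if (r > 0) {
      g <- quality_gap(e, r)
      expect_true(g >= -1e-12 && g <= 100 + 1e-12)
      expect_equal(g == 0, k[2] == 0)
    }
  }
})

test_that("records outside the need denominator never move the estimates", {
  recs <- worked_example_records()
  extra <- person_records(
    person_id = sprintf("e%02d", 1:30),
    wears_correction = FALSE,
    ucva_left = rep(c(acuity_logmar("6/6"), acuity_logmar("6/60")), 15),
    pinhole_left = rep(c(NA, acuity_logmar("CF")), 15))
  both <- dplyr::bind_rows(recs, extra)
  base <- classify_records(recs, quiet = TRUE)
  more <- classify_records(both, quiet = TRUE)
  expect_equal(erec(tabulate_need(more))$value_pct,
               erec(tabulate_need(base))$value_pct)
  expect_equal(rec(tabulate_need(more))$value_pct,
               rec(tabulate_need(base))$value_pct)
})

test_that("weighted estimates are invariant to rescaling all weights", {
  recs <- random_person_records(400, seed = 31)
  cls <- classify_records(recs, quiet = TRUE)
  e1 <- erec(tabulate_need(cls), mode = "weighted")$value_pct
  scaled <- cls
  scaled$weight <- scaled$weight * 7.3
  e2 <- erec(tabulate_need(scaled), mode = "weighted")$value_pct
  expect_equal(e1, e2)
  # one record at weight 2 matches two identical records at weight 1
  base <- person_records(c("a", "b"), c(TRUE, FALSE),
                         ucva_left = c("6/36", "6/60"),
                         cva_left = c("6/9", NA), pinhole_left = c(NA, "6/9"),
                         weight = c(2, 1))
  dup <- person_records(c("a1", "a2", "b"), c(TRUE, TRUE, FALSE),
                        ucva_left = c("6/36", "6/36", "6/60"),
                        cva_left = c("6/9", "6/9", NA),
                        pinhole_left = c(NA, NA, "6/9"), weight = 1)
  s1 <- tabulate_need(classify_records(base, quiet = TRUE))
  s2 <- tabulate_need(classify_records(dup, quiet = TRUE))
  expect_equal(s1$w_met, s2$w_met)
  expect_equal(s1$denominator_w, s2$denominator_w)
})

test_that("Wilson intervals match the score-test oracle and behave at the edges", {
  cls <- classify_records(worked_example_records(), quiet = TRUE)
  got <- confidence_interval(cls, "eREC", "wilson", level = 0.95)
  want <- 100 * prop.test(25, 80, correct = FALSE)$conf.int  # score interval
  expect_equal(got, as.numeric(want), tolerance = 1e-10)
  expect_true(got[1] < 31.25 && 31.25 < got[2])
  for (case in list(c(7, 19, 0.9), c(50, 200, 0.99), c(1, 8, 0.95))) {
    oracle <- suppressWarnings(prop.test(case[1], case[2], correct = FALSE,
                                         conf.level = case[3])$conf.int)
    expect_equal(wilson_interval(case[1], case[2], case[3]),
                 as.numeric(oracle), tolerance = 1e-10)
  }
  expect_equal(wilson_interval(0, 80)[1], 0)   # no successes: lower bound 0
  expect_equal(wilson_interval(80, 80)[2], 1)  # all successes: upper bound 1
  expect_error(wilson_interval(1, 10, level = 1.2), "level")
})

test_that("the cluster bootstrap is seeded, reproducible and warns on few reps", {
  recs <- random_person_records(300, seed = 41)
  recs$cluster_id <- rep(sprintf("c%02d", 1:30), each = 10)
  cls <- classify_records(recs, quiet = TRUE)
  ci1 <- confidence_interval(cls, "eREC", "cluster_bootstrap", reps = 200, seed = 99)
  ci2 <- confidence_interval(cls, "eREC", "cluster_bootstrap", reps = 200, seed = 99)
  ci3 <- confidence_interval(cls, "eREC", "cluster_bootstrap", reps = 200, seed = 100)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, ci3))
  expect_true(ci1[1] <= erec(tabulate_need(cls))$value_pct &&
                erec(tabulate_need(cls))$value_pct <= ci1[2])
  expect_warning(confidence_interval(cls, "eREC", "cluster_bootstrap", reps = 50),
                 "replicates")
})

test_that("stratified estimates pool back to the overall estimate", {
  # two strata with identical composition: each equals the overall value
  recs <- worked_example_records()
  dupl <- dplyr::bind_rows(recs, recs)
  dupl$half <- rep(c("first", "second"), each = nrow(recs))
  dupl$person_id <- as.character(seq_len(nrow(dupl)))
  cls <- classify_records(dupl, quiet = TRUE)
  est <- stratified_estimates(cls, by = "half", ci_method = "none")
  erec_rows <- est[est$indicator == "eREC", ]
  expect_equal(erec_rows$value_pct, rep(31.25, 3))
  # unequal strata: overall is the denominator-weighted mean of stratum values
  recs2 <- random_person_records(600, seed = 55)
  cls2 <- classify_records(recs2, quiet = TRUE)
  est2 <- stratified_estimates(cls2, by = "sex", ci_method = "none")
  e <- est2[est2$indicator == "eREC", ]
  strata <- e[e$stratum != "overall", ]
  den <- strata$n_met + strata$n_under_met + strata$n_unmet
  expect_equal(e$value_pct[e$stratum == "overall"],
               sum(strata$value_pct * den) / sum(den))
  expect_error(stratified_estimates(cls2, by = "nonexistent"), "unknown stratum")
})

test_that("a stratum with no one in need is flagged, not dropped", {
  recs <- person_records(
    person_id = as.character(1:40),
    wears_correction = rep(c(TRUE, FALSE), 20),
    ucva_left = rep(c(acuity_logmar("6/36"), acuity_logmar("6/6")), 20),
    cva_left = rep(c(acuity_logmar("6/9"), NA), 20),
    region = rep(c("need", "none"), 20))
  cls <- classify_records(recs, quiet = TRUE)
  est <- stratified_estimates(cls, by = "region", ci_method = "none")
  none_row <- est[est$stratum == "region=none" & est$indicator == "eREC", ]
  expect_true(none_row$undefined)
  expect_true(is.na(none_row$value_pct))
})

test_that("direct standardisation is a share-weighted mean with checked inputs", {
  est <- tibble::tibble(
    stratum = c("s=a", "s=b"), indicator = "eREC", value_pct = c(0, 100),
    numerator = c(0, 10), denominator = c(10, 10),
    ci_low_pct = NA_real_, ci_high_pct = NA_real_, ci_method = NA_character_,
    mode = "counts", standardised = FALSE, undefined = FALSE)
  ref <- tibble::tibble(stratum = c("s=a", "s=b"), share = c(0.25, 0.75))
  expect_equal(standardise(est, ref)$value_pct, 75)
  # permuting stratum order changes nothing
  expect_equal(standardise(est[2:1, ], ref[2:1, ])$value_pct, 75)
  # self-standardisation with the sample's own need shares recovers the crude value
  den <- est$denominator
  self_ref <- tibble::tibble(stratum = est$stratum, share = den / sum(den))
  crude <- 100 * sum(est$numerator) / sum(den)
  expect_equal(standardise(est, self_ref)$value_pct, crude)
  expect_error(standardise(est, tibble::tibble(stratum = "s=a", share = 1)),
               "lacks share")
  bad_ref <- tibble::tibble(stratum = c("s=a", "s=b"), share = c(0.5, 0.6))
  expect_error(standardise(est, bad_ref), "sum to 1")
  est$undefined[1] <- TRUE
  expect_error(standardise(est, ref), "coarser")
})

test_that("multi-threshold reports always include the 6/12 reference pair", {
  recs <- worked_example_records()
  expect_message(
    rep1 <- multi_threshold_report(recs, "6/18", "6/18", ci_method = "none"),
    "6/12")
  pairs <- unique(rep1$estimates[, c("need_threshold", "outcome_threshold")])
  expect_equal(nrow(pairs), 2)
  expect_true(any(pairs$need_threshold == "6/12" & pairs$outcome_threshold == "6/12"))
  rep2 <- multi_threshold_report(recs, "6/12", "6/12", ci_method = "none")
  expect_equal(nrow(unique(rep2$estimates[, c("need_threshold", "outcome_threshold")])), 1)
  e612 <- rep1$estimates[rep1$estimates$need_threshold == "6/12" &
                           rep1$estimates$indicator == "eREC", ]
  expect_equal(e612$value_pct, 31.25)
})

test_that("display rounding goes half away from zero", {
  expect_equal(round_half_up(31.25), 31)
  expect_equal(round_half_up(37.5), 38)
  expect_equal(round_half_up(16.667), 17)
  expect_equal(round_half_up(33.48, 1), 33.5)
  expect_equal(round_half_up(-2.5), -3)
})
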