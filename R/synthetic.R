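# Seeded synthetic survey cohorts with known true coverage.
#
# The generative model mirrors the category structure of the need
# classification. Per person, independently:
#   has_re        ~ Bernoulli(re_prevalence)      vision-impairing refractive error
#   has_other_vi  ~ Bernoulli(other_vi_prevalence) non-refractive impairment
#   has_correction | has_re       ~ Bernoulli(uptake)
#   correction_good | has_correction ~ Bernoulli(quality)
#
# Non-refractive impairment dominates when present (the pinhole cannot clear
# it), so such people land in OTHER_VI and drop out of the coverage
# denominator; because uptake and quality are independent of it, the
# population eREC among people in need has the closed form uptake x quality
# and REC is uptake — which is what makes parameter-recovery tests possible.

.CHART_LINES <- c("6/6" = log10(1), "6/9" = log10(1.5), "6/12" = log10(2),
                  "6/18" = log10(3), "6/24" = log10(4), "6/36" = log10(6),
                  "6/60" = log10(10), "3/60" = log10(20),
                  "CF" = 2.0, "HM" = 2.3)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a population with moderate refractive-error burden and
#' partially effective services: 30% vision-impairing refractive error, 50%
#' correction uptake among those in need, 80% of possessed corrections
#' achieving the outcome threshold, and 5% non-refractive impairment.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param re_prevalence Probability of vision-impairing refractive error;
#'   either a single number or a tibble with columns `age_band`, `sex`,
#'   `prevalence` for demographic structure.
#' @param uptake Probability a person with refractive error possesses
#'   correction (the generative REC).
#' @param quality Probability a possessed correction achieves the outcome
#'   threshold (so the generative eREC is `uptake * quality`).
#' @param other_vi_prevalence Probability of non-refractive impairment,
#'   independent of refractive status.
#' @param missing_pinhole_rate Probability that the pinhole measurement is
#'   absent (surveys most often skip this extra measurement); affected
#'   people classify as INDETERMINATE unless BCVA is present.
#' @param age_bands Character vector of age-band labels sampled uniformly.
#' @param sex_ratio Proportion female.
#' @param acuity_jitter Probability of shifting a drawn acuity by one chart
#'   line (clamped so the latent category is preserved); 0 = chart lines
#'   exactly as drawn.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n = 1000, seed = 1,
                             re_prevalence = 0.3, uptake = 0.5, quality = 0.8,
                             other_vi_prevalence = 0.05,
                             missing_pinhole_rate = 0,
                             age_bands = c("18-39", "40-59", "60+"),
                             sex_ratio = 0.5,
                             acuity_jitter = 0) {
  probs <- c(uptake = uptake, quality = quality,
             other_vi_prevalence = other_vi_prevalence,
             missing_pinhole_rate = missing_pinhole_rate,
             sex_ratio = sex_ratio, acuity_jitter = acuity_jitter)
  if (is.numeric(re_prevalence) && length(re_prevalence) == 1) {
    probs <- c(probs, re_prevalence = re_prevalence)
  } else if (!all(c("age_band", "sex", "prevalence") %in% names(re_prevalence))) {
    stop("re_prevalence must be a single probability or a table with ",
         "age_band, sex, prevalence columns", call. = FALSE)
  } else if (any(re_prevalence$prevalence < 0 | re_prevalence$prevalence > 1)) {
    stop("re_prevalence table contains values outside [0, 1]", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 re_prevalence = re_prevalence, uptake = uptake,
                 quality = quality, other_vi_prevalence = other_vi_prevalence,
                 missing_pinhole_rate = missing_pinhole_rate,
                 age_bands = age_bands, sex_ratio = sex_ratio,
                 acuity_jitter = acuity_jitter),
            class = "generator_config")
}

.draw_line <- function(n, lines, probs) {
  if (n == 0) return(numeric(0))
  unname(.CHART_LINES[sample(lines, n, replace = TRUE, prob = probs)])
}

# shift a logMAR value by +/- one chart line with probability p, clamped to
# [lo, hi] (logMAR bounds) so the latent state cannot flip
.jitter_line <- function(lm, p, lo = -Inf, hi = Inf) {
  if (p <= 0 || length(lm) == 0) return(lm)
  lines <- unname(.CHART_LINES)
  idx <- match(round(lm, 6), round(lines, 6))
  move <- stats::runif(length(lm)) < p
  dir <- sample(c(-1L, 1L), length(lm), replace = TRUE)
  new_idx <- pmin(pmax(idx + ifelse(move, dir, 0L), 1L), length(lines))
  out <- lines[new_idx]
  bad <- is.na(idx) | out < lo - 1e-9 | out > hi + 1e-9
  out[bad] <- lm[bad]
  out
}

#' Generate a synthetic survey cohort
#'
#' Draws a cohort from the generative model in [generator_config()] and
#' emits acuities consistent with each person's latent state, on standard
#' chart lines:
#'
#' * no impairment: better-eye UCVA at or better than 6/12;
#' * refractive error: better-eye UCVA worse than 6/12; pinhole (and any
#'   correction-mediated measure) clears to the need threshold;
#' * a good correction: CVA at or better than the outcome threshold; a poor
#'   correction: CVA worse, pinhole over correction clearing the need
#'   threshold;
#' * non-refractive impairment: pinhole fails the need threshold (and CVA
#'   fails for wearers) whatever the refractive status.
#'
#' The second eye is drawn at or worse than the better eye so person-level
#' (better-eye) semantics hold by construction.
#'
#' @param config A [generator_config()].
#' @return A list with `records` (person-record tibble ready for
#'   [classify_records()]) and `truth` (tibble of latent flags and the
#'   `true_category` implied by them).
#' @examples
#' cohort <- generate_population(generator_config(n = 100, seed = 42))
#' table(cohort$truth$true_category)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  empty <- list(
    records = person_records(person_id = character(0),
                             wears_correction = logical(0)),
    truth = tibble::tibble(person_id = character(0),
                           has_re = logical(0), has_other_vi = logical(0),
                           has_correction = logical(0),
                           correction_good = logical(0),
                           true_category = factor(character(0),
                                                  levels = need_categories())))
  if (n == 0) return(empty)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(config$seed)

  age_band <- sample(config$age_bands, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  age_years <- vapply(age_band, function(b) {
    rng <- suppressWarnings(as.integer(strsplit(gsub("\\+", "-99", b), "-")[[1]]))
    if (any(is.na(rng))) 40L else sample(rng[1]:rng[2], 1)
  }, 0L)

  p_re <- if (is.numeric(config$re_prevalence)) {
    rep(config$re_prevalence, n)
  } else {
    tab <- config$re_prevalence
    tab$prevalence[match(paste(age_band, sex), paste(tab$age_band, tab$sex))]
  }
  has_re <- stats::runif(n) < p_re
  has_other_vi <- stats::runif(n) < config$other_vi_prevalence
  has_correction <- has_re & stats::runif(n) < config$uptake
  correction_good <- has_correction & stats::runif(n) < config$quality

  need_lm <- acuity_logmar("6/12")
  jit <- config$acuity_jitter

  # better-eye values by latent state (chart-line draws)
  ucva <- numeric(n)
  good_sight <- !has_re & !has_other_vi
  ucva[good_sight] <- .draw_line(sum(good_sight), c("6/6", "6/9", "6/12"),
                                 c(0.6, 0.3, 0.1))
  impaired <- !good_sight
  ucva[impaired] <- .draw_line(sum(impaired),
                               c("6/18", "6/24", "6/36", "6/60", "3/60"),
                               c(0.3, 0.25, 0.2, 0.15, 0.1))
  ucva[good_sight] <- .jitter_line(ucva[good_sight], jit, hi = need_lm)
  ucva[impaired] <- .jitter_line(ucva[impaired], jit,
                                 lo = need_lm + 10 * .LOGMAR_TOL)

  cva <- rep(NA_real_, n)
  good_cor <- correction_good & !has_other_vi
  cva[good_cor] <- .draw_line(sum(good_cor), c("6/6", "6/9", "6/12"),
                              c(0.5, 0.35, 0.15))
  poor_cor <- has_correction & !good_cor
  cva[poor_cor] <- .draw_line(sum(poor_cor), c("6/18", "6/24", "6/36"),
                              c(0.6, 0.3, 0.1))
  cva[good_cor] <- .jitter_line(cva[good_cor], jit, hi = need_lm)
  cva[poor_cor] <- .jitter_line(cva[poor_cor], jit,
                                lo = need_lm + 10 * .LOGMAR_TOL)

  pinhole <- rep(NA_real_, n)
  clears <- impaired & !has_other_vi  # refractive impairment resolves with pinhole
  pinhole[clears] <- .draw_line(sum(clears), c("6/6", "6/9", "6/12"),
                                c(0.3, 0.45, 0.25))
  blocked <- impaired & has_other_vi
  pinhole[blocked] <- .draw_line(sum(blocked), c("6/18", "6/24", "6/36", "6/60", "CF"),
                                 c(0.3, 0.25, 0.2, 0.15, 0.1))
  pinhole[clears] <- .jitter_line(pinhole[clears], jit, hi = need_lm)
  pinhole[blocked] <- .jitter_line(pinhole[blocked], jit,
                                   lo = need_lm + 10 * .LOGMAR_TOL)
  pinhole[stats::runif(n) < config$missing_pinhole_rate] <- NA_real_

  # the fellow eye is at or worse than the better eye by 0-2 chart lines
  worse_eye <- function(lm) {
    idx <- match(round(lm, 6), round(unname(.CHART_LINES), 6))
    shift <- sample(0:2, length(lm), replace = TRUE)
    out <- unname(.CHART_LINES)[pmin(idx + shift, length(.CHART_LINES))]
    out[is.na(idx)] <- lm[is.na(idx)]
    out
  }
  left_better <- stats::runif(n) < 0.5
  eye_pair <- function(lm) {
    worse <- worse_eye(lm)
    list(left = ifelse(left_better, lm, worse),
         right = ifelse(left_better, worse, lm))
  }
  u <- eye_pair(ucva)
  cv <- eye_pair(cva)
  ph <- eye_pair(pinhole)

  true_category <- dplyr::case_when(
    good_sight ~ "NO_NEED",
    has_other_vi ~ "OTHER_VI",
    has_correction & correction_good ~ "MET",
    has_correction ~ "UNDER_MET",
    .default = "UNMET")

  ids <- sprintf("p%06d", seq_len(n))
  records <- person_records(
    person_id = ids,
    wears_correction = has_correction,
    ucva_left = u$left, ucva_right = u$right,
    cva_left = cv$left, cva_right = cv$right,
    pinhole_left = ph$left, pinhole_right = ph$right,
    age_years = age_years, sex = sex, weight = 1,
    age_band = age_band)
  truth <- tibble::tibble(
    person_id = ids,
    has_re = has_re, has_other_vi = has_other_vi,
    has_correction = has_correction, correction_good = correction_good,
    true_category = factor(true_category, levels = need_categories()))
  list(records = records, truth = truth)
}

#' Generative coverage values of a configuration
#'
#' Under the generative model the population eREC among people with
#' refractive-error need is `uptake * quality` (possession and a good
#' outcome are independent) and REC is `uptake`; the relative quality gap is
#' `1 - quality`. These closed forms are what parameter-recovery experiments
#' estimate.
#'
#' @param config A [generator_config()].
#' @return Named list with `erec`, `rec`, `quality_gap` (proportions;
#'   `quality_gap` is `NA` when `uptake` is 0).
#' @export
true_erec <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  list(erec = config$uptake * config$quality,
       rec = config$uptake,
       quality_gap = if (config$uptake > 0) 1 - config$quality else NA_real_)
}

#' Parameter-recovery experiment
#'
#' Repeats generate - classify - estimate across seeds and compares the
#' estimated eREC with the generative truth, including the empirical
#' coverage of the confidence intervals. This is the package's main
#' self-validation: estimates should be unbiased and intervals should cover
#' at close to their nominal level.
#'
#' @param config A [generator_config()]; its `seed` seeds the sequence of
#'   per-replicate seeds.
#' @param n_seeds Number of replicates (at least 1).
#' @param level Confidence level for the per-replicate Wilson interval.
#' @return A tibble with one row per seed: `seed`, `erec_hat` (proportion),
#'   `erec_true`, `abs_error`, `ci_low`, `ci_high`, `covered`.
#' @export
recovery_experiment <- function(config, n_seeds = 50, level = 0.95) {
  stopifnot(inherits(config, "generator_config"), n_seeds >= 1)
  truth <- true_erec(config)$erec
  seeds <- config$seed + seq_len(n_seeds) - 1L
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    cohort <- generate_population(cfg)
    cls <- classify_records(cohort$records, quiet = TRUE)
    est <- erec(tabulate_need(cls))
    ci <- confidence_interval(cls, "eREC", "wilson", level = level)
    tibble::tibble(seed = s,
                   erec_hat = est$value_pct / 100,
                   erec_true = truth,
                   abs_error = abs(est$value_pct / 100 - truth),
                   ci_low = ci[1] / 100, ci_high = ci[2] / 100,
                   covered = ci[1] / 100 <= truth & truth <= ci[2] / 100)
  })
  dplyr::bind_rows(rows)
}
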