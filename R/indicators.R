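# Coverage indicators for refractive error services.
#
# eREC (%)        = a / (a + b + c) * 100
# REC (%)         = (a + b) / (a + b + c) * 100
# quality gap (%) = (1 - eREC / REC) * 100
#
# with a = met need, b = under-met need, c = unmet need. People with no
# need, other vision impairment or an indeterminate classification are
# excluded from both numerator and denominator but always reported. All
# arithmetic uses unrounded proportions; rounding happens only at display.

#' Tabulate need categories
#'
#' Counts (and sums the sampling weights of) each need category from a
#' classified record table, overall or within strata. The coverage
#' denominator is met + under-met + unmet need.
#'
#' @param classified Output of [classify_records()].
#' @param by Optional character vector of stratum column names to tabulate
#'   within.
#' @return A tibble with one row per stratum level combination (a single
#'   `overall` row when `by` is `NULL`): columns `n_*` and `w_*` per
#'   category plus `n`, `denominator_n`, `denominator_w`. The threshold pair
#'   is carried in the `"thresholds"` attribute.
#' @export
tabulate_need <- function(classified, by = NULL) {
  if (!"need_category" %in% names(classified)) {
    stop("records are not classified; run classify_records() first", call. = FALSE)
  }
  thresholds <- attr(classified, "thresholds")
  if (!is.null(by)) {
    missing_by <- setdiff(by, names(classified))
    if (length(missing_by) > 0) {
      stop("unknown stratum label(s): ", paste(missing_by, collapse = ", "),
           "; available: ",
           paste(setdiff(names(classified),
                         c("need_category", "person_id")), collapse = ", "),
           call. = FALSE)
    }
  }

  w <- if ("weight" %in% names(classified)) classified$weight else rep(1, nrow(classified))
  df <- tibble::tibble(.cat = classified$need_category, .w = w)
  if (!is.null(by)) for (col in by) df[[col]] <- classified[[col]]

  grouped <- dplyr::group_by(df, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    n_met = sum(.data$.cat == "MET"),
    n_under_met = sum(.data$.cat == "UNDER_MET"),
    n_unmet = sum(.data$.cat == "UNMET"),
    n_no_need = sum(.data$.cat == "NO_NEED"),
    n_other_vi = sum(.data$.cat == "OTHER_VI"),
    n_indeterminate = sum(.data$.cat == "INDETERMINATE"),
    w_met = sum(.data$.w[.data$.cat == "MET"]),
    w_under_met = sum(.data$.w[.data$.cat == "UNDER_MET"]),
    w_unmet = sum(.data$.w[.data$.cat == "UNMET"]),
    .groups = "drop")
  out$denominator_n <- out$n_met + out$n_under_met + out$n_unmet
  out$denominator_w <- out$w_met + out$w_under_met + out$w_unmet
  if (is.null(by)) out <- tibble::add_column(out, stratum = "overall", .before = 1)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("need_summary", class(out))
  out
}

.summary_counts <- function(summary, mode = c("counts", "weighted")) {
  mode <- match.arg(mode)
  if (mode == "counts") {
    list(a = summary$n_met, b = summary$n_under_met, c = summary$n_unmet)
  } else {
    list(a = summary$w_met, b = summary$w_under_met, c = summary$w_unmet)
  }
}

.coverage_row <- function(indicator, num, den, summary, mode, standardised = FALSE) {
  value <- ifelse(den > 0, 100 * num / den, NA_real_)
  out <- tibble::tibble(
    indicator = indicator,
    value_pct = value,
    numerator = num,
    denominator = den,
    ci_low_pct = NA_real_,
    ci_high_pct = NA_real_,
    ci_method = NA_character_,
    mode = mode,
    standardised = standardised,
    undefined = den <= 0)
  strata_cols <- setdiff(names(summary),
                         c(grep("^[nw]_", names(summary), value = TRUE),
                           "n", "denominator_n", "denominator_w"))
  for (col in rev(strata_cols)) out <- tibble::add_column(out, !!col := summary[[col]], .before = 1)
  attr(out, "thresholds") <- attr(summary, "thresholds")
  out
}

#' Effective refractive error coverage (eREC)
#'
#' The proportion of people with vision-impairing refractive error whose
#' own correction achieves a good visual outcome:
#' eREC (%) = a / (a + b + c) * 100.
#'
#' @param summary A need summary from [tabulate_need()].
#' @param mode `"counts"` (unweighted sample proportions) or `"weighted"`
#'   (ratio of weight sums).
#' @return A coverage-estimate tibble (one row per stratum row of
#'   `summary`). A zero denominator yields `NA` with `undefined = TRUE`,
#'   never a silent `NaN`.
#' @examples
#' recs <- worked_example_records()
#' erec(tabulate_need(classify_records(recs, quiet = TRUE)))$value_pct  # 31.25
#' @export
erec <- function(summary, mode = c("counts", "weighted")) {
  mode <- match.arg(mode)
  k <- .summary_counts(summary, mode)
  .coverage_row("eREC", k$a, k$a + k$b + k$c, summary, mode)
}

#' Refractive error coverage (REC)
#'
#' Coverage regardless of visual outcome — the access element without the
#' quality element: REC (%) = (a + b) / (a + b + c) * 100.
#'
#' @inheritParams erec
#' @return A coverage-estimate tibble.
#' @export
rec <- function(summary, mode = c("counts", "weighted")) {
  mode <- match.arg(mode)
  k <- .summary_counts(summary, mode)
  .coverage_row("REC", k$a + k$b, k$a + k$b + k$c, summary, mode)
}

#' Relative quality gap in refractive error services
#'
#' The share of refractive error coverage that is under-met:
#' gap (%) = (1 - eREC / REC) * 100, computed on unrounded values. Accepts
#' either two coverage-estimate tibbles (matched row-wise) or two bare
#' percentages, so gaps can be recomputed from published (eREC, REC) pairs.
#'
#' @param erec_est eREC estimate tibble, or numeric percentage(s).
#' @param rec_est REC estimate tibble, or numeric percentage(s).
#' @return A coverage-estimate tibble when given tibbles, else a numeric
#'   vector of gap percentages. REC of zero yields `NA` (flagged
#'   `undefined` in the tibble form).
#' @examples
#' quality_gap(15.1, 22.7)  # 33.48... -> prints as 33.5%
#' @export
quality_gap <- function(erec_est, rec_est) {
  if (is.numeric(erec_est) && is.numeric(rec_est)) {
    return(ifelse(rec_est > 0, 100 * (1 - erec_est / rec_est), NA_real_))
  }
  stopifnot(nrow(erec_est) == nrow(rec_est))
  gap <- ifelse(!is.na(rec_est$value_pct) & rec_est$value_pct > 0,
                100 * (1 - erec_est$value_pct / rec_est$value_pct), NA_real_)
  out <- erec_est
  out$indicator <- "quality_gap"
  out$value_pct <- gap
  out$numerator <- NA_real_
  out$denominator <- NA_real_
  out$ci_low_pct <- NA_real_
  out$ci_high_pct <- NA_real_
  out$ci_method <- NA_character_
  out$undefined <- is.na(gap)
  out
}

#' Wilson score interval
#'
#' Closed-form score interval for a binomial proportion; the lower bound is
#' 0 when there are no successes and the upper bound 1 when all trials
#' succeed.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- if (x == 0) 0 else max(0, centre - half)
  high <- if (x == n) 1 else min(1, centre + half)
  c(low, high)
}

#' Confidence interval for a coverage indicator
#'
#' Two methods are offered. `"wilson"` is the closed-form score interval on
#' the unweighted sample proportion — appropriate for self-weighting
#' samples. `"cluster_bootstrap"` resamples primary sampling units
#' (clusters) with replacement — persons, when no `cluster_id` is present —
#' recomputes the weighted indicator per replicate, and takes the percentile
#' interval; use it whenever weights or clustering matter. Bootstrap
#' replication is seeded and reproducible.
#'
#' @param classified Classified record table ([classify_records()]).
#' @param indicator `"eREC"` or `"REC"`.
#' @param method `"wilson"` or `"cluster_bootstrap"`.
#' @param level Confidence level, default 0.95.
#' @param reps Bootstrap replicates (default 1000; fewer than 100 warns).
#' @param seed Integer seed for the bootstrap.
#' @param mode Passed to the indicator for bootstrap replicates.
#' @return Numeric `c(low, high)` in percent.
#' @export
confidence_interval <- function(classified, indicator = c("eREC", "REC"),
                                method = c("wilson", "cluster_bootstrap"),
                                level = 0.95, reps = 1000, seed = 1,
                                mode = c("counts", "weighted")) {
  indicator <- match.arg(indicator)
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)

  summary <- tabulate_need(classified)
  k <- .summary_counts(summary, "counts")
  den <- k$a + k$b + k$c
  if (den <= 0) return(c(NA_real_, NA_real_))
  num <- if (indicator == "eREC") k$a else k$a + k$b

  if (method == "wilson") {
    return(100 * wilson_interval(num, den, level))
  }

  if (reps < 100) warning("fewer than 100 bootstrap replicates; interval will be unstable",
                          call. = FALSE)
  ids <- if ("cluster_id" %in% names(classified) && !all(is.na(classified$cluster_id))) {
    classified$cluster_id
  } else {
    seq_len(nrow(classified))
  }
  groups <- split(seq_len(nrow(classified)), ids)
  est_fun <- if (indicator == "eREC") erec else rec

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    pick <- sample(length(groups), length(groups), replace = TRUE)
    resampled <- classified[unlist(groups[pick], use.names = FALSE), , drop = FALSE]
    attr(resampled, "thresholds") <- attr(classified, "thresholds")
    est_fun(tabulate_need(resampled), mode = mode)$value_pct
  }, 0)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(c(NA_real_, NA_real_))
  unname(stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
}

#' Stratified coverage estimates
#'
#' One eREC, REC and quality-gap estimate per stratum level combination,
#' plus the overall estimate, with confidence intervals for eREC and REC.
#' Strata whose coverage denominator is zero are flagged `undefined`.
#'
#' @param classified Classified record table.
#' @param by Character vector of stratum column names (`NULL` = overall only).
#' @param mode `"counts"` or `"weighted"`.
#' @param ci_method `"wilson"`, `"cluster_bootstrap"` or `"none"`.
#' @param level,reps,seed Confidence-interval settings.
#' @return A coverage-estimate tibble with a `stratum` label column.
#' @export
stratified_estimates <- function(classified, by = NULL,
                                 mode = c("counts", "weighted"),
                                 ci_method = c("wilson", "cluster_bootstrap", "none"),
                                 level = 0.95, reps = 1000, seed = 1) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)

  pieces <- list(list(label = "overall", rows = classified))
  if (!is.null(by)) {
    missing_by <- setdiff(by, names(classified))
    if (length(missing_by) > 0) {
      stop("unknown stratum label(s): ", paste(missing_by, collapse = ", "),
           call. = FALSE)
    }
    key <- interaction(lapply(by, function(col) classified[[col]]),
                       sep = ";", drop = TRUE, lex.order = TRUE)
    labels <- vapply(strsplit(levels(key), ";", fixed = TRUE), function(vals) {
      paste(paste0(by, "=", vals), collapse = ";")
    }, "")
    for (i in seq_along(levels(key))) {
      rows <- classified[key == levels(key)[i], , drop = FALSE]
      attr(rows, "thresholds") <- attr(classified, "thresholds")
      pieces[[length(pieces) + 1]] <- list(label = labels[i], rows = rows)
    }
  }

  out <- lapply(pieces, function(piece) {
    s <- tabulate_need(piece$rows)
    e <- erec(s, mode)
    r <- rec(s, mode)
    if (ci_method != "none" && e$denominator > 0) {
      ci_e <- confidence_interval(piece$rows, "eREC", ci_method, level, reps, seed, mode)
      ci_r <- confidence_interval(piece$rows, "REC", ci_method, level, reps, seed, mode)
      e$ci_low_pct <- ci_e[1]; e$ci_high_pct <- ci_e[2]; e$ci_method <- ci_method
      r$ci_low_pct <- ci_r[1]; r$ci_high_pct <- ci_r[2]; r$ci_method <- ci_method
    }
    g <- quality_gap(e, r)
    est <- dplyr::bind_rows(e, r, g)
    est$stratum <- piece$label
    counts <- s[, c("n", "n_met", "n_under_met", "n_unmet", "n_no_need",
                    "n_other_vi", "n_indeterminate")]
    dplyr::bind_cols(est, counts[rep(1, nrow(est)), ])
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::relocate(out, "stratum")
  attr(out, "thresholds") <- attr(classified, "thresholds")
  out
}

#' Direct standardisation of stratum estimates
#'
#' Weights stratum-specific coverage by external population shares (e.g. a
#' census age-sex distribution): standardised value = sum over strata of
#' share_s * value_s. Used when the sample's age-sex composition does not
#' match the population of interest.
#'
#' @param stratum_estimates Coverage-estimate tibble from
#'   [stratified_estimates()] (the `overall` rows are ignored), or any
#'   tibble with `stratum`, `indicator` and `value_pct` columns.
#' @param reference Tibble with columns `stratum` (labels matching
#'   `stratum_estimates$stratum`) and `share`; shares must cover every
#'   stratum and sum to 1 (tolerance 1e-9).
#' @param indicator Which indicator to standardise (default `"eREC"`).
#' @return A one-row coverage-estimate tibble with `standardised = TRUE`.
#' @export
standardise <- function(stratum_estimates, reference, indicator = "eREC") {
  est <- stratum_estimates[stratum_estimates$indicator == indicator &
                             stratum_estimates$stratum != "overall", , drop = FALSE]
  if (nrow(est) == 0) stop("no stratum-level estimates to standardise", call. = FALSE)
  if (abs(sum(reference$share) - 1) > 1e-9) {
    stop("reference shares must sum to 1", call. = FALSE)
  }
  missing_ref <- setdiff(est$stratum, reference$stratum)
  if (length(missing_ref) > 0) {
    stop("reference table lacks share(s) for stratum: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  if (any(est$undefined | is.na(est$value_pct))) {
    stop("zero-denominator stratum; use coarser strata for standardisation",
         call. = FALSE)
  }
  share <- reference$share[match(est$stratum, reference$stratum)]
  tibble::tibble(
    stratum = "standardised",
    indicator = indicator,
    value_pct = sum(share * est$value_pct),
    numerator = NA_real_,
    denominator = NA_real_,
    ci_low_pct = NA_real_,
    ci_high_pct = NA_real_,
    ci_method = NA_character_,
    mode = est$mode[1],
    standardised = TRUE,
    undefined = FALSE)
}

#' Coverage report across threshold pairs
#'
#' Runs the full pipeline — classification, tabulation, indicators,
#' confidence intervals and optional stratification — at each requested
#' (need, outcome) threshold pair. The 6/12–6/12 pair is always included
#' (appended with a notice when absent) so that every report is
#' internationally comparable.
#'
#' @param records Person-record tibble (unclassified).
#' @param need_thresholds,outcome_thresholds Character vectors of acuity
#'   notations, paired element-wise (recycled to the longer length).
#' @param by,mode,ci_method,level,reps,seed Passed to
#'   [stratified_estimates()].
#' @param correction_definition Free-text note on how correction was defined
#'   (spectacles vs spectacles + contact lenses), stored in the metadata.
#' @return An `erec_report`: list with `estimates` (tibble over thresholds,
#'   strata and indicators), `summaries` (category counts) and `metadata`.
#' @export
multi_threshold_report <- function(records,
                                   need_thresholds = "6/12",
                                   outcome_thresholds = "6/12",
                                   by = NULL, mode = c("counts", "weighted"),
                                   ci_method = c("wilson", "cluster_bootstrap", "none"),
                                   level = 0.95, reps = 1000, seed = 1,
                                   correction_definition = "spectacles or contact lenses") {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  stopifnot(length(need_thresholds) > 0, length(outcome_thresholds) > 0)
  n_pairs <- max(length(need_thresholds), length(outcome_thresholds))
  pairs <- tibble::tibble(need = rep_len(need_thresholds, n_pairs),
                          outcome = rep_len(outcome_thresholds, n_pairs))
  has_ref <- mapply(function(nd, oc) {
    abs(acuity_logmar(nd) - acuity_logmar("6/12")) < .LOGMAR_TOL &&
      abs(acuity_logmar(oc) - acuity_logmar("6/12")) < .LOGMAR_TOL
  }, pairs$need, pairs$outcome)
  if (!any(has_ref)) {
    message("adding the 6/12 need and outcome thresholds for international comparability")
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(need = "6/12", outcome = "6/12"))
  }
  pairs <- dplyr::distinct(pairs)

  estimates <- list()
  summaries <- list()
  for (i in seq_len(nrow(pairs))) {
    cls <- classify_records(records,
                            acuity_threshold(pairs$need[i], "need"),
                            acuity_threshold(pairs$outcome[i], "outcome"),
                            quiet = TRUE)
    est <- stratified_estimates(cls, by = by, mode = mode, ci_method = ci_method,
                                level = level, reps = reps, seed = seed)
    est <- tibble::add_column(est, need_threshold = pairs$need[i],
                              outcome_threshold = pairs$outcome[i], .before = 1)
    s <- tabulate_need(cls, by = by)
    overall <- tabulate_need(cls)
    if (!is.null(by)) {
      s$stratum <- vapply(seq_len(nrow(s)), function(r) {
        paste(paste0(by, "=", unlist(s[r, by])), collapse = ";")
      }, "")
      s <- dplyr::bind_rows(overall, s[, names(overall)])
    } else {
      s <- overall
    }
    s <- tibble::add_column(s, need_threshold = pairs$need[i],
                            outcome_threshold = pairs$outcome[i], .before = 1)
    estimates[[i]] <- est
    summaries[[i]] <- s
  }

  structure(list(
    estimates = dplyr::bind_rows(estimates),
    summaries = dplyr::bind_rows(summaries),
    metadata = list(
      tool = "erec",
      version = as.character(utils::packageVersion("erec")),
      n_records = nrow(records),
      threshold_pairs = pairs,
      correction_definition = correction_definition,
      mode = mode,
      ci_method = ci_method,
      ci_level = level,
      bootstrap_reps = if (ci_method == "cluster_bootstrap") reps else NA_integer_,
      seed = seed)),
    class = "erec_report")
}

#' @export
print.erec_report <- function(x, ...) {
  cat("<erec_report> ", x$metadata$n_records, " records, ",
      nrow(x$metadata$threshold_pairs), " threshold pair(s)\n", sep = "")
  shown <- x$estimates[, intersect(c("need_threshold", "outcome_threshold",
                                     "stratum", "indicator", "value_pct",
                                     "ci_low_pct", "ci_high_pct"),
                                   names(x$estimates))]
  shown$value_pct <- round_half_up(shown$value_pct, 1)
  print(shown, ...)
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding for reports: 31.25 renders as 31.3 and 37.5 as 38,
#' matching conventional epidemiological reporting rather than IEEE
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
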