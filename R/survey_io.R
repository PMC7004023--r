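# Reading survey tables through a column-mapping configuration and writing
# reports. Surveys never share column conventions, so the mapping is a
# human-editable YAML/JSON document naming the input column for each field,
# the acuity dialect, and value maps for categorical encodings.

#' Build a column mapping
#'
#' Describes how the columns of a survey export correspond to the fields of
#' a person record. Only `wears_correction` and at least one uncorrected-VA
#' eye are mandatory; everything else is optional.
#'
#' @param columns Named list mapping record fields (`person_id`,
#'   `wears_correction`, `ucva_left`, `ucva_right`, `cva_left`, `cva_right`,
#'   `pinhole_left`, `pinhole_right`, `bcva_left`, `bcva_right`,
#'   `age_years`, `sex`, `weight`, `cluster_id`) to input column names.
#' @param acuity_dialect `"metric_6"`, `"imperial_20"` or `"logmar"`; either
#'   a single value for all acuity columns or a named list per field.
#' @param strata Named list mapping stratum labels (e.g. `residence`) to
#'   input column names.
#' @param value_maps Named list of named lists recoding raw values, e.g.
#'   `list(sex = list("1" = "male", "2" = "female"))`.
#' @param correction_definition Text note: spectacles only, or spectacles
#'   plus contact lenses. Carried into report metadata.
#' @return A `column_mapping` object.
#' @export
column_mapping <- function(columns, acuity_dialect = "metric_6",
                           strata = list(), value_maps = list(),
                           correction_definition = "spectacles or contact lenses") {
  mandatory <- c("wears_correction")
  missing_m <- setdiff(mandatory, names(columns))
  if (length(missing_m) > 0 ||
      !any(c("ucva_left", "ucva_right") %in% names(columns))) {
    stop("mapping must name columns for wears_correction and at least one ",
         "of ucva_left/ucva_right", call. = FALSE)
  }
  structure(list(columns = columns,
                 acuity_dialect = acuity_dialect,
                 strata = strata,
                 value_maps = value_maps,
                 correction_definition = correction_definition),
            class = "column_mapping")
}

#' Read a column mapping from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` mapping file with keys
#'   `columns`, and optionally `acuity_dialect`, `strata`, `value_maps`,
#'   `correction_definition`. A template ships with the package:
#'   `system.file("extdata", "worked_example_mapping.yaml", package = "erec")`.
#' @return A `column_mapping` object.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  column_mapping(
    columns = raw$columns,
    acuity_dialect = raw$acuity_dialect %||% "metric_6",
    strata = raw$strata %||% list(),
    value_maps = raw$value_maps %||% list(),
    correction_definition = raw$correction_definition %||%
      "spectacles or contact lenses")
}

.parse_bool <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "yes", "true")] <- TRUE
  out[x %in% c("0", "no", "false")] <- FALSE
  out[x %in% c("", "na")] <- NA
  bad <- !x %in% c("1", "yes", "true", "0", "no", "false", "", "na")
  attr(out, "bad") <- bad
  out
}

.acuity_cols <- c("ucva_left", "ucva_right", "cva_left", "cva_right",
                  "pinhole_left", "pinhole_right", "bcva_left", "bcva_right")

#' Read a survey table into person records
#'
#' Reads a delimited text file (comma or tab, sniffed from the header line),
#' applies the column mapping, parses acuities onto the logMAR scale, and
#' validates rows. Rows that fail validation (unparseable acuity or boolean,
#' non-positive weight) are collected into a rejects table with row numbers
#' and reasons and excluded from the output; more than 50% rejected rows is
#' treated as a mis-configured mapping and raises an error.
#'
#' @param path Path to a CSV/TSV file.
#' @param mapping A `column_mapping`, or a path passed to [read_mapping()].
#' @return A person-record tibble; the rejects table is attached as the
#'   `"rejects"` attribute (columns `row`, `reason`).
#' @export
read_survey <- function(path, mapping) {
  if (is.character(mapping)) mapping <- read_mapping(mapping)
  stopifnot(inherits(mapping, "column_mapping"))
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)

  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")

  wanted <- unlist(c(mapping$columns, mapping$strata))
  absent <- setdiff(unname(wanted), names(raw))
  if (length(absent) > 0) {
    stop("mapped column(s) missing from input header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0) {
    warning("survey file has a valid header but no rows", call. = FALSE)
  }

  reject_reason <- rep(NA_character_, n)
  note_reject <- function(idx, reason) {
    reason <- rep_len(reason, n)
    new <- idx & is.na(reject_reason)
    reject_reason[new] <<- reason[new]
  }
  get_col <- function(field) {
    col <- mapping$columns[[field]]
    if (is.null(col)) return(rep(NA_character_, n))
    vals <- raw[[col]]
    vm <- mapping$value_maps[[field]]
    if (!is.null(vm)) {
      mapped <- unlist(vm)[vals]
      vals <- ifelse(is.na(vals), NA_character_, unname(mapped))
    }
    vals
  }
  dialect_for <- function(field) {
    d <- mapping$acuity_dialect
    if (is.list(d)) d[[field]] %||% "metric_6" else d
  }
  parse_acuity_col <- function(field) {
    vals <- get_col(field)
    uniq <- unique(vals[!is.na(vals)])
    lm_map <- vapply(uniq, function(u) {
      tryCatch(acuity_logmar(parse_acuity(u, dialect_for(field))),
               error = function(e) NA_real_)
    }, 0)
    out <- unname(lm_map[match(vals, uniq)])
    bad <- !is.na(vals) & is.na(out)
    if (any(bad)) {
      note_reject(bad, sprintf("unparseable %s acuity '%s'", field, vals))
    }
    out
  }

  # an unrecognised token rejects the row; a genuinely empty value is kept
  # as missing and surfaces as INDETERMINATE at classification
  wears <- .parse_bool(get_col("wears_correction"))
  note_reject(attr(wears, "bad"), "unrecognised wears_correction value")

  acuity_vals <- lapply(stats::setNames(.acuity_cols, .acuity_cols), parse_acuity_col)

  weight <- suppressWarnings(as.numeric(get_col("weight")))
  if (!is.null(mapping$columns$weight)) {
    note_reject(!is.na(get_col("weight")) & (is.na(weight) | weight <= 0),
                "weight not a positive number")
  }
  weight[is.na(weight)] <- 1

  age <- suppressWarnings(as.integer(get_col("age_years")))

  keep <- is.na(reject_reason)
  rejects <- tibble::tibble(row = which(!keep), reason = reject_reason[!keep])
  if (n > 0 && nrow(rejects) / n > 0.5) {
    stop("more than 50% of rows rejected (", nrow(rejects), "/", n,
         "); check the column mapping. First reasons: ",
         paste(utils::head(unique(rejects$reason), 3), collapse = "; "),
         call. = FALSE)
  }

  ids <- get_col("person_id")
  if (all(is.na(ids))) ids <- as.character(seq_len(n))
  records <- tibble::tibble(
    person_id = ids[keep],
    wears_correction = as.logical(wears)[keep])
  for (field in .acuity_cols) records[[field]] <- acuity_vals[[field]][keep]
  records$age_years <- age[keep]
  records$sex <- get_col("sex")[keep]
  records$weight <- weight[keep]
  records$cluster_id <- get_col("cluster_id")[keep]
  for (label in names(mapping$strata)) {
    vals <- raw[[mapping$strata[[label]]]]
    vm <- mapping$value_maps[[label]]
    if (!is.null(vm)) vals <- unname(unlist(vm)[vals])
    records[[label]] <- vals[keep]
  }

  records <- validate_records(records)
  if (nrow(rejects) > 0) {
    message(nrow(rejects), " of ", n, " rows rejected; see attr(, 'rejects')")
  }
  attr(records, "rejects") <- rejects
  attr(records, "correction_definition") <- mapping$correction_definition
  records
}

#' Write a coverage report to disk
#'
#' Serialises an `erec_report` deterministically (stable key order, fixed
#' decimal formatting) so identical inputs and seeds give byte-identical
#' files. JSON carries the full structure including metadata; CSV is the
#' flat estimates table, one row per indicator x threshold pair x stratum.
#'
#' @param report An `erec_report` from [multi_threshold_report()].
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "erec_report"))
  est <- report$estimates
  num_cols <- vapply(est, is.numeric, TRUE)
  est[num_cols] <- lapply(est[num_cols], function(x) round(x, 6))
  if (format == "csv") {
    utils::write.csv(est, path, row.names = FALSE, na = "")
  } else {
    payload <- list(
      metadata = report$metadata,
      estimates = est,
      summaries = report$summaries)
    payload$metadata$threshold_pairs <- as.data.frame(report$metadata$threshold_pairs)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON coverage report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A list with `metadata`, `estimates` and `summaries` (tibbles).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$estimates <- tibble::as_tibble(raw$estimates)
  raw$summaries <- tibble::as_tibble(raw$summaries)
  raw
}
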