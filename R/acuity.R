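# Visual-acuity parsing, representation and comparison.
#
# All comparisons happen on the logMAR scale (log10 of the minimum angle of
# resolution): 6/6 = 0.0, larger values are worse vision. Survey acuities are
# categorical chart lines, so comparisons use a small absolute tolerance and
# recorded lines compare exactly.

# Low-vision categories are mapped to fixed ordinal sentinels strictly worse
# than any measurable Snellen line; only their order matters downstream.
.LOW_VISION_LOGMAR <- c(CF = 2.0, HM = 2.3, PL = 2.6, NPL = 3.0)

# Absolute tolerance for logMAR comparisons (chart lines differ by ~0.08+).
.LOGMAR_TOL <- 1e-6

#' Parse visual-acuity notation onto the logMAR scale
#'
#' Converts acuity strings to an `acuity` vector: a numeric logMAR vector
#' (larger = worse vision) carrying the original notation and the kind of
#' measurement. Three dialects are supported: 6-metre Snellen fractions
#' (`"6/12"`), 20-foot Snellen fractions (`"20/40"`, converted by ratio
#' equivalence so 20/40 is the same line as 6/12) and decimal logMAR
#' (`"0.3"`). The low-vision categories `CF` (counting fingers), `HM` (hand
#' movements), `PL` (perception of light) and `NPL` (no perception of light)
#' are accepted in every dialect and mapped to fixed ordinal sentinels
#' (logMAR 2.0 / 2.3 / 2.6 / 3.0) strictly worse than any chart line.
#'
#' @param x Character vector of acuity notations. `NA` and empty strings
#'   propagate as missing.
#' @param dialect One of `"metric_6"`, `"imperial_20"`, `"logmar"`.
#' @param context Optional label (e.g. a column name or row number) included
#'   in error messages for unparseable values.
#' @return An `acuity` vector: numeric logMAR values with attributes
#'   `notation` (the text as recorded) and `kind` (`"snellen"`, `"logmar"`
#'   or `"low_vision_category"`).
#' @examples
#' parse_acuity(c("6/60", "6/6", "6/12", "CF"))
#' parse_acuity("20/40", dialect = "imperial_20")   # same line as 6/12
#' @export
parse_acuity <- function(x, dialect = c("metric_6", "imperial_20", "logmar"),
                         context = NULL) {
  dialect <- match.arg(dialect)
  x <- as.character(x)
  raw <- x
  x <- toupper(trimws(x))
  x[x == ""] <- NA_character_

  logmar <- rep(NA_real_, length(x))
  kind <- rep(NA_character_, length(x))

  lv <- match(x, names(.LOW_VISION_LOGMAR))
  is_lv <- !is.na(lv)
  logmar[is_lv] <- .LOW_VISION_LOGMAR[lv[is_lv]]
  kind[is_lv] <- "low_vision_category"

  todo <- !is.na(x) & !is_lv
  if (any(todo)) {
    if (dialect == "logmar") {
      val <- suppressWarnings(as.numeric(x[todo]))
      bad <- is.na(val) | !is.finite(val)
      if (any(bad)) .bad_acuity(raw[todo][bad], context)
      logmar[todo] <- val
      kind[todo] <- "logmar"
    } else {
      m <- regmatches(x[todo],
                      regexec("^([0-9]+(?:\\.[0-9]+)?)\\s*/\\s*([0-9]+(?:\\.[0-9]+)?)$",
                              x[todo]))
      num <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[2]) else NA_real_, 0)
      den <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[3]) else NA_real_, 0)
      bad <- is.na(num) | is.na(den) | num <= 0 | den <= 0
      if (any(bad)) .bad_acuity(raw[todo][bad], context)
      logmar[todo] <- log10(den / num)
      kind[todo] <- "snellen"
      if (dialect == "imperial_20") {
        # canonicalise to the equivalent 6-metre line (20/40 is 6/12)
        d6 <- 6 * den / num
        x[todo] <- paste0("6/", ifelse(abs(d6 - round(d6)) < 1e-6,
                                       round(d6), round(d6, 1)))
      }
    }
  }

  new_acuity(logmar, notation = ifelse(is.na(x), NA_character_, x), kind = kind)
}

.bad_acuity <- function(tokens, context) {
  tokens <- unique(tokens)
  where <- if (is.null(context)) "" else paste0(" in ", context)
  stop("unparseable acuity value(s)", where, ": ",
       paste(sprintf("'%s'", utils::head(tokens, 5)), collapse = ", "),
       call. = FALSE)
}

new_acuity <- function(logmar, notation = NA_character_, kind = NA_character_) {
  structure(as.numeric(logmar),
            notation = rep_len(as.character(notation), length(logmar)),
            kind = rep_len(as.character(kind), length(logmar)),
            class = "acuity")
}

#' @export
print.acuity <- function(x, ...) {
  cat("<acuity[", length(x), "]>\n", sep = "")
  print(stats::setNames(round(unclass(x), 4), format_acuity(x)), ...)
  invisible(x)
}

#' @export
`[.acuity` <- function(x, i) {
  new_acuity(unclass(x)[i], attr(x, "notation")[i], attr(x, "kind")[i])
}

#' Extract logMAR values from acuities
#'
#' Accepts an `acuity` vector, a bare numeric logMAR vector, or character
#' notation (parsed as 6-metre Snellen). Used throughout so thresholds can be
#' given as `"6/12"` strings.
#'
#' @param x Acuity in any of the accepted forms.
#' @return Numeric logMAR vector.
#' @export
acuity_logmar <- function(x) {
  if (inherits(x, "acuity")) return(as.numeric(unclass(x)))
  if (is.character(x)) return(as.numeric(unclass(parse_acuity(x))))
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x) && all(is.na(x))) return(as.numeric(x))
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as an acuity", call. = FALSE)
}

#' Format acuities in canonical 6-metre notation
#'
#' Snellen inputs round-trip to their recorded fraction (imperial fractions
#' are converted to the equivalent 6-metre line); low-vision categories keep
#' their code; decimal logMAR values are rendered as the nearest 6-metre
#' fraction `6/x` with `x = 6 * 10^logmar`.
#'
#' @param x An `acuity` vector or numeric logMAR vector.
#' @return Character vector of canonical 6-metre notations.
#' @export
format_acuity <- function(x) {
  lm <- acuity_logmar(x)
  kind <- if (inherits(x, "acuity")) attr(x, "kind") else rep("logmar", length(lm))
  notation <- if (inherits(x, "acuity")) attr(x, "notation") else rep(NA_character_, length(lm))

  out <- rep(NA_character_, length(lm))
  lv_idx <- !is.na(kind) & kind == "low_vision_category"
  out[lv_idx] <- notation[lv_idx]

  rest <- !is.na(lm) & !lv_idx
  if (any(rest)) {
    # sentinel logMARs without notation still print as their category code
    sent <- rest & lm %in% .LOW_VISION_LOGMAR
    out[sent] <- names(.LOW_VISION_LOGMAR)[match(lm[sent], .LOW_VISION_LOGMAR)]
    rest <- rest & !sent
    den <- 6 * 10^lm[rest]
    den <- ifelse(abs(den - round(den)) < 1e-6, round(den), round(den, 1))
    out[rest] <- paste0("6/", den)
  }
  # Snellen notation round-trips exactly as recorded (imperial fractions
  # were canonicalised to 6-metre form at parse time)
  keep <- !is.na(kind) & kind == "snellen" & !is.na(notation) & grepl("/", notation, fixed = TRUE)
  out[keep] <- gsub("\\s", "", notation[keep])
  out
}

#' @export
format.acuity <- function(x, ...) format_acuity(x)

#' Construct an acuity threshold
#'
#' A threshold pairs an acuity value with its role: `"need"` (is the person
#' vision-impaired by the candidate condition?) or `"outcome"` (does their
#' own correction achieve a good visual outcome?). The default for both
#' roles is 6/12 in the better eye, the WHO mild distance vision impairment
#' cut-off, which all coverage reports should include for international
#' comparability.
#'
#' @param value Acuity notation, `acuity` object or logMAR number. Default
#'   `"6/12"`.
#' @param role `"need"` or `"outcome"`.
#' @return An `acuity_threshold` object.
#' @examples
#' acuity_threshold()               # need threshold 6/12
#' acuity_threshold("6/18", "need") # a laxer impairment threshold
#' @export
acuity_threshold <- function(value = "6/12", role = c("need", "outcome")) {
  role <- match.arg(role)
  if (inherits(value, "acuity_threshold")) return(value)
  lm <- acuity_logmar(value)
  if (length(lm) != 1 || is.na(lm)) {
    stop("a threshold must be a single non-missing acuity", call. = FALSE)
  }
  structure(list(logmar = lm,
                 notation = if (is.character(value)) value else format_acuity(lm),
                 role = role),
            class = "acuity_threshold")
}

#' @export
print.acuity_threshold <- function(x, ...) {
  cat("<acuity_threshold> ", x$notation, " (", x$role,
      "), logMAR ", round(x$logmar, 4), "\n", sep = "")
  invisible(x)
}

#' Is an acuity at or better than a threshold?
#'
#' `TRUE` when the acuity is equal to or better than the threshold, i.e.
#' logMAR(va) <= logMAR(threshold) within a small absolute tolerance so that
#' recorded chart lines compare exactly. "Worse than" the threshold is the
#' exact negation, so every non-missing acuity falls on exactly one side.
#' Missing acuities return `NA`.
#'
#' @param va Acuity vector (any accepted form).
#' @param threshold An `acuity_threshold`, or anything `acuity_threshold()`
#'   accepts.
#' @return Logical vector.
#' @examples
#' meets_threshold(parse_acuity(c("6/12", "6/18", "NPL")), acuity_threshold("6/12"))
#' @export
meets_threshold <- function(va, threshold = acuity_threshold()) {
  if (!inherits(threshold, "acuity_threshold")) threshold <- acuity_threshold(threshold)
  acuity_logmar(va) <= threshold$logmar + .LOGMAR_TOL
}

#' Better-eye acuity
#'
#' Person-level coverage uses vision in the better eye. Returns the smaller
#' logMAR of the two eyes; when one eye is missing the other is used; when
#' both are missing the result is missing (never coerced to worst, so that
#' missingness surfaces as an indeterminate classification downstream).
#'
#' @param left,right Acuity vectors (any accepted form), element-wise.
#' @return Numeric logMAR vector of better-eye acuities.
#' @examples
#' better_eye(parse_acuity("6/60"), parse_acuity("6/9"))  # 6/9
#' @export
better_eye <- function(left, right) {
  l <- acuity_logmar(left)
  r <- acuity_logmar(right)
  n <- max(length(l), length(r))
  l <- rep_len(l, n)
  r <- rep_len(r, n)
  out <- pmin(l, r, na.rm = TRUE)
  out[is.na(l) & is.na(r)] <- NA_real_
  out
}
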