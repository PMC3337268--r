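# Heterogeneous indicator values as found in chronic-study records: the same
# survival-rate indicator appears as '0/5 (weeks 27-30)' in one study and as
# a bare '10/10' in another, and qualitative observations are free strings
# like "MORTALITY, INCREASED". These parsers type such values so records
# from different studies become comparable.

.ratio_rx <- "^\\s*(\\d+)\\s*/\\s*(\\d+)\\s*(?:\\(\\s*weeks\\s+(\\d+)\\s*-\\s*(\\d+)\\s*\\))?\\s*$"

.direction_synonyms <- c(
  INCREASED = "INCREASED", INCREASE = "INCREASED", ELEVATED = "INCREASED",
  DECREASED = "DECREASED", DECREASE = "DECREASED", REDUCED = "DECREASED",
  UNCHANGED = "UNCHANGED", "NO CHANGE" = "UNCHANGED",
  "NOT CHANGED" = "UNCHANGED")

#' Parse survival-ratio strings
#'
#' Parses strings of the form `"<survived>/<tested>"` with an optional
#' observation period `"(weeks <start>-<end>)"` (keyword matched
#' case-insensitively, whitespace flexible) into typed records: the number
#' of surviving animals among the tested ones, optionally during a concrete
#' week interval of the study. Whether the interval qualifies the deaths or
#' the measurement time is not encoded in the source records, so it is
#' stored uninterpreted. A string whose numerator exceeds its denominator is
#' a *domain* error (`toxowl_domain_error`), distinct from a syntax error
#' (`toxowl_parse_error`): "6/5" is well-formed but impossible.
#'
#' @param text Character vector of raw value strings.
#' @param strict If `TRUE` (default), the first offending string raises an
#'   error that carries it. If `FALSE`, offending strings are kept verbatim
#'   with `parsed = FALSE` and NA fields, with a warning -- such records
#'   exist in real databases and must be carried, not dropped.
#' @return A tibble with one row per input: `text`, `numerator`,
#'   `denominator`, `period_start_week`, `period_end_week`, `parsed`.
#' @examples
#' parse_ratio(c("0/5 (weeks 27-30)", "10/10"))
#' @export
parse_ratio <- function(text, strict = TRUE) {
  stopifnot(is.character(text))
  m <- regmatches(text, regexec(.ratio_rx, text, ignore.case = TRUE))
  out <- tibble(text = text,
                numerator = NA_integer_, denominator = NA_integer_,
                period_start_week = NA_integer_,
                period_end_week = NA_integer_,
                parsed = FALSE)
  for (i in seq_along(text)) {
    g <- m[[i]]
    fail <- function(msg, class) {
      if (strict) {
        stop_toxowl(paste0(msg, ": '", text[[i]], "'"), class,
                    offending = text[[i]])
      }
      warn(paste0(msg, ", kept verbatim: '", text[[i]], "'"))
    }
    if (length(g) == 0) {
      fail("unparseable ratio value", "toxowl_parse_error")
      next
    }
    num <- as.integer(g[[2]]); den <- as.integer(g[[3]])
    has_period <- nzchar(g[[4]])
    a <- if (has_period) as.integer(g[[4]]) else NA_integer_
    b <- if (has_period) as.integer(g[[5]]) else NA_integer_
    if (den == 0L) {
      fail("tested-animal count must be positive", "toxowl_domain_error")
      next
    }
    if (num > den) {
      fail("more survivors than tested animals", "toxowl_domain_error")
      next
    }
    if (has_period && (a == 0L || a > b)) {
      fail("invalid week interval", "toxowl_domain_error")
      next
    }
    out$numerator[[i]] <- num
    out$denominator[[i]] <- den
    out$period_start_week[[i]] <- a
    out$period_end_week[[i]] <- b
    out$parsed[[i]] <- TRUE
  }
  out
}

#' Format survival ratios back to their string form
#'
#' Inverse of [parse_ratio()] (the round-trip identity the test suite
#' exercises): `format_ratio(parse_ratio(x))` reproduces the canonical
#' spelling of `x`.
#'
#' @param ratios A tibble as returned by [parse_ratio()], or a data frame
#'   with columns `numerator`, `denominator` and optional
#'   `period_start_week`/`period_end_week`.
#' @return A character vector of value strings.
#' @export
format_ratio <- function(ratios) {
  stopifnot(is.data.frame(ratios))
  ifelse(
    !is.na(ratios$period_start_week),
    sprintf("%d/%d (weeks %d-%d)", ratios$numerator, ratios$denominator,
            ratios$period_start_week, ratios$period_end_week),
    sprintf("%d/%d", ratios$numerator, ratios$denominator))
}

#' Parse qualitative effect strings
#'
#' Parses free-text observations of the form `"<INDICATOR>, <DIRECTION>"`
#' (e.g. `"MORTALITY, INCREASED"`) into an indicator token and a direction
#' from the closed set `INCREASED`/`DECREASED`/`UNCHANGED`. The split is on
#' the *last* comma, so indicators may themselves contain commas; both parts
#' are trimmed and upper-cased, and direction synonyms (`INCREASE`,
#' `ELEVATED`, `REDUCED`, `NO CHANGE`, ...) are mapped onto the closed set.
#'
#' @inheritParams parse_ratio
#' @return A tibble with one row per input: `text`, `indicator`,
#'   `direction`, `parsed`.
#' @examples
#' parse_effect("MORTALITY, INCREASED")
#' @export
parse_effect <- function(text, strict = TRUE) {
  stopifnot(is.character(text))
  out <- tibble(text = text, indicator = NA_character_,
                direction = NA_character_, parsed = FALSE)
  for (i in seq_along(text)) {
    fail <- function(msg) {
      if (strict) {
        stop_toxowl(paste0(msg, ": '", text[[i]], "'"),
                    "toxowl_parse_error", offending = text[[i]])
      }
      warn(paste0(msg, ", kept verbatim: '", text[[i]], "'"))
    }
    pos <- gregexpr(",", text[[i]], fixed = TRUE)[[1]]
    if (pos[[1]] == -1) {
      fail("effect value without a comma")
      next
    }
    cut <- pos[[length(pos)]]
    indicator <- toupper(trimws(substr(text[[i]], 1L, cut - 1L)))
    dir_raw <- toupper(trimws(substring(text[[i]], cut + 1L)))
    if (!nzchar(indicator)) {
      fail("effect value with empty indicator")
      next
    }
    direction <- .direction_synonyms[dir_raw]
    if (is.na(direction)) {
      fail(paste0("unknown direction '", dir_raw, "'"))
      next
    }
    out$indicator[[i]] <- indicator
    out$direction[[i]] <- unname(direction)
    out$parsed[[i]] <- TRUE
  }
  out
}

#' Format qualitative effects back to their string form
#'
#' @param effects A tibble as returned by [parse_effect()], or a data frame
#'   with columns `indicator` and `direction`.
#' @return A character vector of `"<INDICATOR>, <DIRECTION>"` strings.
#' @export
format_effect <- function(effects) {
  stopifnot(is.data.frame(effects))
  paste0(effects$indicator, ", ", effects$direction)
}
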