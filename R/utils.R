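#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble add_row
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_lgl pmap keep imap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# All package errors carry class "toxowl_error" plus a specific subclass so
# callers can distinguish, e.g., a syntax failure from a domain violation.
stop_toxowl <- function(message, class, ...) {
  abort(message, class = c(class, "toxowl_error"), ...)
}

#' Convert a label to UpperCamelCase
#'
#' Splits on whitespace, hyphens and underscores, capitalizes each piece and
#' concatenates. Already-camel-cased labels pass through unchanged; this is the
#' naming convention every generated ontology class uses.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of UpperCamelCase labels.
#' @examples
#' to_upper_camel(c("treatment group", "nervous system and special sense organs"))
#' @export
to_upper_camel <- function(x) {
  vapply(x, function(s) {
    parts <- strsplit(s, "[\\s_\\-]+", perl = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return("")
    paste(paste0(toupper(substring(parts, 1, 1)), substring(parts, 2)),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic local RNG: run `expr` under a seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

path_parts <- function(path) strsplit(path, "/", fixed = TRUE)

parent_of <- function(path) {
  parts <- path_parts(path)[[1]]
  if (length(parts) <= 1) return("")
  paste(parts[-length(parts)], collapse = "/")
}

terminal_name <- function(path) {
  vapply(path_parts(path), function(p) p[length(p)], character(1))
}
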