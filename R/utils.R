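#' @keywords internal
"_PACKAGE"

# Condition helpers: the CLI maps these classes onto exit codes, so every
# user-facing validation failure in the package goes through one of them.

stop_schema <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("sociodom_schema_error", "error", "condition")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("sociodom_validation_error", "error", "condition")))
}

stop_param <- function(msg) {
  stop(errorCondition(msg, class = c("sociodom_param_error", "error", "condition")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("sociodom_io_error", "error", "condition")))
}

#' Canonical ordering of animal or bin identifiers
#'
#' Identifiers are opaque strings, but field data often use numeric-looking
#' ids (ear-tag numbers such as "227"). When every id parses as a plain
#' integer the ids are ordered numerically so that printed tables match the
#' conventional ear-tag order; otherwise a plain lexicographic (radix) sort
#' is used. Leading zeros survive either way because the ids themselves are
#' never converted.
#'
#' @param ids character vector of identifiers.
#' @return the ids in canonical order, duplicates removed.
#' @export
sort_ids <- function(ids) {
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) return(character(0))
  if (all(grepl("^[0-9]+$", ids))) {
    ids[order(as.numeric(ids), ids, method = "radix")]
  } else {
    sort(ids, method = "radix")
  }
}

# shared integer-second gap: timestamps carry second resolution, so gaps are
# computed in whole seconds and rounded to kill floating noise from POSIXct
gap_seconds <- function(later, earlier) {
  round(as.numeric(later) - as.numeric(earlier))
}
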