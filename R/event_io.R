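# Reading, validating and writing bin-event logs and interaction tables.
#
# Electronic feeder/drinker systems export one row per visit: which bin,
# which animal, when it entered and when it left. Raw exports sometimes
# carry entry time plus a duration instead of an exit time; and date/time
# may be split over two columns. Everything downstream works on the
# normalised `event_log` produced here.

DEFAULT_DATETIME_FORMAT <- "%d/%m/%Y %H:%M:%S"

# case-insensitive, trimmed header lookup; returns index or NA
match_column <- function(header, name) {
  idx <- match(tolower(name), tolower(trimws(header)))
  idx
}

# locate a timestamp column that may be split into "<name>_date"/"<name>_time"
# (or "<name> date"/"<name> time"); returns a character vector of values or
# NULL when absent entirely
extract_datetime_column <- function(df, name) {
  idx <- match_column(names(df), name)
  if (!is.na(idx)) return(trimws(df[[idx]]))
  parts <- vapply(c("_date", " date"), function(sfx) match_column(names(df), paste0(name, sfx)),
                  integer(1))
  d <- parts[!is.na(parts)][1]
  parts <- vapply(c("_time", " time"), function(sfx) match_column(names(df), paste0(name, sfx)),
                  integer(1))
  t <- parts[!is.na(parts)][1]
  if (!is.na(d) && !is.na(t)) {
    return(paste(trimws(df[[d]]), trimws(df[[t]])))
  }
  NULL
}

parse_timestamps <- function(x, datetime_format, what, lenient = FALSE) {
  out <- as.POSIXct(x, format = datetime_format, tz = "UTC")
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  bad <- unique(c(bad, which(is.na(x) | !nzchar(trimws(x)))))
  if (length(bad) > 0 && !lenient) {
    stop_validation(sprintf(
      "unparseable %s timestamp(s) with format '%s' at data row(s): %s",
      what, datetime_format, paste(utils::head(sort(bad), 10), collapse = ", ")))
  }
  out
}

new_event_log <- function(equip_id, animal_id, t_in, t_out) {
  df <- data.frame(
    equip_id = as.character(equip_id),
    animal_id = as.character(animal_id),
    t_in = t_in,
    t_out = t_out,
    stringsAsFactors = FALSE
  )
  class(df) <- c("event_log", "data.frame")
  df
}

validate_event_log <- function(df, lenient = FALSE) {
  if (any(!nzchar(df$equip_id)) || any(!nzchar(df$animal_id))) {
    bad <- which(!nzchar(df$equip_id) | !nzchar(df$animal_id))
    if (lenient) {
      warning(sprintf("dropping %d row(s) with empty equip_id/animal_id", length(bad)))
      df <- df[-bad, , drop = FALSE]
    } else {
      stop_validation(sprintf("empty equip_id or animal_id at data row(s): %s",
                              paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  neg <- which(gap_seconds(df$t_out, df$t_in) < 0)
  if (length(neg) > 0) {
    if (lenient) {
      warning(sprintf("dropping %d row(s) with OUT earlier than IN", length(neg)))
      df <- df[-neg, , drop = FALSE]
    } else {
      stop_validation(sprintf("OUT earlier than IN at data row(s): %s",
                              paste(utils::head(neg, 10), collapse = ", ")))
    }
  }
  rownames(df) <- NULL
  df
}

#' Read an electronic bin event log
#'
#' Reads a CSV export of visits to electronic feed/water bins. The file must
#' carry columns `equip_id`, `animal_id`, `IN` and `OUT` (matched
#' case-insensitively after trimming; use `col_map` to translate other
#' headers). `IN`/`OUT` may each arrive either as a single
#' "dd/mm/yyyy HH:MM:SS" column or split into `*_date` and `*_time`
#' columns, which are concatenated with a space before parsing.
#'
#' Identifiers are kept as opaque strings: ear-tag numbers keep leading
#' zeros and are never coerced to numeric.
#'
#' @param path path to the CSV file.
#' @param datetime_format timestamp format, default `"%d/%m/%Y %H:%M:%S"`.
#' @param col_map optional named character vector mapping file column names
#'   to the canonical names, e.g. `c(feeder = "equip_id", tag = "animal_id")`.
#' @param lenient if `TRUE`, rows failing validation (bad timestamps,
#'   `OUT` before `IN`, empty ids) are dropped with a warning instead of
#'   raising an error.
#' @param delim field delimiter, default comma.
#' @return an `event_log`: a data frame with columns `equip_id`,
#'   `animal_id`, `t_in`, `t_out` (POSIXct, treated as naive local times).
#' @seealso [derive_out_from_duration()] for exports carrying a duration
#'   instead of an exit time, [detect_replacements()] for the next stage.
#' @export
read_bin_events <- function(path, datetime_format = DEFAULT_DATETIME_FORMAT,
                            col_map = NULL, lenient = FALSE, delim = ",") {
  if (!file.exists(path)) stop_io(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        sep = delim, strip.white = TRUE)
  df <- apply_col_map(df, col_map)
  as_event_log(df, datetime_format = datetime_format, lenient = lenient)
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  hit <- match(names(col_map), names(df))
  names(df)[hit[!is.na(hit)]] <- unname(col_map[!is.na(hit)])
  df
}

#' Coerce a raw visit table to an event log
#'
#' @param df a data frame with columns `equip_id`, `animal_id`, `IN`, `OUT`
#'   (timestamps as character in `datetime_format`, or already POSIXct).
#' @inheritParams read_bin_events
#' @return an `event_log`.
#' @export
as_event_log <- function(df, datetime_format = DEFAULT_DATETIME_FORMAT,
                         lenient = FALSE) {
  for (req in c("equip_id", "animal_id")) {
    if (is.na(match_column(names(df), req))) {
      stop_schema(sprintf("missing required column: %s", req))
    }
  }
  t_in_raw <- extract_datetime_column(df, "IN")
  t_out_raw <- extract_datetime_column(df, "OUT")
  if (is.null(t_in_raw)) stop_schema("missing required column: IN")
  if (is.null(t_out_raw)) stop_schema("missing required column: OUT")
  t_in <- parse_timestamps(t_in_raw, datetime_format, "IN", lenient)
  t_out <- parse_timestamps(t_out_raw, datetime_format, "OUT", lenient)
  keep <- !(is.na(t_in) | is.na(t_out))
  if (lenient && !all(keep)) {
    warning(sprintf("dropping %d row(s) with unparseable timestamps", sum(!keep)))
  }
  log <- new_event_log(
    equip_id = trimws(df[[match_column(names(df), "equip_id")]])[keep],
    animal_id = trimws(df[[match_column(names(df), "animal_id")]])[keep],
    t_in = t_in[keep], t_out = t_out[keep])
  validate_event_log(log, lenient = lenient)
}

#' Derive exit times from visit durations
#'
#' Some bin systems export the entry timestamp and the visit duration in
#' seconds rather than an exit timestamp. The exit time is the entry time
#' plus the duration; visits crossing midnight roll the date forward
#' automatically through POSIXct arithmetic.
#'
#' @param raw a data frame (or CSV path) with columns `equip_id`,
#'   `animal_id`, `IN` and `duration_s` (case-insensitive).
#' @inheritParams read_bin_events
#' @return an `event_log` with `t_out = t_in + duration_s`.
#' @export
derive_out_from_duration <- function(raw, datetime_format = DEFAULT_DATETIME_FORMAT,
                                     col_map = NULL, lenient = FALSE) {
  if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) stop_io(sprintf("input file not found: %s", raw))
    raw <- utils::read.csv(raw, colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  }
  raw <- apply_col_map(raw, col_map)
  for (req in c("equip_id", "animal_id", "IN", "duration_s")) {
    if (is.na(match_column(names(raw), req)) &&
        !(req == "IN" && !is.null(extract_datetime_column(raw, "IN")))) {
      stop_schema(sprintf("missing required column: %s", req))
    }
  }
  t_in <- parse_timestamps(extract_datetime_column(raw, "IN"),
                           datetime_format, "IN", lenient)
  dur <- suppressWarnings(as.numeric(raw[[match_column(names(raw), "duration_s")]]))
  bad <- which(is.na(dur) | dur < 0)
  if (length(bad) > 0) {
    if (lenient) {
      warning(sprintf("dropping %d row(s) with missing/negative duration", length(bad)))
    } else {
      stop_validation(sprintf("negative or missing duration_s at data row(s): %s",
                              paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  keep <- !(is.na(t_in) | is.na(dur) | dur < 0)
  log <- new_event_log(
    equip_id = trimws(raw[[match_column(names(raw), "equip_id")]])[keep],
    animal_id = trimws(raw[[match_column(names(raw), "animal_id")]])[keep],
    t_in = t_in[keep],
    t_out = t_in[keep] + dur[keep])
  validate_event_log(log, lenient = lenient)
}

#' Animals and bins present in an event log
#'
#' @param log an `event_log`.
#' @return character vector of distinct ids in canonical order.
#' @export
animals <- function(log) sort_ids(log$animal_id)

#' @rdname animals
#' @export
bins <- function(log) sort_ids(log$equip_id)

#' Sort an event log canonically
#'
#' Stable sort by bin, then entry time; ties keep input order (a warning is
#' emitted downstream when simultaneous entries at one bin make the
#' actor/reactor assignment depend on file order).
#'
#' @param log an `event_log`.
#' @return the sorted `event_log`.
#' @export
sort_event_log <- function(log) {
  ord <- order(log$equip_id, log$t_in, method = "radix")
  out <- log[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events, %d animals, %d bins\n",
              nrow(x), length(unique(x$animal_id)), length(unique(x$equip_id))))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

new_interaction_list <- function(actor, reactor, equip_id = NULL, t = NULL) {
  df <- data.frame(actor = as.character(actor), reactor = as.character(reactor),
                   stringsAsFactors = FALSE)
  if (!is.null(equip_id)) df$equip_id <- as.character(equip_id)
  if (!is.null(t)) df$t <- t
  class(df) <- c("interaction_list", "data.frame")
  df
}

#' Read an observational interaction table
#'
#' For competition data collected by direct observation or video rather
#' than electronic bins: a CSV with one row per agonistic interaction and
#' columns `actor` (winner/displacer) and `reactor` (loser/displaced).
#' Input order is preserved — sequential indices such as the Elo rating
#' depend on it.
#'
#' @param path path to the CSV file.
#' @param lenient if `TRUE`, self-interaction rows (`actor == reactor`) are
#'   dropped with a warning instead of raising an error.
#' @param delim field delimiter, default comma.
#' @return an `interaction_list`: a data frame with columns `actor`,
#'   `reactor` and, when present in the file, `equip_id` and `t`.
#' @export
read_interactions <- function(path, lenient = FALSE, delim = ",") {
  if (!file.exists(path)) stop_io(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        sep = delim, strip.white = TRUE)
  for (req in c("actor", "reactor")) {
    if (is.na(match_column(names(df), req))) {
      stop_schema(sprintf("missing required column: %s", req))
    }
  }
  actor <- trimws(df[[match_column(names(df), "actor")]])
  reactor <- trimws(df[[match_column(names(df), "reactor")]])
  eq_idx <- match_column(names(df), "equip_id")
  eq <- if (!is.na(eq_idx)) trimws(df[[eq_idx]]) else NULL
  bad <- which(actor == reactor)
  if (length(bad) > 0) {
    if (lenient) {
      warning(sprintf("dropping %d row(s) with actor == reactor", length(bad)))
      actor <- actor[-bad]; reactor <- reactor[-bad]
      if (!is.null(eq)) eq <- eq[-bad]
    } else {
      stop_validation(sprintf("actor equals reactor at data row(s): %s",
                              paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  new_interaction_list(actor, reactor, equip_id = eq)
}

#' @export
print.interaction_list <- function(x, ...) {
  cat(sprintf("<interaction_list> %d interactions, %d animals\n",
              nrow(x), length(unique(c(x$actor, x$reactor)))))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Write a result table or matrix to CSV
#'
#' Data-frame results (interaction lists, frequency tables, dominance
#' tables) are written as plain CSV with a header. Square matrices
#' (sociomatrix, dyadic matrix) are written in display orientation:
#' reactor labels down the first column (headed `reactor`), actor labels
#' across the header — the transpose of the internal rows-are-actors
#' convention. [read_result()] reverses either layout exactly.
#'
#' @param obj a result object produced by this package.
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_table <- function(obj, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("output directory does not exist: %s", dir))
  if (is.matrix(obj)) {
    disp <- t(unclass(obj))  # rows = reactors, columns = actors
    df <- data.frame(reactor = rownames(disp), disp, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (is.data.frame(obj)) {
    df <- as.data.frame(obj)
    if ("t" %in% names(df) && inherits(df$t, "POSIXct")) {
      df$t <- format(df$t, DEFAULT_DATETIME_FORMAT)
    }
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop_param("write_table() expects a data frame or labelled matrix result")
  }
  invisible(path)
}

#' Read back a result written by [write_table()]
#'
#' @param path CSV path written by [write_table()].
#' @param type one of `"interactions"`, `"frequency"`, `"bin_frequency"`,
#'   `"dominance"`, `"sociomatrix"`, `"dyadic"`, `"scores"`.
#' @param datetime_format timestamp format for the optional `t` column.
#' @return the reconstructed object.
#' @export
read_result <- function(path, type = c("interactions", "frequency", "bin_frequency",
                                       "dominance", "sociomatrix", "dyadic", "scores"),
                        datetime_format = DEFAULT_DATETIME_FORMAT) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_io(sprintf("input file not found: %s", path))
  if (type %in% c("sociomatrix", "dyadic")) {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    labs <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- labs
    m <- t(m)  # back to rows = actors
    class(m) <- c(if (type == "sociomatrix") "socio_matrix" else "dyadic_matrix",
                  class(m))
    return(m)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  num <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else NULL
  switch(type,
    interactions = {
      il <- new_interaction_list(df$actor, df$reactor, equip_id = df$equip_id)
      if ("t" %in% names(df)) {
        il$t <- as.POSIXct(df$t, format = datetime_format, tz = "UTC")
      }
      il
    },
    frequency = {
      out <- data.frame(animal_id = df$animal_id,
                        count = as.integer(df$count),
                        percent = num("percent"), stringsAsFactors = FALSE)
      class(out) <- c("frequency_table", "data.frame")
      out
    },
    bin_frequency = {
      out <- data.frame(equip_id = df$equip_id,
                        replacements = as.integer(df$replacements),
                        percent = num("percent"), stringsAsFactors = FALSE)
      class(out) <- c("bin_frequency_table", "data.frame")
      out
    },
    dominance = {
      out <- data.frame(animal_id = df$animal_id,
                        dominance_value = as.integer(df$dominance_value),
                        stringsAsFactors = FALSE)
      if ("social_rank" %in% names(df)) out$social_rank <- df$social_rank
      if ("social_hierarchy" %in% names(df)) out$social_hierarchy <- df$social_hierarchy
      class(out) <- c("dominance_table", "data.frame")
      out
    },
    scores = {
      out <- data.frame(animal_id = df$animal_id, score = num("score"),
                        stringsAsFactors = FALSE)
      if ("method" %in% names(df)) attr(out, "method") <- df$method[1L]
      class(out) <- c("score_table", "data.frame")
      out
    })
}
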