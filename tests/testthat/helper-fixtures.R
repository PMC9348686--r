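# Fixture builders and independent oracles shared across the suite.

DT_FMT <- "%d/%m/%Y %H:%M:%S"

write_csv_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

stamp <- function(x) format(x, DT_FMT)

base_time <- function(s = "01/03/2021 08:00:00") {
  as.POSIXct(s, format = DT_FMT, tz = "UTC")
}

# random raw visit log with frequent collisions (overlaps, self-succession,
# simultaneous entries are all possible) — deliberately messier than the
# package's own generator
random_raw_log <- function(n_events, n_animals = 6, n_bins = 3, span = 1800,
                           max_dur = 120) {
  t0 <- base_time()
  t_in <- t0 + sample.int(span, n_events, replace = TRUE)
  dur <- sample.int(max_dur, n_events, replace = TRUE)
  df <- data.frame(
    equip_id = sample(sprintf("F%d", seq_len(n_bins)), n_events, replace = TRUE),
    animal_id = sample(sprintf("%d", 100 + seq_len(n_animals)), n_events,
                       replace = TRUE),
    IN = stamp(t_in), OUT = stamp(t_in + dur),
    stringsAsFactors = FALSE)
  as_event_log(df)
}

# independent detection oracle: explicit enumeration of every consecutive
# same-bin pair after a per-bin stable sort, no shared code with the
# package's linear scan
brute_force_replacements <- function(log, sec, cmp = "lt") {
  rows <- list()
  for (b in unique(log$equip_id)) {
    ev <- log[log$equip_id == b, , drop = FALSE]
    ev <- ev[order(as.numeric(ev$t_in)), , drop = FALSE]
    if (nrow(ev) < 2L) next
    for (i in 2:nrow(ev)) {
      gap <- round(as.numeric(ev$t_in[i]) - as.numeric(ev$t_out[i - 1L]))
      qualifies <- gap >= 0 &&
        (if (cmp == "lt") gap < sec else gap <= sec) &&
        ev$animal_id[i] != ev$animal_id[i - 1L]
      if (qualifies) {
        rows[[length(rows) + 1L]] <- data.frame(
          actor = ev$animal_id[i], reactor = ev$animal_id[i - 1L],
          equip_id = b, t = ev$t_in[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    data.frame(actor = character(0), reactor = character(0),
               equip_id = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}

interaction_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$actor, df$reactor, df$equip_id,
             as.numeric(df$t), sep = "|"))
}

# random sociomatrix over n animals with controllable sparsity
random_sociomatrix <- function(n, n_interactions, p_dyad = 1) {
  ids <- sprintf("%d", 200 + seq_len(n))
  pairs <- t(combn(n, 2))
  live <- pairs[runif(nrow(pairs)) < p_dyad, , drop = FALSE]
  if (nrow(live) == 0L || n_interactions == 0L) {
    return(sociomatrix(data.frame(actor = character(0), reactor = character(0)),
                       roster = ids))
  }
  k <- sample.int(nrow(live), n_interactions, replace = TRUE)
  flip <- runif(n_interactions) < 0.5
  actor <- ifelse(flip, live[k, 1], live[k, 2])
  reactor <- ifelse(flip, live[k, 2], live[k, 1])
  sociomatrix(data.frame(actor = ids[actor], reactor = ids[reactor],
                         stringsAsFactors = FALSE), roster = ids)
}

# dyadic matrix of a strict linear order over n animals
linear_dyadic <- function(n) {
  ids <- sprintf("%d", 100 + seq_len(n))
  pairs <- t(combn(n, 2))
  il <- data.frame(actor = ids[pairs[, 1]], reactor = ids[pairs[, 2]],
                   stringsAsFactors = FALSE)
  dyadic_matrix(sociomatrix(il))
}
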