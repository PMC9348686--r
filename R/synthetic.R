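# Synthetic interaction lists and bin-event logs with a known latent
# hierarchy, so detection and ranking can be validated end to end without
# field data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

default_ids <- function(n) sprintf("%d", 100 + seq_len(n))

#' Simulate agonistic interactions under a latent linear hierarchy
#'
#' Draws a latent strict dominance order (a random permutation of the
#' animal ids, dominant first), then stages `n_events` contests: each
#' picks an unordered dyad uniformly at random, and the higher-ranked
#' animal wins (is the actor) with probability `1 - p_upset`.
#'
#' @param n_animals group size (>= 2).
#' @param n_events number of interactions to stage (>= 0).
#' @param p_upset probability the lower-ranked animal wins, in `[0, 0.5]`.
#' @param seed integer seed; the global RNG state is restored afterwards.
#' @param ids optional animal ids (default ear-tag-style "101", "102", ...).
#' @return a list with `interactions` (an `interaction_list`) and `truth`
#'   (a `synthetic_truth` list carrying `latent_order` — dominant first —
#'   `p_upset` and `seed`).
#' @export
simulate_interactions <- function(n_animals, n_events, p_upset = 0.1,
                                  seed = NULL, ids = NULL) {
  if (!is.numeric(n_animals) || n_animals < 2) {
    stop_param("n_animals must be at least 2")
  }
  if (!is.numeric(n_events) || n_events < 0) {
    stop_param("n_events must be non-negative")
  }
  if (!is.numeric(p_upset) || p_upset < 0 || p_upset > 0.5) {
    stop_param("p_upset must lie in [0, 0.5]")
  }
  if (is.null(ids)) ids <- default_ids(n_animals)
  if (length(ids) != n_animals) stop_param("ids must have length n_animals")
  with_seed(seed, {
    latent <- sample(ids)  # latent[1] is the most dominant
    if (n_events > 0) {
      i <- sample.int(n_animals - 1L, n_events, replace = TRUE)
      j_off <- vapply(i, function(ii) sample.int(n_animals - ii, 1L), integer(1))
      j <- i + j_off  # i < j: i is the higher-ranked of the dyad
      upset <- stats::runif(n_events) < p_upset
      actor_rank <- ifelse(upset, j, i)
      reactor_rank <- ifelse(upset, i, j)
      il <- new_interaction_list(latent[actor_rank], latent[reactor_rank])
    } else {
      il <- new_interaction_list(character(0), character(0))
    }
    truth <- structure(list(latent_order = latent, p_upset = p_upset,
                            inserted_replacements = NULL, seed = seed),
                       class = "synthetic_truth")
    list(interactions = il, truth = truth)
  })
}

#' Simulate a bin event log with staged replacements
#'
#' Builds a visit log for `n_bins` electronic bins over `n_days` days.
#' Each bin's timeline is a sequence of "slots" separated by
#' `slot_gap` seconds (well above any detection threshold under test).
#' A slot is either a single background visit by a random animal, or a
#' staged replacement: two visits by different animals where the second
#' animal enters `gap` seconds after the first leaves, with `gap` drawn
#' uniformly from `gap_range`. Staged pairs follow the latent hierarchy
#' with upset probability `p_upset`, exactly as in
#' [simulate_interactions()]. Because slot boundaries are `slot_gap`
#' seconds wide, detection at any threshold between `max(gap_range)` and
#' `slot_gap` recovers precisely the staged pairs: precision and recall 1
#' by construction.
#'
#' Visit durations are exponential with mean `visit_duration_mean`
#' seconds, rounded to whole seconds; bins are chosen uniformly.
#'
#' @param n_animals group size (>= 2).
#' @param n_bins number of bins.
#' @param n_days days of recording (spreads slots over days).
#' @param visit_rate mean background visits per animal per day; the total
#'   background count is Poisson unless `background_events` fixes it.
#' @param gap_range integer two-vector, inclusive bounds (seconds) for
#'   staged replacement gaps.
#' @param n_replacements number of staged replacement pairs.
#' @param background_events optional exact number of background visits.
#' @param p_upset probability the lower-ranked animal displaces the
#'   higher-ranked, in `[0, 0.5]`.
#' @param seed integer seed; RNG state restored afterwards.
#' @param visit_duration_mean mean visit duration in seconds.
#' @param slot_gap seconds between consecutive slots at one bin; must
#'   exceed any detection threshold you intend to test.
#' @param ids optional animal ids.
#' @return a list with `log` (an `event_log`) and `truth` (a
#'   `synthetic_truth` whose `inserted_replacements` data frame records
#'   `actor`, `reactor`, `equip_id`, `gap` and `t` for every staged pair).
#' @export
simulate_bin_log <- function(n_animals = 20, n_bins = 5, n_days = 3,
                             visit_rate = 10, gap_range = c(0, 9),
                             n_replacements = 50, background_events = NULL,
                             p_upset = 0.1, seed = NULL,
                             visit_duration_mean = 120, slot_gap = 300,
                             ids = NULL) {
  if (!is.numeric(n_animals) || n_animals < 2) stop_param("n_animals must be at least 2")
  if (n_bins < 1 || n_days < 1) stop_param("n_bins and n_days must be positive")
  if (visit_rate < 0 || n_replacements < 0) {
    stop_param("visit_rate and n_replacements must be non-negative")
  }
  if (length(gap_range) != 2L || any(gap_range < 0) || gap_range[1] > gap_range[2]) {
    stop_param("gap_range must be c(lo, hi) with 0 <= lo <= hi")
  }
  if (!is.numeric(p_upset) || p_upset < 0 || p_upset > 0.5) {
    stop_param("p_upset must lie in [0, 0.5]")
  }
  if (slot_gap <= gap_range[2]) stop_param("slot_gap must exceed max(gap_range)")
  if (is.null(ids)) ids <- default_ids(n_animals)
  with_seed(seed, {
    latent <- sample(ids)
    n_bg <- if (is.null(background_events)) {
      stats::rpois(1, visit_rate * n_animals * n_days)
    } else as.integer(background_events)
    # slot plan: background slots and replacement slots, shuffled over bins
    kind <- sample(c(rep("bg", n_bg), rep("rep", n_replacements)))
    bin_of <- sample(sprintf("B%d", seq_len(n_bins)), length(kind), replace = TRUE)
    t0 <- as.POSIXct("01/06/2021 06:00:00", format = DEFAULT_DATETIME_FORMAT,
                     tz = "UTC")
    rows <- vector("list", length(kind))
    truth_rows <- list()
    cursor <- stats::setNames(rep(0, n_bins), sprintf("B%d", seq_len(n_bins)))
    dur <- function() max(1, round(stats::rexp(1, 1 / visit_duration_mean)))
    for (s in seq_along(kind)) {
      b <- bin_of[s]
      t_start <- t0 + cursor[b]
      if (kind[s] == "bg") {
        a <- sample(ids, 1)
        d <- dur()
        rows[[s]] <- data.frame(equip_id = b, animal_id = a,
                                t_in = t_start, t_out = t_start + d,
                                stringsAsFactors = FALSE)
        cursor[b] <- cursor[b] + d + slot_gap
      } else {
        pair <- sort(sample.int(n_animals, 2))  # ranks in latent order
        upset <- stats::runif(1) < p_upset
        winner <- latent[if (upset) pair[2] else pair[1]]
        loser <- latent[if (upset) pair[1] else pair[2]]
        g <- gap_range[1] + sample.int(gap_range[2] - gap_range[1] + 1L, 1L) - 1L
        d1 <- dur(); d2 <- dur()
        t2 <- t_start + d1 + g
        rows[[s]] <- data.frame(
          equip_id = c(b, b), animal_id = c(loser, winner),
          t_in = c(t_start, t2), t_out = c(t_start + d1, t2 + d2),
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          actor = winner, reactor = loser, equip_id = b, gap = g, t = t2,
          stringsAsFactors = FALSE)
        cursor[b] <- cursor[b] + d1 + g + d2 + slot_gap
      }
    }
    log <- if (length(rows) > 0) {
      df <- do.call(rbind, rows)
      new_event_log(df$equip_id, df$animal_id, df$t_in, df$t_out)
    } else {
      new_event_log(character(0), character(0),
                    as.POSIXct(character(0), tz = "UTC"),
                    as.POSIXct(character(0), tz = "UTC"))
    }
    inserted <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
      data.frame(actor = character(0), reactor = character(0),
                 equip_id = character(0), gap = integer(0),
                 t = as.POSIXct(character(0), tz = "UTC"),
                 stringsAsFactors = FALSE)
    truth <- structure(list(latent_order = latent, p_upset = p_upset,
                            inserted_replacements = inserted, seed = seed),
                       class = "synthetic_truth")
    list(log = log, truth = truth)
  })
}
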