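# Sociomatrix, dyadic dominance matrix and Kondo-Hurnik dominance values.
#
# Internal matrix convention: rows are actors, columns are reactors, so
# X[i, j] counts the interactions i won over j. CSV serialisation through
# write_table() transposes to the conventional display orientation
# (reactors down the rows, actors across the columns).

#' Build a sociomatrix from an interaction list
#'
#' The sociomatrix X is the square count matrix of the group's competition:
#' `X[i, j]` is the number of interactions with animal i as actor (winner)
#' and j as reactor (loser). Labels are the union of ids appearing in the
#' interactions and an optional roster, in canonical order (numeric-aware
#' for ear-tag-style ids, see [sort_ids()]).
#'
#' @param interactions an `interaction_list` (or data frame with columns
#'   `actor` and `reactor`).
#' @param roster optional character vector of additional animal ids to
#'   include as all-zero rows/columns (animals never observed competing).
#' @return a `socio_matrix`: an integer matrix with identical row and
#'   column labels, zero diagonal, total sum equal to `nrow(interactions)`.
#' @export
sociomatrix <- function(interactions, roster = NULL) {
  labs <- sort_ids(c(interactions$actor, interactions$reactor, roster))
  n <- length(labs)
  X <- matrix(0L, n, n, dimnames = list(labs, labs))
  if (nrow(interactions) > 0L) {
    tab <- table(factor(interactions$actor, levels = labs),
                 factor(interactions$reactor, levels = labs))
    X <- X + unclass(tab)
    storage.mode(X) <- "integer"
    dimnames(X) <- list(labs, labs)
  }
  structure(X, class = c("socio_matrix", class(matrix())))
}

#' Dyadic dominance relationship matrix
#'
#' Reduces the sociomatrix to the sign of each dyad's net outcome:
#' `S[i, j] = sign(X[i, j] - X[j, i])`, i.e. +1 where i dominates j
#' (more wins than losses), -1 where i is subordinate, and 0 both for tied
#' dyads (equal non-zero win counts) and unknown dyads (no interactions in
#' either direction) — the zero case also guards the 0/0 division in the
#' sign formula. The result is antisymmetric with a zero diagonal.
#'
#' @param m a `socio_matrix`.
#' @return a `dyadic_matrix`: an integer matrix with entries in
#'   \{-1, 0, +1\}.
#' @export
dyadic_matrix <- function(m) {
  X <- unclass(m)
  S <- sign(X - t(X))
  storage.mode(S) <- "integer"
  dimnames(S) <- dimnames(m)
  structure(S, class = c("dyadic_matrix", class(matrix())))
}

#' Kondo-Hurnik dominance values with social rank and hierarchy
#'
#' The dominance value of animal i is the sum of its dyadic relationships
#' over all herd mates, `S_i = sum_j S[i, j]` — the number of animals it
#' dominates minus the number it is subordinate to. Values sum to zero
#' over the group and are bounded by n - 1 in absolute value.
#'
#' Social categories split the observed value range into equal-width bins
#' (see [categorize()]): two bins give the social rank (low/high), three
#' give the social hierarchy (subordinate/intermediate/dominant).
#'
#' @param d a `dyadic_matrix`.
#' @param with_rank add the 2-category `social_rank` column (default TRUE).
#' @param with_hierarchy add the 3-category `social_hierarchy` column
#'   (default TRUE).
#' @param rank_labels,hierarchy_labels category labels in ascending order
#'   of dominance; override for byte-level compatibility with other tools.
#' @return a `dominance_table` data frame with columns `animal_id`,
#'   `dominance_value` and the requested category columns, sorted by
#'   ascending dominance value.
#' @export
dominance_values <- function(d, with_rank = TRUE, with_hierarchy = TRUE,
                             rank_labels = c("low", "high"),
                             hierarchy_labels = c("subordinate", "intermediate",
                                                  "dominant")) {
  if (nrow(d) == 0L) {
    out <- data.frame(animal_id = character(0), dominance_value = integer(0),
                      stringsAsFactors = FALSE)
    if (with_rank) out$social_rank <- character(0)
    if (with_hierarchy) out$social_hierarchy <- character(0)
    class(out) <- c("dominance_table", "data.frame")
    return(out)
  }
  v <- as.integer(rowSums(unclass(d)))
  out <- data.frame(animal_id = rownames(d), dominance_value = v,
                    stringsAsFactors = FALSE)
  if (with_rank) out$social_rank <- categorize(v, k = 2, labels = rank_labels)
  if (with_hierarchy) {
    out$social_hierarchy <- categorize(v, k = 3, labels = hierarchy_labels)
  }
  out <- out[order(out$dominance_value,
                   match(out$animal_id, sort_ids(out$animal_id))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dominance_table", "data.frame")
  out
}

#' Equal-width categorisation of dominance values
#'
#' The value range spans `max - min + 1` integer points (the +1 counts the
#' zero point between the extremes). That width is split into `k`
#' equal-width real-valued bins of size `(max - min + 1) / k`; an animal
#' with value v falls in bin `floor((v - min) / size)`, clipped to the top
#' bin. Bins map in ascending order onto the labels, so the lowest values
#' (most subordinate) take the first label.
#'
#' When all values are equal the range is degenerate: every animal is
#' assigned the middle category (k = 3) or the first (k = 2), with a
#' warning.
#'
#' @param values integer vector of dominance values (non-empty).
#' @param k number of categories, 2 or 3.
#' @param labels category labels, length k, ascending; defaults to
#'   low/high (k = 2) or subordinate/intermediate/dominant (k = 3).
#' @return character vector of category labels, same length as `values`.
#' @export
categorize <- function(values, k, labels = NULL) {
  if (length(values) == 0L) stop_param("values must be non-empty")
  if (!k %in% c(2L, 3L)) stop_param("k must be 2 or 3")
  if (is.null(labels)) {
    labels <- if (k == 2) c("low", "high") else
      c("subordinate", "intermediate", "dominant")
  }
  if (length(labels) != k) stop_param("labels must have length k")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    warning("degenerate dominance-value range: all values equal")
    return(rep(if (k == 3) labels[2L] else labels[1L], length(values)))
  }
  size <- (hi - lo + 1) / k
  bin <- pmin(floor((values - lo) / size), k - 1)
  labels[bin + 1L]
}
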