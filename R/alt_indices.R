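# Comparison dominance indices: David's score, sequential Elo rating, and
# cross-method Pearson correlations.

new_score_table <- function(animal_id, score, method) {
  out <- data.frame(animal_id = as.character(animal_id), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("score_table", "data.frame")
  out
}

#' David's score
#'
#' A zero-sum dominance score built from dyadic win proportions
#' `P_ij = X_ij / (X_ij + X_ji)` (non-interacting dyads contribute 0).
#' Each animal's overall success weighs the opponents' success:
#' `DS_i = w_i + w2_i - l_i - l2_i`, with `w_i = sum_j P_ij`,
#' `w2_i = sum_j P_ij w_j`, and `l`, `l2` the mirror-image loss terms.
#' The `"Dij"` variant replaces P by the sample-size-corrected
#' `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`, shrinking sparsely observed
#' dyads toward an even record.
#'
#' @param m a `socio_matrix` over at least 2 animals.
#' @param variant `"Pij"` (raw proportions, default) or `"Dij"`
#'   (dyadic correction).
#' @return a `score_table` with one row per animal; scores sum to zero.
#' @export
davids_score <- function(m, variant = c("Pij", "Dij")) {
  variant <- match.arg(variant)
  n <- nrow(m)
  if (n < 2L) stop_param("David's score requires at least 2 animals")
  X <- unclass(m)
  storage.mode(X) <- "double"
  nij <- X + t(X)
  P <- matrix(0, n, n, dimnames = dimnames(X))
  has <- nij > 0
  P[has] <- X[has] / nij[has]
  if (variant == "Dij") {
    P[has] <- P[has] - (P[has] - 0.5) / (nij[has] + 1)
  }
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.numeric(P %*% w)
  l2 <- as.numeric(t(P) %*% l)
  new_score_table(rownames(m), w + w2 - l - l2,
                  method = paste0("davids_score_", variant))
}

#' Sequential Elo rating
#'
#' Processes the interactions in input order. Before each interaction the
#' winner's expected success is
#' `E = 1 / (1 + 10^((R_loser - R_winner) / 400))`; the winner gains
#' `k * (1 - E)` and the loser loses the same amount, so the total rating
#' mass `n * start` is conserved. Unlike the matrix-based indices the
#' result depends on interaction order and on `k`, so Elo is best read as
#' a comparison method here.
#'
#' @param interactions an `interaction_list` (order matters).
#' @param k update constant (> 0), default 100.
#' @param start initial rating for every animal, default 1000.
#' @param roster optional ids to include even if they never interact
#'   (they keep the `start` rating).
#' @return a `score_table` with final ratings in canonical id order.
#' @export
elo_rating <- function(interactions, k = 100, start = 1000, roster = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop_param("k must be a single positive number")
  }
  ids <- sort_ids(c(interactions$actor, interactions$reactor, roster))
  r <- stats::setNames(rep(as.numeric(start), length(ids)), ids)
  for (i in seq_len(nrow(interactions))) {
    a <- interactions$actor[i]; b <- interactions$reactor[i]
    e_win <- 1 / (1 + 10^((r[b] - r[a]) / 400))
    delta <- k * (1 - e_win)
    r[a] <- r[a] + delta
    r[b] <- r[b] - delta
  }
  new_score_table(ids, unname(r), method = "elo")
}

#' Kondo-Hurnik dominance values as a score table
#'
#' Convenience wrapper putting the dominance values on the same footing as
#' the other indices for [method_correlations()].
#'
#' @param d a `dyadic_matrix`.
#' @return a `score_table`.
#' @export
kondo_hurnik_scores <- function(d) {
  new_score_table(rownames(d), rowSums(unclass(d)), method = "kondo_hurnik")
}

#' Pearson correlations between dominance methods
#'
#' Pairwise Pearson correlation (with two-sided p-value from
#' [stats::cor.test()]) between the scores of every pair of methods,
#' computed over the animals present in both tables.
#'
#' @param tables a named list of `score_table`s (names default to each
#'   table's method attribute).
#' @return a `correlation_report` data frame with columns `method_a`,
#'   `method_b`, `r`, `p`, `n` for every unordered method pair.
#' @export
method_correlations <- function(tables) {
  if (length(tables) < 2L) stop_param("need at least 2 score tables")
  nms <- names(tables)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(tables, function(t) attr(t, "method") %||% "scores", character(1))
  }
  pairs <- utils::combn(length(tables), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- tables[[ij[1]]]; b <- tables[[ij[2]]]
    shared <- intersect(a$animal_id, b$animal_id)
    if (length(shared) < 3L) {
      stop_validation(sprintf("methods %s and %s share fewer than 3 animals",
                              nms[ij[1]], nms[ij[2]]))
    }
    x <- a$score[match(shared, a$animal_id)]
    y <- b$score[match(shared, b$animal_id)]
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(method_a = nms[ij[1]], method_b = nms[ij[2]],
               r = unname(ct$estimate), p = ct$p.value, n = length(shared),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
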