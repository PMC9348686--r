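# Linearity of the dominance structure: Landau's h and the improved h'.

#' Number of animals dominated by each animal
#'
#' `V[a]` counts the +1 entries in animal a's actor row of the dyadic
#' matrix — the herd mates it holds a net winning record against.
#'
#' @param d a `dyadic_matrix`.
#' @return named integer vector, one entry per animal.
#' @export
dominated_counts <- function(d) {
  V <- as.integer(rowSums(unclass(d) == 1L))
  names(V) <- rownames(d)
  V
}

#' Landau's linearity index
#'
#' Measures how close the group's dominance structure is to a strict
#' linear order:
#' \deqn{h = \frac{12}{n^3 - n} \sum_a \left(V_a - \frac{n-1}{2}\right)^2}
#' where n is the group size and V_a the number of animals a dominates.
#' h = 1 for a perfectly linear hierarchy (the V values are a permutation
#' of 0..n-1) and 0 when every animal dominates the same number of others
#' (e.g. a circular triad). Values above about 0.9 are conventionally read
#' as strongly linear. With unknown or tied relationships the index is
#' depressed; no renormalisation is applied here — see [improved_index()]
#' for the correction that accounts for unknown dyads.
#'
#' @param d a `dyadic_matrix` over at least 2 animals.
#' @return the index h.
#' @export
landau_index <- function(d) {
  n <- nrow(d)
  if (n < 2L) stop_param("Landau's index requires at least 2 animals")
  V <- dominated_counts(d)
  (12 / (n^3 - n)) * sum((V - (n - 1) / 2)^2)
}

#' Count unknown dyads in a sociomatrix
#'
#' A dyad \{i, j\} is unknown when no interaction was observed in either
#' direction (`X[i, j] = X[j, i] = 0`). Tied dyads — equal non-zero win
#' counts — are not unknown: the animals did meet, the record is just
#' balanced. This is why the count is taken from the sociomatrix; the
#' dyadic matrix alone cannot separate the two cases.
#'
#' @param m a `socio_matrix`.
#' @return integer count u in `[0, n(n-1)/2]`.
#' @export
count_unknown <- function(m) {
  X <- unclass(m)
  tot <- X + t(X)
  sum(tot[upper.tri(tot)] == 0L)
}

#' Improved linearity index (unknown-dyad correction)
#'
#' Adds to Landau's h a correction proportional to the number of unknown
#' relationships:
#' \deqn{h' = h + \frac{6}{n^3 - n}\, u}
#' so that sparsely observed groups are not penalised for dyads that were
#' simply never seen to interact. h' = h exactly when every dyad
#' interacted at least once.
#'
#' @param d a `dyadic_matrix`.
#' @param m the `socio_matrix` the dyadic matrix was derived from (same
#'   labels, same order).
#' @return the index h'.
#' @export
improved_index <- function(d, m) {
  if (!identical(dim(d), dim(m)) || !identical(rownames(d), rownames(m))) {
    stop_validation("dyadic matrix and sociomatrix labels do not match")
  }
  n <- nrow(d)
  if (n < 2L) stop_param("the improved index requires at least 2 animals")
  landau_index(d) + (6 / (n^3 - n)) * count_unknown(m)
}

#' Full linearity summary
#'
#' @inheritParams improved_index
#' @return a `linearity_result` list with elements `n`, `V`, `u`, `h`,
#'   `h_prime` and `strongly_linear` (h > 0.9, an interpretive annotation,
#'   not a statistical test).
#' @export
linearity_summary <- function(d, m) {
  h <- landau_index(d)
  u <- count_unknown(m)
  hp <- improved_index(d, m)
  structure(list(n = nrow(d), V = dominated_counts(d), u = u,
                 h = h, h_prime = hp, strongly_linear = h > 0.9),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Linearity over %d animals: h = %.6f, h' = %.6f (u = %d unknown dyads)\n",
              x$n, x$h, x$h_prime, x$u))
  if (x$strongly_linear) cat("h > 0.9: strongly linear hierarchy\n")
  invisible(x)
}
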