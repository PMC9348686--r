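test_that("the sociomatrix counts ordered actor/reactor pairs", {
  il <- data.frame(actor = c("A", "A", "B"), reactor = c("B", "B", "A"),
                   stringsAsFactors = FALSE)
  m <- sociomatrix(il)
  expect_equal(m["A", "B"], 2L, ignore_attr = TRUE)
  expect_equal(m["B", "A"], 1L, ignore_attr = TRUE)
  expect_equal(sum(m), 3L)
  expect_equal(diag(unclass(m)), c(A = 0L, B = 0L))

  z <- sociomatrix(il[0, ], roster = c("A", "B"))
  expect_equal(dim(z), c(2L, 2L))
  expect_true(all(z == 0L))

  expect_equal(dim(sociomatrix(il[0, ])), c(0L, 0L))
})

test_that("sociomatrix total equals the number of interactions tallied", {
  set.seed(5)
  ids <- c("9", "10", "101", "27", "3")
  pick <- replicate(100, sample(ids, 2))
  il <- data.frame(actor = pick[1, ], reactor = pick[2, ], stringsAsFactors = FALSE)
  m <- sociomatrix(il)
  expect_equal(sum(m), 100L)
  # numeric-aware canonical order for ear-tag ids
  expect_equal(rownames(m), c("3", "9", "10", "27", "101"))
  # every cell matches a direct recount of the generated list
  for (i in rownames(m)) for (j in colnames(m)) {
    expect_equal(m[i, j], sum(il$actor == i & il$reactor == j),
                 ignore_attr = TRUE)
  }
})

test_that("the dyadic matrix is the sign of the net dyad outcome", {
  il <- data.frame(actor = c(rep("A", 2), "B", rep("B", 3), rep("C", 3)),
                   reactor = c(rep("B", 2), "A", rep("C", 3), rep("B", 3)),
                   stringsAsFactors = FALSE)
  d <- dyadic_matrix(sociomatrix(il, roster = "D"))
  expect_equal(d["A", "B"], 1L, ignore_attr = TRUE)   # 2 vs 1
  expect_equal(d["B", "A"], -1L, ignore_attr = TRUE)
  expect_equal(d["B", "C"], 0L, ignore_attr = TRUE)   # tied 3-3
  expect_equal(d["A", "D"], 0L, ignore_attr = TRUE)   # unknown 0-0
  expect_true(all(unclass(d) == -t(unclass(d))))
})

test_that("dominance values sum the actor rows and sort ascending", {
  d <- linear_dyadic(3)
  dt <- dominance_values(d)
  expect_equal(dt$dominance_value, c(-2L, 0L, 2L))
  expect_equal(sum(dt$dominance_value), 0L)
  expect_equal(dt$social_hierarchy, c("subordinate", "intermediate", "dominant"))
  expect_equal(dt$social_rank, c("low", "low", "high"))

  empty <- dominance_values(dyadic_matrix(sociomatrix(
    data.frame(actor = character(0), reactor = character(0)))))
  expect_equal(nrow(empty), 0L)
})

test_that("category labels are configurable", {
  d <- linear_dyadic(3)
  dt <- dominance_values(d, hierarchy_labels = c("sub", "mid", "dominate"))
  expect_equal(dt$social_hierarchy, c("sub", "mid", "dominate"))
})

test_that("categorize matches an explicit lattice enumeration of the range", {
  # oracle: enumerate the 46 integer points of -26..19 and split into k
  # equal-width bins by explicit cumulative widths
  lattice_oracle <- function(values, k, labels) {
    lo <- min(values); hi <- max(values)
    width <- hi - lo + 1
    breaks <- lo + width / k * seq_len(k)  # right bin edges on the lattice
    vapply(values, function(v) labels[which(v < breaks)[1]], character(1))
  }
  vals <- -26:19
  expect_equal(categorize(vals, 2), lattice_oracle(vals, 2, c("low", "high")))
  # -4 sits in the first 23-point half (-26..-4); -3 starts the second
  expect_equal(categorize(c(-26, -4, -3, 19), 2),
               c("low", "low", "high", "high"))
  expect_equal(categorize(vals, 3),
               lattice_oracle(vals, 3, c("subordinate", "intermediate", "dominant")))

  expect_equal(categorize(c(-2, 0, 2), 3),
               c("subordinate", "intermediate", "dominant"))
})

test_that("categorize is monotone and handles degenerate ranges", {
  set.seed(13)
  for (rep in 1:20) {
    v <- sample(-30:30, 12, replace = TRUE)
    if (min(v) == max(v)) v[1] <- v[1] + 1
    for (k in 2:3) {
      lab <- categorize(v, k)
      ord <- match(lab, if (k == 2) c("low", "high") else
        c("subordinate", "intermediate", "dominant"))
      expect_true(all(diff(ord[order(v)]) >= 0))
    }
  }
  expect_warning(lab <- categorize(5L, 3), "degenerate")
  expect_equal(lab, "intermediate")
  expect_warning(lab2 <- categorize(c(2L, 2L), 2), "degenerate")
  expect_equal(lab2, c("low", "low"))
})

test_that("the dyadic matrix is invariant to interaction order and id relabeling", {
  set.seed(37)
  ids <- sprintf("%d", 101:106)
  pick <- replicate(80, sample(ids, 2))
  il <- data.frame(actor = pick[1, ], reactor = pick[2, ], stringsAsFactors = FALSE)
  d1 <- dyadic_matrix(sociomatrix(il))
  perm <- il[sample.int(nrow(il)), ]
  d2 <- dyadic_matrix(sociomatrix(perm))
  expect_identical(unclass(d1)[, ], unclass(d2)[, ])

  # relabeling equivariance: renaming ids permutes rows/columns consistently
  map <- setNames(sprintf("Z%s", rev(ids)), ids)
  il3 <- data.frame(actor = unname(map[il$actor]),
                    reactor = unname(map[il$reactor]), stringsAsFactors = FALSE)
  d3 <- dyadic_matrix(sociomatrix(il3))
  relab <- unclass(d3)[map[rownames(d1)], map[colnames(d1)]]
  expect_equal(unname(relab), unname(unclass(d1)[, ]))
})

test_that("dominance invariants hold on random sociomatrices", {
  set.seed(41)
  for (rep in 1:25) {
    m <- random_sociomatrix(n = sample(4:10, 1), n_interactions = sample(0:60, 1),
                            p_dyad = runif(1, 0.3, 1))
    d <- dyadic_matrix(m)
    n <- nrow(d)
    expect_true(all(unclass(d) == -t(unclass(d))))
    v <- rowSums(unclass(d))
    expect_equal(sum(v), 0)
    expect_true(all(abs(v) <= n - 1))
  }
})
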