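two_visit_log <- function(in2, out2 = NULL, animal2 = "B") {
  df <- data.frame(
    equip_id = c("F1", "F1"), animal_id = c("A", animal2),
    IN = c("01/01/2021 08:00:00", in2),
    OUT = c("01/01/2021 08:05:00", if (is.null(out2)) "01/01/2021 08:20:00" else out2),
    stringsAsFactors = FALSE)
  as_event_log(df)
}

test_that("a qualifying pair is detected with actor = successor", {
  il <- detect_replacements(two_visit_log("01/01/2021 08:05:04"), sec = 10)
  expect_equal(nrow(il), 1L)
  expect_equal(il$actor, "B")
  expect_equal(il$reactor, "A")
  expect_equal(il$equip_id, "F1")
  expect_equal(stamp(il$t), "01/01/2021 08:05:04")
})

test_that("pairs with too large a gap or the same animal are not replacements", {
  expect_equal(nrow(detect_replacements(two_visit_log("01/01/2021 08:05:15"), 10)), 0L)
  expect_equal(nrow(detect_replacements(
    two_visit_log("01/01/2021 08:05:05", animal2 = "A"), 10)), 0L)
})

test_that("the threshold boundary follows the configured comparison", {
  log <- two_visit_log("01/01/2021 08:05:10")  # gap exactly 10 s
  expect_equal(nrow(detect_replacements(log, 10, gap_comparison = "lt")), 0L)
  expect_equal(nrow(detect_replacements(log, 10, gap_comparison = "le")), 1L)
})

test_that("overlapping visits only count when negative gaps are allowed", {
  log <- two_visit_log("01/01/2021 08:04:55")  # enters before A leaves
  expect_equal(nrow(detect_replacements(log, 10)), 0L)
  il <- detect_replacements(log, 10, allow_negative_gap = TRUE)
  expect_equal(nrow(il), 1L)
})

test_that("only the immediate predecessor within a bin is compared", {
  df <- data.frame(
    equip_id = "F1", animal_id = c("A", "A", "B"),
    IN = c("01/01/2021 08:00:00", "01/01/2021 08:05:02", "01/01/2021 08:10:03"),
    OUT = c("01/01/2021 08:05:00", "01/01/2021 08:10:00", "01/01/2021 08:15:00"),
    stringsAsFactors = FALSE)
  il <- detect_replacements(as_event_log(df), 10)
  # B vs second A qualifies (gap 3); the A,A pair is self-succession
  expect_equal(nrow(il), 1L)
  expect_equal(il$reactor, "A")
})

test_that("events at different bins never pair up", {
  df <- data.frame(
    equip_id = c("F1", "F2"), animal_id = c("A", "B"),
    IN = c("01/01/2021 08:00:00", "01/01/2021 08:05:02"),
    OUT = c("01/01/2021 08:05:00", "01/01/2021 08:10:00"),
    stringsAsFactors = FALSE)
  expect_equal(nrow(detect_replacements(as_event_log(df), 10)), 0L)
})

test_that("detection equals the brute-force consecutive-pair oracle", {
  set.seed(91)
  for (rep in 1:60) {
    log <- random_raw_log(n_events = sample(10:80, 1))
    sec <- sample(c(0, 5, 30, 120), 1)
    il <- suppressWarnings(detect_replacements(log, sec))
    oracle <- brute_force_replacements(log, sec)
    expect_identical(interaction_keys(il), interaction_keys(oracle))
  }
})

test_that("the interaction set grows monotonically with the threshold", {
  set.seed(17)
  for (rep in 1:25) {
    log <- random_raw_log(n_events = 60)
    s <- sort(sample.int(200, 2))
    k1 <- interaction_keys(suppressWarnings(detect_replacements(log, s[1])))
    k2 <- interaction_keys(suppressWarnings(detect_replacements(log, s[2])))
    expect_true(all(k1 %in% k2))
  }
})

test_that("identical inputs give byte-identical serialized output", {
  set.seed(3)
  log <- random_raw_log(100)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_table(suppressWarnings(detect_replacements(log, 20)), p1)
  write_table(suppressWarnings(detect_replacements(log, 20)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("per-bin counts cover all bins and sum to the interaction total", {
  set.seed(29)
  for (rep in 1:20) {
    log <- random_raw_log(n_events = 60, n_bins = 4)
    sec <- sample(c(10, 60), 1)
    bf <- suppressWarnings(replacements_by_bin(log, sec))
    il <- suppressWarnings(detect_replacements(log, sec))
    expect_setequal(bf$equip_id, bins(log))
    expect_equal(sum(bf$replacements), nrow(il))
    if (nrow(il) > 0) expect_equal(sum(bf$percent), 100, tolerance = 1e-9)
  }
})

test_that("a single-bin log concentrates 100% of replacements", {
  il <- replacements_by_bin(two_visit_log("01/01/2021 08:05:04"), 10)
  expect_equal(il$percent, 100)
  expect_equal(il$replacements, 1L)
})

test_that("actor and reactor frequencies count roles with percent of total", {
  il <- data.frame(actor = c("A", "A", "B"), reactor = c("B", "C", "C"),
                   stringsAsFactors = FALSE)
  fa <- actor_frequency(il)
  expect_equal(fa$animal_id, c("A", "B"))
  expect_equal(fa$count, c(2L, 1L))
  expect_equal(fa$percent, c(200 / 3, 100 / 3), tolerance = 1e-9)
  fr <- reactor_frequency(il)
  expect_equal(fr$animal_id, c("B", "C"))
  expect_equal(fr$count, c(1L, 2L))
  # each interaction contributes one actor and one reactor
  expect_equal(sum(fa$count), nrow(il))
  expect_equal(sum(fr$count), nrow(il))
  expect_equal(sum(fa$percent), 100, tolerance = 1e-9)

  empty <- actor_frequency(il[0, ])
  expect_equal(nrow(empty), 0L)

  withz <- actor_frequency(il, roster = c("A", "B", "C", "D"))
  expect_equal(withz$count[withz$animal_id == "D"], 0L)
})

test_that("simultaneous entries at one bin warn about order dependence", {
  df <- data.frame(
    equip_id = "F1", animal_id = c("A", "B"),
    IN = c("01/01/2021 08:00:00", "01/01/2021 08:00:00"),
    OUT = c("01/01/2021 08:01:00", "01/01/2021 08:02:00"),
    stringsAsFactors = FALSE)
  expect_warning(detect_replacements(as_event_log(df), 10), "input order")
})

test_that("invalid detection parameters are rejected", {
  expect_error(detection_config(-1), class = "sociodom_param_error")
  expect_error(detect_replacements(two_visit_log("01/01/2021 08:05:04"), -1),
               class = "sociodom_param_error")
})
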