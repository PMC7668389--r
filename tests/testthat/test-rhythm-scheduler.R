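# Beat-duration scheduling and the premature-group taxonomy.

test_that("zero-variance schedules are exact divisions of the record", {
  s <- regular_schedule(60, 0, 10)
  expect_equal(nrow(s), 10)
  expect_true(all(s$duration_ms == 1000))
  expect_true(all(s$role == "reference"))
  s2 <- regular_schedule(120, 0, 10)
  expect_equal(nrow(s2), 20)
  expect_true(all(s2$duration_ms == 500))
})

test_that("scheduled durations always cover the requested length", {
  set.seed(61)
  for (i in 1:10) {
    hr <- runif(1, 50, 180)
    len <- runif(1, 5, 60)
    s <- regular_schedule(hr, 40, len)
    expect_gte(sum(s$duration_ms), len * 1000)
    expect_true(all(s$duration_ms > 0))
  }
})

test_that("RR draws average to the configured mean (law of large numbers)", {
  set.seed(71)
  s <- regular_schedule(60, 50, 10000)  # ~1e4 beats
  n <- nrow(s)
  expect_gte(n, 9900)
  expect_lt(abs(mean(s$duration_ms) - 1000), 3 * 50 / sqrt(n))
  # truncation: no draw beyond 3 sd
  expect_true(all(abs(s$duration_ms - 1000) <= 150 + 1e-9))
})

test_that("heart rates outside [50, 180] are rejected, bounds inclusive", {
  expect_error(regular_schedule(49, 0, 10), "\\[50, 180\\]")
  expect_error(regular_schedule(181, 0, 10), "\\[50, 180\\]")
  expect_silent(regular_schedule(50, 0, 10))
  expect_silent(regular_schedule(180, 0, 10))
})

test_that("compensation insertion preserves the paired-beat duration identity", {
  set.seed(81)
  s <- insert_premature_groups(regular_schedule(60, 0, 30), "compensation",
                               count = 1)
  grp <- s[s$role != "reference", ]
  expect_equal(nrow(grp), 2)
  expect_equal(grp$role, c("first", "second"))
  expect_equal(grp$duration_ms, c(830, 1170))
  expect_equal(sum(grp$duration_ms), 2000)  # d1 + d2 = 2 * d0
})

test_that("interpolation and reset ratios shorten the pair and extend the tail", {
  set.seed(82)
  s0 <- regular_schedule(60, 0, 30)
  s <- insert_premature_groups(s0, "interpolation", count = 1)
  grp <- s[s$role != "reference", ]
  expect_equal(grp$duration_ms, c(561, 475))
  # record re-extended to cover the originally scheduled time
  expect_gte(sum(s$duration_ms), sum(s0$duration_ms))
  set.seed(83)
  r <- insert_premature_groups(s0, "reset", count = 1)
  rsum <- sum(r$duration_ms[r$role != "reference"])
  expect_gt(rsum, 1000)   # strictly inside (d0, 2 d0)
  expect_lt(rsum, 2000)
})

test_that("count = 0 is the identity and infeasible counts fail", {
  s <- regular_schedule(60, 0, 10)
  expect_identical(insert_premature_groups(s, "compensation", 0), s)
  expect_error(insert_premature_groups(s, "compensation", 5), "at least 16")
})

test_that("groups are never adjacent and placements are seed-stable", {
  place <- function(seed) {
    set.seed(seed)
    s <- insert_premature_groups(regular_schedule(60, 0, 60), "compensation",
                                 count = 5)
    which(s$role == "first")
  }
  for (seed in c(91, 92, 93)) {
    pos <- place(seed)
    expect_length(pos, 5)
    expect_true(all(diff(sort(pos)) >= 3))       # >= 1 reference between
    expect_true(min(pos) >= 2)                   # reference at both ends
    expect_identical(pos, place(seed))           # identical seed, placement
  }
})

test_that("group classification reproduces the taxonomy exemplars", {
  expect_equal(classify_group(1000, 850, 1150), "compensation")
  expect_equal(classify_group(1000, 650, 1150), "reset")
  expect_equal(classify_group(1000, 400, 600), "interpolation")
  expect_equal(classify_group(1000, 1000, 1000), "regular")
  expect_equal(classify_group(1000, 400, 500), "re-entry (unsupported)")
  expect_error(classify_group(1000, -1, 500), "positive")
})

test_that("classification inverts insertion for the default templates", {
  set.seed(101)
  for (type in c("compensation", "reset")) {
    s <- insert_premature_groups(regular_schedule(60, 0, 30), type, 1)
    grp <- s[s$role != "reference", ]
    expect_equal(classify_group(1000, grp$duration_ms[1], grp$duration_ms[2]),
                 type)
  }
  s <- insert_premature_groups(regular_schedule(60, 0, 30), "interpolation", 1)
  grp <- s[s$role != "reference", ]
  # template ratios sum to 1.036 * d0; needs the wider band
  expect_equal(classify_group(1000, grp$duration_ms[1], grp$duration_ms[2],
                              tol = 0.04), "interpolation")
})

test_that("implied second durations follow the group identities", {
  expect_equal(implied_second_duration("compensation", 1000, 850), 1150)
  expect_equal(implied_second_duration("interpolation", 1000, 400), 600)
  expect_equal(implied_second_duration("compensation", 1000, 1000), 1000)
  expect_error(implied_second_duration("reset", 1000, 600), "under|determine")
  expect_error(implied_second_duration("interpolation", 1000, 1000), "d2 <= 0")
  expect_error(implied_second_duration("compensation", 1000, 1100), "d1 <= d0")
})

test_that("configuration validation reports every broken rule", {
  expect_match(validate_config(list(mean_hr = 49)), "range")
  expect_length(validate_config(list(mean_hr = 180)), 0)
  msgs <- validate_config(list(signal_type = "interpolation", mean_hr = 60,
                               length_s = 10, irregular_times = 5))
  expect_match(msgs, "too large")
  expect_match(validate_config(list(signal_type = "reset", mean_hr = 60,
                                    length_s = 30, irregular_times = 0)),
               "irregular_times is 0")
  expect_length(validate_config(list(signal_type = "compensation",
                                     mean_hr = 60, length_s = 30,
                                     irregular_times = 2)), 0)
})
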