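# Template sampling, pulse concatenation, junction smoothing.

test_that("template sets expose feasible means and the fixed ratios", {
  t_reg <- template_set("regular")
  expect_named(t_reg$roles, "reference")
  expect_null(t_reg$ratios)
  t_cmp <- template_set("compensation")
  expect_equal(t_cmp$ratios, c(0.830, 1.170))
  expect_equal(template_set("reset")$ratios, c(0.607, 0.596))
  expect_equal(template_set("interpolation")$ratios, c(0.561, 0.475))
  for (type in c("regular", "compensation", "reset", "interpolation"))
    for (role in names(template_set(type)$roles)) {
      m <- template_set(type)$roles[[role]]$mean
      expect_identical(
        check_constraints(do.call(pulse_params, as.list(m))), character(0))
    }
})

test_that("zero-sd sampling returns the template means exactly", {
  tpl <- template_set("regular")
  tpl$roles$reference$sd[] <- 0
  p <- sample_params(tpl, "reference")
  expect_equal(as.numeric(unlist(p)), as.numeric(tpl$roles$reference$mean))
})

test_that("every template draw satisfies the constraint set", {
  set.seed(111)
  for (type in c("regular", "reset")) {
    tpl <- template_set(type)
    for (role in names(tpl$roles)) {
      draws <- replicate(2500, sample_params(tpl, role), simplify = FALSE)
      ok <- vapply(draws, function(p) length(check_constraints(p)) == 0L,
                   logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("parameter sampling is reproducible under a fixed seed", {
  tpl <- template_set("compensation")
  set.seed(121); a <- sample_params(tpl, "first")
  set.seed(121); b <- sample_params(tpl, "first")
  expect_identical(a, b)
})

test_that("assembly concatenates pulses on the half-open grid", {
  set.seed(131)
  sched <- regular_schedule(60, 0, 5)
  tpl <- template_set("regular")
  rec <- assemble_signal(sched, tpl, fs = 125, length_s = 5)
  expect_length(rec$samples, 625)
  expect_equal(rec$onsets, c(0, 125, 250, 375, 500))
  expect_equal(rec$beats$role, sched$role)
  expect_equal(rec$beats$group_type, sched$group_type)
  expect_error(assemble_signal(sched, tpl, fs = 20), "not supported")
})

test_that("unsmoothed record samples equal the standalone pulse outputs bit-exactly", {
  set.seed(141)
  sched <- regular_schedule(70, 30, 8)
  tpl <- template_set("regular")
  rec <- assemble_signal(sched, tpl, fs = 125, length_s = 8)
  for (i in seq_along(rec$onsets)) {
    b <- rec$beats[i, ]
    p <- pulse_params(b$a1, b$a2, b$b1, b$b2, b$theta1, b$theta2)
    z <- pulse_waveform(p, b$n_samples / 125, 125)
    idx <- rec$onsets[i] + seq_len(b$n_samples)
    idx <- idx[idx <= length(rec$samples)]
    expect_identical(rec$samples[idx], z[seq_along(idx)])
  }
})

test_that("duration quantization never drifts by more than one sample", {
  set.seed(151)
  sched <- regular_schedule(73, 40, 30)   # awkward rate: fractional samples
  rec <- assemble_signal(sched, template_set("regular"), fs = 125)
  cum_ms <- cumsum(sched$duration_ms)
  expect_true(all(abs(rec$onsets - c(0, cum_ms[-length(cum_ms)]) * 0.125)
                  <= 0.5 + 1e-9))
})

test_that("spline smoothing replaces exactly the middle window per onset", {
  set.seed(161)
  fs <- 100
  sched <- regular_schedule(60, 40, 6)
  rec <- assemble_signal(sched, template_set("regular"), fs = fs)
  sm <- spline_smooth(rec)
  w <- round(0.1 * fs)
  m <- round(0.05 * fs)
  expect_equal(w, 10)  # 0.1 s at 100 Hz
  expect_equal(m, 5)
  windows <- integer(0)
  for (o in rec$onsets[-1]) {
    start <- o - ceiling(w / 2)
    windows <- c(windows, start:(start + w - 1))
  }
  changed <- which(sm$samples != rec$samples) - 1L  # 0-based
  expect_true(all(changed %in% windows))
  # the windows exist and have exactly round(0.1*fs) samples each
  expect_equal(length(windows), (length(rec$onsets) - 1) * w)
})

test_that("smoothing an already-smooth waveform is a near no-op", {
  set.seed(171)
  sched <- regular_schedule(60, 0, 5)
  rec <- assemble_signal(sched, template_set("regular"), fs = 100)
  rec$samples <- sin(2 * pi * 1 * (seq_along(rec$samples) - 1) / 100)
  sm <- spline_smooth(rec)
  expect_lt(max(abs(sm$samples - rec$samples)), 1e-3)
})

test_that("smoothed junctions are no rougher than their surroundings", {
  set.seed(181)
  sched <- regular_schedule(60, 40, 10)
  rec <- assemble_signal(sched, template_set("regular"), fs = 125)
  sm <- spline_smooth(rec)
  w <- round(0.1 * 125); m <- round(0.05 * 125)
  for (o in sm$onsets[-1]) {
    start <- o - ceiling(w / 2)
    mid <- sm$samples[(start:(start + w - 1)) + 1]
    fit <- sm$samples[c((start - m):(start - 1),
                        (start + w):(start + w + m - 1)) + 1]
    expect_lte(max(abs(diff(mid))), 3 * max(abs(diff(fit))) + 1e-12)
  }
})

test_that("colliding smoothing windows are skipped with a warning", {
  set.seed(191)
  # interpolation second beats at 180 bpm are shorter than the 0.2-s window
  sched <- insert_premature_groups(regular_schedule(180, 0, 5),
                                   "interpolation", 1)
  rec <- assemble_signal(sched, template_set("interpolation"), fs = 100)
  expect_warning(spline_smooth(rec), "skipping junction")
})
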