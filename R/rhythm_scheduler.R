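# Beat-duration scheduling.
#
# Reference beat durations are i.i.d. Gaussian around 60000/HR ms; premature
# atrial contraction groups replace pairs of consecutive reference beats. The
# taxonomy, with d0 the reference duration and d1, d2 the two group beats:
#   compensation:  d1 + d2 = 2 d0   (the pause fully compensates)
#   reset:         d0 < d1 + d2 < 2 d0
#   interpolation: d1 + d2 = d0     (the group fits inside one reference beat)
#   re-entry:      d1 + d2 < d0     (no template exists; not generated)

#' Regular beat schedule with Gaussian RR variability
#'
#' Draws beat durations i.i.d. from `Normal(60000 / mean_hr, rr_sd)` ms until
#' their cumulative sum covers the requested signal length. Draws are
#' truncated to `mean +/- 3 sd` and floored at 250 ms so that no
#' non-physiological or negative duration can occur. Uses the current R RNG
#' stream; call `set.seed()` (or use [run_synthesis()]) for reproducibility.
#'
#' @param mean_hr Mean heart rate in beats per minute, in `[50, 180]`.
#' @param rr_sd Standard deviation of the RR interval in ms (>= 0).
#' @param length_s Requested signal length in seconds (> 0).
#' @return A `beat_schedule`: data frame with columns `duration_ms`, `role`
#'   (`"reference"`, `"first"`, `"second"`) and `group_type` (`"none"`,
#'   `"compensation"`, `"reset"`, `"interpolation"`).
#' @examples
#' regular_schedule(60, 0, 10) # 10 beats of exactly 1000 ms
#' @export
regular_schedule <- function(mean_hr, rr_sd = 0, length_s = 10) {
  if (!is.numeric(mean_hr) || length(mean_hr) != 1 || !is.finite(mean_hr) ||
      mean_hr < 50 || mean_hr > 180)
    stop("mean_hr must lie in [50, 180] bpm", call. = FALSE)
  if (!is.numeric(rr_sd) || rr_sd < 0)
    stop("rr_sd must be >= 0 ms", call. = FALSE)
  if (!is.numeric(length_s) || length_s <= 0)
    stop("length_s must be > 0", call. = FALSE)
  mean_rr <- 60000 / mean_hr
  target <- length_s * 1000
  dur <- numeric(0)
  total <- 0
  while (total < target) {
    d <- stats::rnorm(1, mean_rr, rr_sd)
    d <- min(max(d, mean_rr - 3 * rr_sd), mean_rr + 3 * rr_sd)
    d <- max(d, 250)
    dur <- c(dur, d)
    total <- total + d
  }
  new_beat_schedule(dur, rep("reference", length(dur)),
                    rep("none", length(dur)))
}

new_beat_schedule <- function(duration_ms, role, group_type) {
  sched <- data.frame(duration_ms = duration_ms, role = role,
                      group_type = group_type, stringsAsFactors = FALSE)
  class(sched) <- c("beat_schedule", "data.frame")
  sched
}

#' Default first/second-beat duration ratios per group type
#'
#' The fixed template ratios of first and second premature-beat duration to
#' the local reference duration: compensation (0.830, 1.170), reset
#' (0.607, 0.596), interpolation (0.561, 0.475).
#'
#' @param group_type `"compensation"`, `"reset"` or `"interpolation"`.
#' @return Numeric vector `c(r1, r2)`.
#' @export
duration_ratios <- function(group_type) {
  switch(match.arg(group_type, c("compensation", "reset", "interpolation")),
         compensation = c(0.830, 1.170),
         reset = c(0.607, 0.596),
         interpolation = c(0.561, 0.475))
}

#' Insert premature-atrial-contraction groups into a schedule
#'
#' Replaces `count` pairs of consecutive reference beats by premature groups.
#' Replacement positions are drawn uniformly at random among eligible
#' reference positions, keeping at least one reference beat between groups
#' and at both ends of the record. Each group gets durations `d1 = r1 * d0`
#' and `d2 = r2 * d0` where `d0` is the replaced reference beat's duration.
#' When the group is shorter than the two beats it replaces (reset,
#' interpolation), reference beats of the mean reference duration are
#' appended so the schedule still covers the originally scheduled time.
#'
#' @param schedule A `beat_schedule` of reference beats.
#' @param group_type `"compensation"`, `"reset"` or `"interpolation"`.
#' @param count Number of groups to insert (>= 0).
#' @param ratios Duration ratios `c(r1, r2)`; defaults to
#'   [duration_ratios()] for the group type.
#' @return The modified `beat_schedule`.
#' @examples
#' set.seed(1)
#' s <- regular_schedule(60, 0, 30)
#' s2 <- insert_premature_groups(s, "compensation", count = 1)
#' sum(s2$duration_ms[s2$role != "reference"]) # 2000: d1 + d2 = 2 * d0
#' @export
insert_premature_groups <- function(schedule, group_type, count,
                                    ratios = duration_ratios(group_type)) {
  stopifnot(inherits(schedule, "beat_schedule"))
  group_type <- match.arg(group_type,
                          c("compensation", "reset", "interpolation"))
  if (!is.numeric(count) || count < 0 || count != round(count))
    stop("count must be a non-negative integer", call. = FALSE)
  if (length(ratios) != 2 || any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be two positive numbers", call. = FALSE)
  if (count == 0) return(schedule)

  n <- nrow(schedule)
  if (3 * count + 1 > n)
    stop(sprintf(
      "cannot place %d premature group(s) in %d beats; need at least %d",
      count, n, 3 * count + 1), call. = FALSE)

  # first-slot positions i: group occupies beats (i, i+1); a reference beat
  # must remain before, after, and between any two groups (|i - j| >= 3)
  chosen <- NULL
  for (attempt in seq_len(100)) {
    elig <- seq(2L, n - 2L)
    sel <- integer(0)
    ok <- TRUE
    for (g in seq_len(count)) {
      if (!length(elig)) { ok <- FALSE; break }
      i <- if (length(elig) == 1L) elig else sample(elig, 1L)
      sel <- c(sel, i)
      elig <- setdiff(elig, (i - 2L):(i + 2L))
    }
    if (ok) { chosen <- sel; break }
  }
  if (is.null(chosen))
    stop("could not place the requested number of premature groups",
         call. = FALSE)

  total_before <- sum(schedule$duration_ms)
  for (i in chosen) {
    d0 <- schedule$duration_ms[i]
    schedule$duration_ms[i]      <- ratios[1] * d0
    schedule$duration_ms[i + 1L] <- ratios[2] * d0
    schedule$role[i]       <- "first"
    schedule$role[i + 1L]  <- "second"
    schedule$group_type[c(i, i + 1L)] <- group_type
  }

  deficit <- total_before - sum(schedule$duration_ms)
  if (deficit > 0) {
    ref_mean <- mean(schedule$duration_ms[schedule$role == "reference"])
    extra <- ceiling(deficit / ref_mean)
    schedule <- rbind(
      schedule,
      new_beat_schedule(rep(ref_mean, extra), rep("reference", extra),
                        rep("none", extra)))
    class(schedule) <- c("beat_schedule", "data.frame")
  }
  schedule
}

#' Classify a premature group from its durations
#'
#' Applies the duration taxonomy with a relative tolerance band: regular if
#' all three durations agree within `tol * d0`; compensation if
#' `|d1 + d2 - 2 d0| <= tol * d0`; interpolation if
#' `|d1 + d2 - d0| <= tol * d0`; re-entry (unsupported for synthesis) if the
#' sum falls below the interpolation band; reset if the sum lies strictly
#' between `d0` and `2 d0` outside both bands. Sums beyond the compensation
#' band are `"unclassified"`.
#'
#' @param d0 Reference beat duration in ms (> 0).
#' @param d1,d2 First and second group beat durations in ms (> 0).
#' @param tol Relative tolerance (fraction of `d0`), default 0.02.
#' @return One of `"regular"`, `"compensation"`, `"reset"`,
#'   `"interpolation"`, `"re-entry (unsupported)"`, `"unclassified"`.
#' @examples
#' classify_group(1000, 850, 1150)  # compensation
#' classify_group(1000, 650, 1150)  # reset
#' classify_group(1000, 400, 600)   # interpolation
#' @export
classify_group <- function(d0, d1, d2, tol = 0.02) {
  if (any(c(d0, d1, d2) <= 0))
    stop("durations must be positive", call. = FALSE)
  s <- d1 + d2
  band <- tol * d0
  if (abs(d1 - d0) <= band && abs(d2 - d0) <= band) return("regular")
  if (abs(s - 2 * d0) <= band) return("compensation")
  if (abs(s - d0) <= band) return("interpolation")
  if (s < d0) return("re-entry (unsupported)")
  if (s > d0 && s < 2 * d0) return("reset")
  "unclassified"
}

#' Second-beat duration implied by a group definition
#'
#' For group types whose definition pins down the sum `d1 + d2`, returns the
#' second-beat duration: `2 d0 - d1` for compensation, `d0 - d1` for
#' interpolation. Reset only brackets the sum, so it is under-determined.
#'
#' @param group_type `"compensation"` or `"interpolation"` (`"reset"` is an
#'   error).
#' @param d0 Reference beat duration in ms.
#' @param d1 First group beat duration in ms, `0 < d1 <= d0`.
#' @return Second-beat duration `d2` in ms.
#' @examples
#' implied_second_duration("compensation", 1000, 850)  # 1150
#' implied_second_duration("interpolation", 1000, 400) # 600
#' @export
implied_second_duration <- function(group_type, d0, d1) {
  group_type <- match.arg(group_type,
                          c("compensation", "reset", "interpolation"))
  if (group_type == "reset")
    stop("reset groups do not determine d2 from d0 and d1", call. = FALSE)
  if (!is.numeric(d0) || !is.numeric(d1) || d0 <= 0 || d1 <= 0 || d1 > d0)
    stop("require 0 < d1 <= d0", call. = FALSE)
  if (group_type == "interpolation" && d1 >= d0)
    stop("interpolation with d1 >= d0 would give d2 <= 0", call. = FALSE)
  switch(group_type,
         compensation = 2 * d0 - d1,
         interpolation = d0 - d1)
}

#' Validate a synthesis configuration
#'
#' Total function returning human-readable messages for every violated
#' configuration rule; an empty character vector means valid. Checks the
#' heart-rate range `[50, 180]` bpm, the feasibility of the requested number
#' of premature groups (each group consumes two beat slots plus one
#' separating reference beat, so `3 * irregular_times + 1` must not exceed
#' the expected beat count), a zero `irregular_times` when an irregular
#' signal type is selected, and — when present in the config — the sampling
#' rate (>= 30 Hz) and signal length (> 0).
#'
#' @param config A list or [synthesis_config()] with (a subset of) fields
#'   `signal_type`, `mean_hr`, `rr_sd`, `irregular_times`, `length_s`, `fs`.
#' @return Character vector of validation messages (empty if valid).
#' @examples
#' validate_config(list(mean_hr = 49))
#' validate_config(list(signal_type = "interpolation", mean_hr = 60,
#'                      length_s = 10, irregular_times = 5))
#' @export
validate_config <- function(config) {
  msgs <- character(0)
  hr <- config$mean_hr
  if (!is.null(hr) && (!is.numeric(hr) || hr < 50 || hr > 180))
    msgs <- c(msgs, sprintf(
      "mean_hr = %s is outside the supported range [50, 180] bpm",
      format(hr)))
  if (!is.null(config$rr_sd) && config$rr_sd < 0)
    msgs <- c(msgs, "rr_sd must be >= 0 ms")
  if (!is.null(config$length_s) && config$length_s <= 0)
    msgs <- c(msgs, "length_s must be > 0")
  if (!is.null(config$fs) && config$fs < 30)
    msgs <- c(msgs, "fs must be >= 30 Hz")
  st <- config$signal_type
  it <- config$irregular_times
  irregular <- !is.null(st) && st != "regular"
  if (irregular && !is.null(it) && !is.null(hr) && !is.null(config$length_s)
      && is.numeric(hr) && hr >= 50 && hr <= 180) {
    expected <- round(config$length_s * hr / 60)
    if (3 * it + 1 > expected)
      msgs <- c(msgs, sprintf(
        paste("irregular_times = %d is too large for the signal length:",
              "needs at least %d beats but only %d are expected"),
        it, 3 * it + 1, expected))
    if (it == 0)
      msgs <- c(msgs, sprintf(
        "signal_type = '%s' selected but irregular_times is 0", st))
  }
  msgs
}
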