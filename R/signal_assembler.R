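# Template distributions, beat-by-beat assembly, junction smoothing.
#
# Each beat role (reference / first / second) carries a (mean, sd) pair per
# pulse parameter, derived from real fingertip PPG recordings; per-beat
# parameters are independent Gaussian draws re-sampled until feasible.
# Concatenating independently drawn pulses leaves small steps at beat
# junctions, removed by a natural cubic spline fitted around each interior
# onset.

# template table: per signal type, per role, mean and sd of the six pulse
# parameters, plus the fixed duration ratios of the premature beats
.template_table <- local({
  row <- function(a1, a2, b1, b2, th1, th2, a1s, a2s, b1s, b2s, th1s, th2s) {
    list(mean = c(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                  theta1 = th1, theta2 = th2),
         sd = c(a1 = a1s, a2 = a2s, b1 = b1s, b2 = b2s,
                theta1 = th1s, theta2 = th2s))
  }
  regular <- row(0.997, 0.225, 0.641, 0.937, -1.471, 1.019,
                 0.028, 0.030, 0.034, 0.161, 0.147, 0.102)
  list(
    regular = list(roles = list(reference = regular), ratios = NULL),
    compensation = list(
      roles = list(
        reference = regular,
        first  = row(0.829, 0.420, 0.732, 1.219, -1.008, 0.450,
                     0.010, 0.018, 0.033, 0.021, 0.147, 0.167),
        second = row(0.785, 0.405, 0.678, 1.115, -1.792, -0.607,
                     0.034, 0.049, 0.036, 0.065, 0.080, 0.107)),
      ratios = c(0.830, 1.170)),
    reset = list(
      roles = list(
        reference = regular,
        first  = row(0.774, 0.774, 0.647, 1.007, -1.378, 0.173,
                     0.012, 0.012, 0.041, 0.046, 0.180, 0.180),
        second = row(0.995, 0.197, 0.778, 1.045, -1.809, 0.892,
                     0.002, 0.024, 0.055, 0.341, 0.203, 0.325)),
      ratios = c(0.607, 0.596)),
    interpolation = list(
      roles = list(
        reference = regular,
        first  = row(0.668, 0.490, 0.893, 1.428, -0.627, 0.442,
                     0.151, 0.006, 0.034, 0.062, 0.292, 0.635),
        second = row(0.595, 0.537, 0.889, 1.321, -1.049, -0.289,
                     0.084, 0.092, 0.170, 0.289, 0.207, 0.480)),
      ratios = c(0.561, 0.475)))
})

#' Template parameter distributions for a signal type
#'
#' Returns the per-role (reference / first / second beat) mean and standard
#' deviation of each pulse parameter, together with the fixed duration ratios
#' of the premature beats. Defaults are the template values fitted to real
#' recordings; reference beats of irregular signals use the regular template.
#'
#' @param signal_type One of `"regular"`, `"compensation"`, `"reset"`,
#'   `"interpolation"`.
#' @return A `template_set`: list with elements `type`, `roles` (per role a
#'   list with numeric vectors `mean` and `sd` named `a1, a2, b1, b2, theta1,
#'   theta2`) and `ratios` (`c(r1, r2)`, `NULL` for regular).
#' @examples
#' template_set("compensation")$ratios # 0.830 1.170
#' @export
template_set <- function(signal_type = c("regular", "compensation",
                                         "reset", "interpolation")) {
  signal_type <- match.arg(signal_type)
  tpl <- .template_table[[signal_type]]
  out <- structure(list(type = signal_type, roles = tpl$roles,
                        ratios = tpl$ratios),
                   class = "template_set")
  validate_template_set(out)
  out
}

validate_template_set <- function(template) {
  for (role in names(template$roles)) {
    r <- template$roles[[role]]
    if (any(r$sd < 0))
      stop("template sd must be >= 0 (role ", role, ")", call. = FALSE)
    m <- do.call(pulse_params, c(as.list(r$mean), check = FALSE))
    bad <- check_constraints(m)
    if (length(bad))
      stop("template means for role '", role, "' are infeasible: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(template)
}

#' Draw feasible pulse parameters for one beat
#'
#' Each parameter is an independent Gaussian draw from the role's (mean, sd);
#' the six-vector is re-drawn until it satisfies [check_constraints()]
#' (at most 100 attempts, after which the template means are returned with a
#' warning). With all sd = 0 the means are returned exactly.
#'
#' @param template A [template_set()].
#' @param role `"reference"`, `"first"` or `"second"`.
#' @param max_attempts Resampling cap (default 100).
#' @return A feasible [pulse_params()] object.
#' @export
sample_params <- function(template, role = "reference", max_attempts = 100) {
  stopifnot(inherits(template, "template_set"))
  r <- template$roles[[role]]
  if (is.null(r))
    stop("template has no role '", role, "'", call. = FALSE)
  for (k in seq_len(max_attempts)) {
    draw <- stats::rnorm(6, r$mean, r$sd)
    p <- pulse_params(draw[1], draw[2], draw[3], draw[4], draw[5], draw[6],
                      check = FALSE)
    if (!length(check_constraints(p))) return(p)
  }
  warning("no feasible draw in ", max_attempts,
          " attempts; returning template means", call. = FALSE)
  do.call(pulse_params, as.list(r$mean))
}

#' Assemble a PPG record from a beat schedule
#'
#' Samples per-beat parameters by role, generates each pulse on the half-open
#' grid `[0, d)` and concatenates them. Beat durations are quantized to
#' integer sample counts against the cumulative schedule, so rounding error
#' never accumulates beyond one sample. The record is truncated to
#' `round(length_s * fs)` samples.
#'
#' @param schedule A `beat_schedule` (see [regular_schedule()]).
#' @param template A [template_set()].
#' @param fs Sampling frequency in Hz (>= 30).
#' @param length_s Requested record length in seconds; defaults to the full
#'   scheduled duration.
#' @return A `ppg_record`: list with `samples` (numeric vector), `fs`,
#'   `onsets` (0-based sample indices of beat starts, first onset 0),
#'   `beats` (data frame: scheduled duration, role, group type, sample count
#'   and the six drawn parameters per beat) and `meta` (provenance).
#' @export
assemble_signal <- function(schedule, template, fs,
                            length_s = sum(schedule$duration_ms) / 1000) {
  stopifnot(inherits(schedule, "beat_schedule"),
            inherits(template, "template_set"))
  if (!is.numeric(fs) || fs < 30)
    stop("sampling rates below 30 Hz are not supported", call. = FALSE)
  nb <- nrow(schedule)
  boundaries <- round(cumsum(schedule$duration_ms) * fs / 1000)
  n_k <- diff(c(0, boundaries))
  if (any(n_k < 2))
    stop("a scheduled beat is shorter than 2 samples at fs = ", fs,
         call. = FALSE)
  onsets <- c(0, boundaries[-nb])

  role_of <- ifelse(schedule$role %in% c("first", "second"),
                    schedule$role, "reference")
  draws <- matrix(NA_real_, nb, 6,
                  dimnames = list(NULL, c("a1", "a2", "b1", "b2",
                                          "theta1", "theta2")))
  pieces <- vector("list", nb)
  for (i in seq_len(nb)) {
    p <- sample_params(template, role_of[i])
    draws[i, ] <- as_param_vector(p)
    pieces[[i]] <- pulse_waveform(p, n_k[i] / fs, fs)
  }
  samples <- unlist(pieces, use.names = FALSE)

  n_total <- round(length_s * fs)
  if (n_total < 1) stop("record would be empty", call. = FALSE)
  n_total <- min(n_total, length(samples))
  samples <- samples[seq_len(n_total)]
  keep <- onsets < n_total

  beats <- cbind(as.data.frame(schedule)[keep, , drop = FALSE],
                 n_samples = n_k[keep], as.data.frame(draws[keep, ,
                                                            drop = FALSE]))
  rownames(beats) <- NULL
  new_ppg_record(samples, fs, as.integer(onsets[keep]), beats,
                 meta = list(signal_type = template$type,
                             length_s = length_s, smoothed = FALSE))
}

new_ppg_record <- function(samples, fs, onsets, beats, meta = list()) {
  if (length(onsets) && (onsets[1] != 0 || is.unsorted(onsets, strictly = TRUE)))
    stop("onsets must start at 0 and be strictly increasing", call. = FALSE)
  structure(list(samples = samples, fs = fs, onsets = onsets,
                 beats = beats, meta = meta),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %g Hz (%.3g s), %d beats\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              length(x$onsets)))
  if (!is.null(x$beats) && nrow(x$beats)) {
    tab <- table(x$beats$group_type)
    irr <- tab[names(tab) != "none"]
    if (length(irr))
      cat("  premature beats:",
          paste(names(irr), irr, sep = "=", collapse = ", "), "\n")
  }
  if (isTRUE(x$meta$smoothed)) cat("  junction-smoothed\n")
  if (!is.null(x$meta$noise)) cat("  noise added\n")
  invisible(x)
}

#' @export
plot.ppg_record <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "PPG (a.u.)", ...)
  irr <- x$onsets[x$beats$role == "first"]
  if (length(irr))
    graphics::abline(v = irr / x$fs, col = "red", lty = 2)
  invisible(x)
}

#' Smooth beat junctions with a natural cubic spline
#'
#' Independent per-beat parameter draws leave a step where one pulse ends and
#' the next begins. Around every interior beat onset, a window of 0.2 s is
#' considered: the `round(0.05 * fs)` samples before and after the middle
#' window anchor a natural cubic spline, and the middle `round(0.1 * fs)`
#' samples (centered on the onset) are replaced by the spline's values. All
#' other samples are untouched; the first onset has no left neighbour and is
#' never smoothed. Onsets whose windows would run past the record ends or
#' into a neighbouring onset's window are skipped with a warning.
#'
#' @param record A `ppg_record` from [assemble_signal()].
#' @return The record with smoothed junctions (`meta$smoothed = TRUE`).
#' @export
spline_smooth <- function(record) {
  stopifnot(inherits(record, "ppg_record"))
  fs <- record$fs
  m <- round(0.05 * fs)   # fit samples on each side
  w <- round(0.1 * fs)    # replaced samples, centered on the onset
  s <- record$samples
  n <- length(s)
  last_end <- -Inf
  for (o in record$onsets[-1]) {
    mid_start <- o - ceiling(w / 2)          # 0-based
    full_start <- mid_start - m
    full_end <- mid_start + w + m - 1
    if (full_start < 0 || full_end > n - 1 || full_start <= last_end) {
      warning(sprintf("skipping junction at sample %d: window out of range",
                      o), call. = FALSE)
      next
    }
    xfit <- c(seq(full_start, mid_start - 1),
              seq(mid_start + w, full_end))
    yfit <- s[xfit + 1]
    mid <- seq(mid_start, mid_start + w - 1)
    s[mid + 1] <- stats::spline(xfit, yfit, xout = mid,
                                method = "natural")$y
    last_end <- full_end
  }
  record$samples <- s
  record$meta$smoothed <- TRUE
  record
}
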