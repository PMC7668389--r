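# Two-Gaussian polar pulse model.
#
# A single PPG pulse is the z-component of a trajectory whose (x, y) projection
# traverses the unit circle once per beat:
#   x(t) = cos(w (t - t0) - pi),  y(t) = sin(w (t - t0) - pi),
#   z(t) = a1 exp(-(theta - theta1)^2 / (2 b1^2)) +
#          a2 exp(-(theta - theta2)^2 / (2 b2^2)),
# with theta = atan2(y, x) the instantaneous phase. The two Gaussians are the
# systolic and diastolic sub-waves. The phase is computed analytically as the
# wrap of w (t - t0) - pi into [-pi, pi); the atan2 form is numerically
# identical and is used as an oracle in the tests.

#' Pulse-model parameters
#'
#' Bundles the six parameters of the two-Gaussian PPG pulse model: amplitudes
#' `a1` (systolic) and `a2` (diastolic), Gaussian widths `b1`, `b2` (radians)
#' and Gaussian centers `theta1`, `theta2` (radians, phase of each peak).
#'
#' The feasible set is `0 <= a2 <= a1 <= 1`, `0 <= b1 < b2 <= 3` and
#' `-pi <= theta1 < theta2 <= pi` (the systolic peak precedes the diastolic
#' one). The amplitude inequality is non-strict so that templates with
#' `a1 == a2` remain feasible.
#'
#' @param a1,a2 Peak amplitudes (dimensionless), `0 <= a2 <= a1 <= 1`.
#' @param b1,b2 Gaussian standard deviations (radians), `0 <= b1 < b2 <= 3`.
#' @param theta1,theta2 Peak phases (radians), `-pi <= theta1 < theta2 <= pi`.
#' @param check If `TRUE` (default) the constraint set is enforced and a
#'   violation is an error; `check = FALSE` builds the object unchecked (used
#'   internally, e.g. to describe candidate points for [check_constraints()]).
#' @return A `pulse_params` object (named list of the six parameters).
#' @seealso [check_constraints()], [pulse_waveform()]
#' @examples
#' p <- pulse_params(a1 = 0.997, a2 = 0.225, b1 = 0.641, b2 = 0.937,
#'                   theta1 = -1.471, theta2 = 1.019)
#' @export
pulse_params <- function(a1, a2, b1, b2, theta1, theta2, check = TRUE) {
  vals <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
            theta1 = theta1, theta2 = theta2)
  if (!is.numeric(vals) || length(vals) != 6L || any(!is.finite(vals)))
    stop("all six pulse parameters must be finite numeric scalars",
         call. = FALSE)
  p <- structure(as.list(vals), class = "pulse_params")
  if (check) {
    bad <- check_constraints(p)
    if (length(bad))
      stop("infeasible pulse parameters: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  p
}

#' @export
print.pulse_params <- function(x, ...) {
  cat("<pulse_params>\n")
  cat(sprintf("  a1=%.4g a2=%.4g  b1=%.4g b2=%.4g  theta1=%.4g theta2=%.4g\n",
              x$a1, x$a2, x$b1, x$b2, x$theta1, x$theta2))
  invisible(x)
}

as_param_vector <- function(p) {
  c(p$a1, p$a2, p$b1, p$b2, p$theta1, p$theta2)
}

params_from_vector <- function(v, check = FALSE) {
  pulse_params(v[1], v[2], v[3], v[4], v[5], v[6], check = check)
}

#' Angular velocity of a pulse
#'
#' One beat corresponds to one revolution of the unit circle, so the angular
#' velocity is `2 * pi / T` for a pulse of duration `T` seconds.
#'
#' @param duration_T Pulse duration in seconds (> 0).
#' @return Angular velocity in rad/s.
#' @examples
#' angular_velocity(1)   # 2*pi
#' angular_velocity(0.5) # 4*pi
#' @export
angular_velocity <- function(duration_T) {
  if (!is.numeric(duration_T) || any(!is.finite(duration_T)) ||
      any(duration_T <= 0))
    stop("pulse duration must be a positive finite number", call. = FALSE)
  2 * pi / duration_T
}

# wrap an angle into [-pi, pi)
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Instantaneous phase within a pulse
#'
#' Maps a time inside one pulse to its phase angle on the unit circle:
#' `phi = w (t - t0) - pi` wrapped to `[-pi, pi)`, where `w` is the angular
#' velocity of the pulse. The onset `t = t0` maps to `-pi` and the phase
#' increases strictly and linearly to (but excluding) `pi` over the pulse.
#'
#' @param t Time(s) in seconds; must lie in `[t0, t0 + duration_T)`.
#' @param t0 Pulse start time in seconds.
#' @param duration_T Pulse duration in seconds (> 0).
#' @return Phase angle(s) in radians, in `[-pi, pi)`.
#' @export
pulse_phase <- function(t, t0, duration_T) {
  w <- angular_velocity(duration_T)
  if (any(t < t0) || any(t >= t0 + duration_T))
    stop("t must lie in [t0, t0 + duration_T)", call. = FALSE)
  wrap_phase(w * (t - t0) - pi)
}

# z(theta) for a parameter set; theta in radians
pulse_z <- function(params, theta) {
  params$a1 * exp(-(theta - params$theta1)^2 / (2 * params$b1^2)) +
    params$a2 * exp(-(theta - params$theta2)^2 / (2 * params$b2^2))
}

#' Sample one PPG pulse
#'
#' Evaluates the two-Gaussian pulse model on a uniform sampling grid. The
#' pulse occupies the half-open interval `[t0, t0 + T)` and is sampled at
#' `n = round(T * fs)` points `t = t0 + k / fs`, `k = 0, ..., n - 1`, so that
#' consecutive pulses concatenate without duplicated boundary samples. With
#' `T = 1` s and `fs = 125` Hz a pulse is exactly 125 samples.
#'
#' Output stays in model units: every sample lies in `[0, a1 + a2]`; no
#' rescaling is applied.
#'
#' @param params A [pulse_params()] object.
#' @param duration_T Pulse duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Pulse start time in seconds (>= 0); affects only the implied time
#'   axis, not the returned amplitudes.
#' @return Numeric vector of `round(duration_T * fs)` amplitude samples.
#' @examples
#' p <- pulse_params(0.997, 0.225, 0.641, 0.937, -1.471, 1.019)
#' z <- pulse_waveform(p, duration_T = 1, fs = 125)
#' length(z) # 125
#' @export
pulse_waveform <- function(params, duration_T, fs, t0 = 0) {
  stopifnot(inherits(params, "pulse_params"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite number", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("t0 must be a finite number >= 0", call. = FALSE)
  n <- round(duration_T * fs)
  if (n < 2)
    stop("pulse must contain at least 2 samples (round(duration_T * fs) >= 2)",
         call. = FALSE)
  # t = t0 + k/fs, k = 0..n-1; k < round(T*fs) keeps w*(t-t0) - pi below pi,
  # so no sample ever wraps back past the onset phase
  theta <- wrap_phase(2 * pi * (seq_len(n) - 1) / (fs * duration_T) - pi)
  pulse_z(params, theta)
}
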