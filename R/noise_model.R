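# Additive noise: SNR-calibrated white Gaussian noise and deterministic
# multi-frequency sinusoids n(t) = sum_i A_i sin(2 pi f_i t).
#
# SNR convention: the reference power is the AC power of the clean signal
# (mean squared deviation from its mean). The synthetic PPG rides on a
# positive offset; including that DC term would inflate the SNR arbitrarily.
# Scaling uses the analytic target power, so the realized sample SNR
# fluctuates around the request and converges to it with record length.

#' Noise specification
#'
#' @param snr_db Target white-Gaussian signal-to-noise ratio in dB (optional).
#' @param amplitude,frequency Equal-length numeric vectors describing
#'   sinusoidal components `A_i sin(2 pi f_i t)` (optional); amplitudes must
#'   be non-negative and frequencies positive (and below the Nyquist rate
#'   when applied).
#' @return A `noise_spec` object; both parts may be present at once, and an
#'   empty spec is allowed (identity when applied).
#' @examples
#' noise_spec(snr_db = 20)
#' noise_spec(amplitude = c(0.1, 0.05), frequency = c(5, 12))
#' @export
noise_spec <- function(snr_db = NULL, amplitude = NULL, frequency = NULL) {
  if (!is.null(snr_db) &&
      (!is.numeric(snr_db) || length(snr_db) != 1 || !is.finite(snr_db)))
    stop("snr_db must be a single finite number", call. = FALSE)
  if (length(amplitude) != length(frequency))
    stop("'amplitude' and 'frequency' must have the same number of values",
         call. = FALSE)
  if (length(amplitude)) {
    if (any(!is.finite(amplitude)) || any(amplitude < 0))
      stop("amplitudes must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(frequency)) || any(frequency <= 0))
      stop("frequencies must be finite and > 0", call. = FALSE)
  }
  structure(list(snr_db = snr_db,
                 amplitude = as.numeric(amplitude),
                 frequency = as.numeric(frequency)),
            class = "noise_spec")
}

#' White Gaussian noise at a requested SNR
#'
#' Draws i.i.d. zero-mean Gaussian noise scaled so that
#' `10 * log10(P_ac(signal) / P_noise) = snr_db`, where `P_ac` is the mean
#' squared deviation of the clean signal from its mean. Uses the current R
#' RNG stream.
#'
#' @param signal Clean amplitude sequence (must not be constant).
#' @param snr_db Target SNR in dB (finite; 0 dB makes the target noise power
#'   equal the signal's AC power).
#' @return Noise vector of the same length as `signal`.
#' @export
white_gaussian_noise <- function(signal, snr_db) {
  if (!is.numeric(snr_db) || length(snr_db) != 1 || !is.finite(snr_db))
    stop("snr_db must be a single finite number", call. = FALSE)
  p_ac <- mean((signal - mean(signal))^2)
  if (p_ac == 0)
    stop("signal has zero AC power; SNR is undefined", call. = FALSE)
  p_noise <- p_ac / 10^(snr_db / 10)
  stats::rnorm(length(signal), mean = 0, sd = sqrt(p_noise))
}

#' Multi-frequency sinusoidal noise
#'
#' Returns `sum_i A_i * sin(2 * pi * f_i * t)` evaluated at `t = k / fs`,
#' `k = 0, ..., n - 1`. Deterministic (no RNG use).
#'
#' @param amplitude,frequency Equal-length vectors of component amplitudes
#'   and frequencies (Hz); every frequency must be below the Nyquist rate
#'   `fs / 2`.
#' @param fs Sampling frequency in Hz.
#' @param n Number of samples.
#' @return Noise vector of length `n`.
#' @examples
#' multifrequency_noise(1, 1, fs = 100, n = 100)[26] # sin(pi/2) = 1
#' @export
multifrequency_noise <- function(amplitude, frequency, fs, n) {
  if (length(amplitude) != length(frequency))
    stop("'amplitude' and 'frequency' must have the same number of values",
         call. = FALSE)
  if (!length(amplitude))
    stop("component list must be non-empty", call. = FALSE)
  if (any(frequency >= fs / 2))
    stop("noise frequencies must be below the Nyquist rate fs/2 = ",
         fs / 2, " Hz", call. = FALSE)
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (i in seq_along(amplitude))
    out <- out + amplitude[i] * sin(2 * pi * frequency[i] * t)
  out
}

#' Add noise to a PPG record
#'
#' Adds white Gaussian noise (if `spec$snr_db` is set) and multi-frequency
#' sinusoidal noise (if components are present) to the record's samples.
#' Onsets and beat annotations are unchanged; provenance records the spec.
#' An empty spec is the identity.
#'
#' @param record A `ppg_record`.
#' @param spec A [noise_spec()].
#' @return The record with noisy samples and updated provenance.
#' @export
add_noise <- function(record, spec) {
  stopifnot(inherits(record, "ppg_record"), inherits(spec, "noise_spec"))
  s <- record$samples
  if (!is.null(spec$snr_db))
    s <- s + white_gaussian_noise(record$samples, spec$snr_db)
  if (length(spec$amplitude))
    s <- s + multifrequency_noise(spec$amplitude, spec$frequency,
                                  record$fs, length(s))
  record$samples <- s
  record$meta$noise <- spec[c("snr_db", "amplitude", "frequency")]
  record
}
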