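# Independent oracles and shared fixtures for the test suite.

# template means used repeatedly in tests
regular_means <- function() {
  pulse_params(0.997, 0.225, 0.641, 0.937, -1.471, 1.019)
}

comp_first_means <- function() {
  pulse_params(0.829, 0.420, 0.732, 1.219, -1.008, 0.450)
}

# Scalar, loop-based evaluation of the fit objective, deliberately written
# without vectorized R idioms or cor(): phase via the trig-then-atan2 route,
# Pearson r from explicit sums.
oracle_objective <- function(params, samples, fs, duration_T) {
  n <- length(samples)
  w <- 2 * pi / duration_T
  z <- numeric(n)
  for (k in seq_len(n)) {
    t <- (k - 1) / fs
    th <- atan2(sin(w * t - pi), cos(w * t - pi))
    z[k] <- params$a1 * exp(-(th - params$theta1)^2 / (2 * params$b1^2)) +
      params$a2 * exp(-(th - params$theta2)^2 / (2 * params$b2^2))
  }
  sse <- 0
  for (k in seq_len(n)) sse <- sse + (z[k] - samples[k])^2
  mz <- sum(z) / n
  ms <- sum(samples) / n
  num <- 0; dz <- 0; ds <- 0
  for (k in seq_len(n)) {
    num <- num + (z[k] - mz) * (samples[k] - ms)
    dz <- dz + (z[k] - mz)^2
    ds <- ds + (samples[k] - ms)^2
  }
  sse + (1 - num / sqrt(dz * ds))
}

# Dense-grid argmax of z(theta) over [-pi, pi); returns the peak phase.
oracle_peak_phase <- function(params, n_grid = 1e5) {
  th <- seq(-pi, pi, length.out = n_grid)
  z <- params$a1 * exp(-(th - params$theta1)^2 / (2 * params$b1^2)) +
    params$a2 * exp(-(th - params$theta2)^2 / (2 * params$b2^2))
  th[which.max(z)]
}

# random feasible parameter set (rejection sampling over the box)
random_feasible_params <- function() {
  repeat {
    a <- sort(runif(2, 0, 1))
    b <- sort(runif(2, 0.1, 3))
    th <- sort(runif(2, -pi, pi))
    if (b[2] - b[1] > 1e-3 && th[2] - th[1] > 1e-3) {
      return(pulse_params(a[2], a[1], b[1], b[2], th[1], th[2]))
    }
  }
}
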