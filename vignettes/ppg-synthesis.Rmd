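---
title: "Synthesizing regular and arrhythmic PPG waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing regular and arrhythmic PPG waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgsim)
```

## The pulse model

`ppgsim` treats one heartbeat of a fingertip PPG as the z-component of a
trajectory whose (x, y) projection moves once around the unit circle. For a
beat of duration $T$ seconds starting at $t_0$, the angular velocity is
$\omega = 2\pi/T$ and the phase is

$$\theta(t) = \omega (t - t_0) - \pi \quad \text{wrapped to } [-\pi, \pi),$$

so the beat onset (the valley of the waveform) sits at phase $-\pi$. The
waveform itself is a sum of two Gaussians in phase — the systolic and
diastolic sub-waves:

$$z(t) = a_1 e^{-(\theta(t)-\theta_1)^2/2b_1^2}
       + a_2 e^{-(\theta(t)-\theta_2)^2/2b_2^2}.$$

The feasible parameter set is $0 \le a_2 \le a_1 \le 1$,
$0 \le b_1 < b_2 \le 3$ and $-\pi \le \theta_1 < \theta_2 \le \pi$: the
systolic wave is at least as tall and narrower than the diastolic one and
precedes it in phase. The amplitude inequality is deliberately non-strict
because the reset first-beat template has $a_1 = a_2 = 0.774$; the
orientation $\theta_1 < \theta_2$ is the one every template row satisfies.
Output stays in model units (roughly $[0, 1]$); no rescaling is applied.

Two numerical choices matter here:

* **Half-open sampling grid.** A pulse occupies $[t_0, t_0 + T)$ and is
  sampled at $n = \mathrm{round}(T f_s)$ points $t_0 + k/f_s$. Pulses then
  concatenate without duplicated boundary samples, and a 1-s pulse at
  125 Hz is exactly 125 samples.
* **Analytic phase.** The phase is computed directly as the wrap of
  $\omega(t - t_0) - \pi$ rather than through $\mathrm{atan2}(\sin, \cos)$.
  The two agree to machine precision everywhere except the onset itself,
  where atan2 sits on its $\pm\pi$ branch point; we define the onset phase
  as $-\pi$. The test suite checks the equivalence against the atan2 form
  at 1000 random times to $10^{-12}$.

## Fitting the model to an observed beat

`fit_pulse()` minimizes
$\sum_n (z_p(n) - s(n))^2 + (1 - \mathrm{corr}(z_p, s))$ over the feasible
set, where $s$ is the observed beat, $z_p$ the model pulse on the same
grid, and corr Pearson's linear correlation. The sum of squares is left
unnormalized (not divided by the beat length); the correlation term rewards
shape agreement independently of vertical offset. The objective is zero
exactly when the model reproduces the beat.

The constraints are nine linear inequalities, so the problem is solved with
`stats::constrOptim` — an adaptive logarithmic-barrier method in the
interior-point family — using analytic gradients (the correlation gradient
is $\partial r/\partial z_k = v_k/(S_z S_s) - r u_k/S_z^2$ with $u, v$ the
centered vectors). Numerical choices:

* Strict inequalities are implemented with a separation epsilon of
  $10^{-6}$, since the barrier needs closed half-spaces with non-empty
  interior.
* The barrier parameter is $\mu = 10^{-6}$; convergence tolerances default
  to $10^{-9}$ on the relative objective and the outer step, with at most
  500 inner iterations.
* Because the barrier biases solutions slightly away from active
  constraints, the result is **polished** by an unconstrained BFGS run and
  the polished point is kept only if it still satisfies every constraint.
* Auto-initialization takes $a_1$ from the tallest sample, the peak phases
  from the two largest well-separated local maxima (falling back to typical
  systolic/diastolic phases $-1.471$ and $1.019$ when the diastolic wave is
  only a shoulder), $a_2 = a_1/2$, $b_1 = 0.6$, $b_2 = 1.0$. Since the
  objective is non-convex, auto mode is a small multi-start: the
  data-driven point plus three fixed starts covering narrow-peaked and
  broad/overlapping morphologies, keeping the best fit. A user-supplied
  infeasible start is an error; non-convergence within the iteration budget
  is reported via `converged = FALSE`, not an exception.

These optimizer settings are this package's own declared defaults.

## Rhythms and premature groups

Reference beat durations are i.i.d. Gaussian,
$\mathcal{N}(60000/\mathrm{HR}\ \mathrm{ms}, \mathrm{rr\_sd}\ \mathrm{ms})$,
drawn until they cover the requested length. Draws are truncated to the
mean $\pm 3$ SD and floored at 250 ms so that no non-physiological or
negative duration can occur — a guard the underlying model needs but does
not itself prescribe. Heart rates are restricted to $[50, 180]$ bpm,
bounds inclusive.

A premature atrial contraction perturbs two consecutive beats — the
*premature group* — with first-beat duration $d_1$ and second-beat duration
$d_2$ against the local reference duration $d_0$:

| class | definition | template ratios $(r_1, r_2)$ |
|---|---|---|
| compensation | $d_1 + d_2 = 2d_0$ | (0.830, 1.170) |
| reset | $d_0 < d_1 + d_2 < 2d_0$ | (0.607, 0.596) |
| interpolation | $d_1 + d_2 = d_0$ | (0.561, 0.475) |

Groups are inserted by replacing two consecutive reference beats, at
positions drawn uniformly among eligible slots with at least one reference
beat between groups and at both record ends (the source material says only
"randomly replaced"; this placement rule is ours). Each group uses the fixed
template ratios rather than random draws, so the class identity of a group
is never changed by sampling noise. When a group is shorter than the two
beats it replaces (reset, interpolation), reference beats at the mean
reference duration are appended — deterministically, to avoid extra RNG
draws — until the originally scheduled time is covered again.

Two quirks of the template ratios are kept as printed rather than
reconciled: the interpolation ratios sum to $1.036\,d_0$, not exactly
$d_0$ (so classification of generated interpolation groups needs a
tolerance of at least 0.04, while the default `classify_group` tolerance is
0.02, enough to separate the textbook exemplars); and the reset second-beat
ratio 0.596 is not prolonged relative to $d_0$ even though the class
description says it is. Re-entry groups ($d_1 + d_2 < d_0$) are recognized
by `classify_group` but never generated: no morphology template exists for
them. Sums beyond $2d_0$ fall outside the taxonomy and are reported as
`"unclassified"`.

The feasibility rule for a requested number of groups is
$3\,\mathrm{irregular\_times} + 1 \le$ expected beat count (two slots per
group plus a separating reference beat); a zero count with an irregular
type selected is a warning, not an error, since the result is simply a
regular record.

## Per-beat variability and assembly

Each beat's six parameters are independent Gaussian draws from its role's
template distribution (reference beats of irregular records use the regular
template), re-drawn until feasible with a cap of 100 attempts, after which
the means are returned with a warning. Template means and SDs ship with the
package (`template_set()`); they were fitted to real fingertip recordings.

Beat durations are quantized to whole samples against the *cumulative*
schedule, so rounding error is corrected by $\pm 1$ sample on subsequent
beats and never accumulates. Onsets are stored as 0-based sample indices
(`onset / fs` is the onset time); beat duration is realized
onset-to-onset, i.e. valley-to-valley.

Because consecutive pulses are drawn independently, the junction between
them is discontinuous. Every interior onset is therefore smoothed: the
`round(0.05 fs)` samples before and after a middle window anchor a cubic
spline, and the middle `round(0.1 fs)` samples centered on the onset are
replaced by spline values — 0.2 s of context in total. We use *natural*
spline end conditions (`stats::spline(method = "natural")`); the underlying
description pins down only a cubic interpolant with value/derivative
continuity, not the end conditions. Whether only irregular junctions or all
junctions should be smoothed is equally unspecified; we smooth every
interior onset, since regular junctions also jump when `rr_sd` or the
parameter SDs are non-zero. Windows that would run off the record or into a
neighbouring onset's window (possible for interpolation second beats at
high heart rates, which can be shorter than 0.2 s) are skipped with a
warning. Smoothing happens **before** noise injection so that noise is not
smoothed away.

## Noise

White Gaussian noise is scaled to a requested SNR defined against the
clean signal's **AC power** (mean squared deviation from its mean):
synthetic PPG rides on a positive offset, and including that DC term would
let the offset inflate the SNR arbitrarily. The scale uses the analytic
target power, so the realized sample SNR fluctuates around the request and
converges with record length (checked at $10^5$ samples to ±0.3 dB).
Sinusoidal noise $\sum_i A_i \sin(2\pi f_i t)$ is deterministic and
requires every $f_i$ below the Nyquist rate; amplitude and frequency lists
must be equal length. Both kinds add element-wise to the clean record and
never touch onsets or labels.

## Reproducibility and serialization

A single seeded RNG stream is threaded through scheduling, group placement,
parameter sampling and noise, in that fixed order, so identical
(configuration, seed) pairs give bit-identical records and seeds are stable
across feature toggles that are off. Records serialize to a `time_s,ppg`
CSV plus a JSON sidecar with onsets, per-beat labels and the full
configuration; the sidecar alone regenerates the record. CSV numbers are
written with 15 significant digits so a round-trip reproduces samples to
better than $10^{-12}$.

## What the generator does and does not emulate

The generator reproduces: two-wave pulse morphology and its beat-to-beat
variability, RR-interval variability, the duration structure of
compensation/reset/interpolation premature groups, broadband sensor noise
and narrowband interference. It does **not** model respiratory baseline
wander, motion-artifact morphology, amplitude modulation trends across
beats beyond independent parameter draws, sensor-site or transfer-function
differences, premature *ventricular* contractions, re-entry beats, or any
hemodynamic covariates. Tests passing on synthetic records therefore
demonstrate algorithmic correctness under this model's assumptions, not
performance on real recordings.

## Problem sizes in the test suite

The shipped tests run at deliberately modest sizes chosen to exercise the
asymptotics without waste: 1000-point phase-oracle comparisons, 2500-draw
feasibility checks per template role, a ~$10^4$-beat schedule for the
law-of-large-numbers check on RR means, $10^5$ samples for the empirical
SNR check, and 30–60 s records for end-to-end determinism and round-trip
checks. Fits in the tests use 125–250 Hz, 1-s beats.

## Known limitations

* Recovery guarantees for `fit_pulse` hold for well-separated truths
  ($\theta_2 - \theta_1 \ge 0.5$ rad, $a_1 - a_2 \ge 0.1$); heavily
  overlapping Gaussians are weakly identifiable and the fit may return an
  equivalent-looking local optimum.
* The interpolation templates do not satisfy their own class identity
  exactly (ratios sum to $1.036\,d_0$); classification of generated groups
  needs the documented wider tolerance.
* `classify_group` labels groups from durations alone; it does not inspect
  morphology.
* Only CSV + JSON output is supported; spreadsheet/MAT containers were
  dropped in favour of portable formats.
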