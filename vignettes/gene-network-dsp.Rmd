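---
title: "Gene network motifs as discrete-time systems: models, estimators, and control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene network motifs as discrete-time systems: models, estimators, and control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genenetdsp)
```

## The model

All simulators in this package share one modelling premise: protein
concentrations are sampled on a uniform grid (default one sample per
minute; the first sample, index n = 1, sits at elapsed time 0) and evolve
by linear difference equations. One step combines a *retention fraction*
— the share of the protein surviving degradation and dilution — with
linear *production* terms contributed by upstream regulators. For the
two-gene cascade x → y:

$$y(n) = p_y\,y(n-1) + p_{xy}\,x(n-1) + b_0,$$

with $p_y \in [0,1]$, $p_{xy} \ge 0$, and optional basal production
$b_0 \ge 0$. Values of $p_y$ outside $[0,1]$ are rejected: above 1 the
protein would grow without input, below 0 it would turn negative.
Saturation of the production machinery is modelled as a hard clamp
$y(n) \mapsto \min(y(n), y_{max})$; a soft (Hill-type) saturation would
also be defensible, but the clamp is the simplest form consistent with
"a maximum attainable level" and keeps the unsaturated recursion exactly
linear, which the analytics rely on.

Key consequences, each of which is exercised by the test suite:

* **Steady state.** For $p_y < 1$ and constant input $\bar x$,
  $y_\infty = (p_{xy}\bar x + b_0)/(1-p_y)$, independent of the initial
  value.
* **Response time.** Started from 0, $y(n) = y_\infty(1 - p_y^{\,n-1})$,
  so the *discrete* response time is $dt \cdot k$ with $k$ the smallest
  integer satisfying $1 - p_y^k \ge 1 - 1/e$ (≈ 63.2% of the steady
  state). We adopt this first-sample-crossing convention because it
  reproduces both printed reference values (10 minutes at $p_y = 0.9$, 2
  minutes at $p_y = 0.4$) simultaneously; the continuous time constant
  $-1/\ln p_y$ (in steps) is reported alongside, since the two
  conventions differ and figures elsewhere may use either.
* **Co-modulation.** Production moves only the level; degradation moves
  level and speed. `design_comodulation()` therefore solves the
  response-time target first. Among the one-parameter family of feasible
  retentions it deterministically returns the largest one meeting the
  discrete threshold, $p_y = e^{-dt/\tau_{target}}$ (the slowest compliant
  degradation), then sets $p_{xy} = y_{target}(1-p_y)/\bar x$.

## Motif variants

**Autoregulation** adds a self-term: $+\,\mathrm{par}\cdot y(n-1)$
(positive) or $-\,\mathrm{nar}\cdot y(n-1)$ (negative). This is
algebraically an effective retention $p_y \pm s$, so positive
autoregulation raises both the steady state and the response time and can
destabilise the motif (effective retention above 1); runs that exceed a
$10^{12}$ uM overflow guard fail fast with an unstable-motif error rather
than returning infinities. Negative autoregulation lowers both level and
response time; its trajectories are clamped at 0 from below.

**Feedforward loops** are built from the same retention + linear
production structure. In the coherent type-1 loop, z receives additive
input from both the direct edge (x → z) and the indirect branch
(x → y → z); the indirect component rises more slowly, so the normalized
trajectory of their sum crosses half-maximum strictly later than direct
activation alone — the delay element. The incoherent type-1 loop carries
the y branch with a negative sign (y represses z), which produces the
pulse: a fast direct rise followed by repression as y accumulates, with
the trajectory clamped at 0. The interlocked variant chains a second
type-1 loop onto the first (four species x, y, z, w), which yields
sequential half-maximum crossing times down the cascade. The choice of
additive inputs (rather than, say, multiplicative AND-gating) is a design
decision: it is the minimal form that provably satisfies all three
behavioral contracts (delay, pulse, ordered expression) and stays within
the linear framework of the other motifs.

**Extrinsic noise** is modelled as per-sample Gaussian draws (default
mean 0, sd 1) added to a targeted species *after* its update and *before*
it feeds downstream equations, so upstream ("extrinsic") noise propagates
into downstream ("intrinsic") fluctuations. Negative post-noise levels
are clamped to 0 and clamp events are counted in an attribute. Every
noise realization is determined by a mandatory integer seed, and drawing
is isolated from the caller's RNG state. Because the cascade is a
first-order low-pass filter, the downstream fluctuation level is smaller
than the injected noise by the white-noise gain
$\sqrt{p_{xy}^2/(1-p_y^2)}$ — the quantity `noise_gain()` returns and the
10^5-sample property test verifies to within 10%.

## Estimation

The general prediction model uses $M$ past inputs and $N$ past outputs
("ARX" structure); `build_regression()` stacks the data vectors
$d(n) = (x(n-1),\dots,x(n-M),\,y(n-1),\dots,y(n-N))^T$ row-wise, inputs
first. Three estimators share this plumbing:

* `fit_least_squares()` minimises $\sum e(n)^2$ by SVD with a
  machine-epsilon-scaled rank cutoff; rank-deficient designs (constant
  input with converged output is the canonical case) return the
  minimum-norm solution with a warning rather than an error.
* `fit_wiener()` solves $R w = p$ with $R = E[dd^T]$, $p = E[dy]$
  replaced by single-realization sample averages — the ergodic estimate;
  true expectations would need an ensemble of repeated experiments. On
  the same sample window this is algebraically the least-squares
  solution, which the suite checks to $10^{-6}$.
* `fit_lms()` is the stochastic-gradient adaptive filter
  $w(n+1) = w(n) + \mu e(n) d(n)$, initialised at $w_0 = 0$ with default
  $\mu = 10^{-3}$ and a divergence guard at $|w|_\infty > 10^8$ that
  names the offending step size. The stable range of $\mu$ scales
  inversely with the power of the data vector, so fixtures whose outputs
  reach tens of uM use smaller steps. On time-varying data (a mid-run
  production-gain switch) the adaptive weights track the new regime and
  outperform any fixed least-squares fit on the final quarter of the
  record; error-comparison metrics exclude the first 10% of samples,
  where the filter is still learning.

## Frequency domain

The z-transform of the cascade gives
$H(z) = p_{xy} z^{-1} / (1 - p_y z^{-1})$: a single-pole IIR low-pass
filter whose DC gain equals the steady-state gain (a cross-module
identity the tests assert). `freq_response()` evaluates magnitude and
phase on a 512-point grid over $[0, \pi]$ by default and refuses
unit-circle poles, naming the frequency.

`dft()` uses the forward transform with the negative-exponent kernel,
$X(\omega_m) = \sum_{n=0}^{N-1} x(n) e^{-j\omega_m n}$,
$\omega_m = 2\pi m/N$, delegating to the fast transform in base R; the
$O(N^2)$ direct summation serves as an independent oracle in the tests,
alongside Parseval's identity and the mirror symmetry of real-signal
spectra. Inside the transform the time index runs 0..N−1; the package's
series start at n = 1, and the one-sample offset changes only phase,
never magnitude. `dominant_frequency()` searches $m = 1..\lfloor N/2
\rfloor$ (DC excluded by default, mirror half disregarded) and breaks
ties — to within a $10^{-9}$ relative rounding band — toward the lower
frequency, a deterministic convention.

The oscillation fixture (`fig9`) is a *synthetic* p53-like rhythm: a
sinusoid with five cycles per 30 hours (≈ 0.167 cycles/hour), hourly
sampling, 180 samples, amplitude 5 uM around a 10 uM baseline, with
seeded sd-0.2 jitter. Real p53 traces are noisier and less strictly
periodic; what the passing test shows is that the DFT pipeline localises
a known periodicity to within one frequency bin, not that it would
denoise experimental data.

## Feedback and control

The negative-feedback network adds a controller gene c between input and
output:

$$c(n) = p_c\,c(n-1) + p_{xc}\,x(n-1) - p_{yc}\,y(n-1), \qquad
  y(n) = p_y\,y(n-1) + p_{cy}\,c(n-1) + d(n),$$

the negative $y(n-1)$ term being the feedback (y downregulates c) and
$d(n)$ an additive step disturbance on the output. The controller's own
retention $p_c$ is kept as an explicit slot defaulting to 0 (the
controller then re-computes the weighted error each step); either choice
leaves the closed loop second-order with two poles. Applying the final
value theorem to the disturbance-to-error transfer with a step of size
$d_0$ gives

$$e_D(\infty) = \frac{-p_{yc}\,d_0\,(1-p_c)}{(1-p_y)(1-p_c) + p_{cy}p_{yc}},$$

cross-validated against long simulations to $10^{-6}$ over random stable
parameter sweeps. Its magnitude falls as $p_{cy}$ grows or $p_y$ shrinks:
production and degradation rates, seemingly irrelevant to robustness,
set how well the network rejects disturbances. Stability is read off the
denominator roots (`tf_poles()`), strictly inside the unit circle;
unit-magnitude poles are labelled *marginal* rather than stable, since
they do not decay — both labels are surfaced. The equivalent state-space
form (`to_state_space()`) has state $(y, c)^T$ and a state matrix whose
eigenvalues equal the poles, checked to $10^{-9}$.

The in-silico control loop closes around a light-driven plant
$x(n) = p_x x(n-1) + p_{cx} c(n-1)$ with a positional discrete PID law:
rectangular-sum integral and backward-difference derivative, the simplest
discretisation consistent with the standard controller. Light intensity
cannot be negative, so the control signal is clamped at 0, and the
integral term is frozen while the clamp is active (conditional
anti-windup) — without it, integral windup during saturation corrupts
step tracking. `tune_pid()` places the PI closed-loop poles at $\{q,
q^2\}$ for a requested dominant pole $q \in (0,1)$: the secondary pole is
tied to the dominant one so the placement is a one-parameter design, and
the resulting $K_I = (1-q)(1-q^2)/p_{cx}$ is always positive, so a tuned
loop tracks steps with zero steady-state error. `identify_plant_online()`
is the LMS filter applied with one input and one output lag, so its
weight history reads directly as per-step plant estimates
$(\hat p_{cx}(n), \hat p_x(n))$. Dual-channel control (separate light
colors modulating production and degradation in parallel) is a documented
extension point, not implemented.

## Numerical choices

* Steady-state convergence: relative one-step change below $10^{-9}$,
  capped at $10^6$ steps. For retentions near 1 the *remaining gap* at
  stopping scales like $\mathrm{value}\cdot 10^{-9} p_y/(1-p_y)$, which
  is why cross-validation against the closed form iterates a fixed
  sufficient horizon instead of reusing the detector.
* Response-time threshold comparisons carry a $10^{-12}$ absolute slack
  so that the boundary design $p_y = e^{-1/k}$ (whose $k$-step remainder
  equals $1/e$ exactly in exact arithmetic) round-trips in floating
  point.
* Clamping at 0 applies to concentrations (noise- or repression-induced
  negativity) and to light intensity; clamp events are counted and
  exposed as an attribute, never silent.
* Divergence guards: $10^{12}$ uM for motif and closed-loop trajectories
  (fail fast with pole magnitudes in the message), $10^8$ for LMS weight
  norms (naming $\mu$).
* Rank decisions in the linear solvers use a singular-value cutoff of
  `max(dim) * .Machine$double.eps * max(singular values)`.

## Problem sizes

The test suite and the reproduction script are sized for interactive use:
design-point simulations run a few hundred steps; estimator fixtures use
3 000–5 000 samples; the noise-attenuation and final-value checks use
$10^5$ and 3 000 samples respectively; property sweeps draw 10–100 random
parameter sets under fixed seeds. The whole suite completes in well under
a minute.

## Limitations

* The models are concentration-level and linear (up to clamps): no
  molecule-count stochastic chemistry (Gillespie-type simulation), no
  mRNA intermediates — transcription and translation are collapsed into
  one gain — and no Hill-type nonlinear regulation.
* The noise model is additive Gaussian; multiplicative or bursty noise
  is out of scope.
* Estimators assume uniform sampling and contiguous lags; there is no
  model-order selection (orders are chosen by hand) and no RLS/Kalman
  variant.
* Control synthesis is limited to LMS identification plus PI pole
  placement; robust, adaptive and model-predictive control are out of
  scope, as is any hardware/imaging layer.
* Passing tests on the synthetic fixtures demonstrates correctness of
  the algorithms under the stated generative conditions, not performance
  on experimental recordings, which are noisier, non-stationary, and
  irregularly sampled.
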