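---
title: "Single-molecule recycling: models, estimator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule recycling: models, estimator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrkit)
```

This vignette documents the science implemented in `smrkit`: the physical
model behind the simulator, the detection/control/estimation chain, the
parameters that matter, and the design decisions taken where the problem
was genuinely open.  It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## 1. Physical model

**Axial diffusion.** A molecule confined to the axis of a micron-bore
capillary performs 1D Brownian motion with drift, governed by the
drift–diffusion (Fokker–Planck) equation
$\partial_t p = D\,\partial_x^2 p - v\,\partial_x p$.  For a point release
the solution is Gaussian with mean $vt$ and standard deviation
$\sigma(t)=\sqrt{2Dt}$ (`propagator_pdf()`); the simulator integrates the
corresponding SDE by Euler–Maruyama (`step_brownian()`), which is exact for
this process at any step size.  The 2 µm radial bore is collapsed to a pure
1D model: radial excursions modulate brightness, which is absorbed into the
peak count rate $F$.

**Photon emission.** The focus is modelled as a transverse Gaussian
intensity $I(x)\propto e^{-2x^2/\omega_0^2}$ with waist
$\omega_0 = 1\,\mu$m.  This specific profile is the one choice consistent
with the matched filter below: a transit at constant speed $v$ then
produces a *temporal* Gaussian of width $\sigma_t=\omega_0/(2v)$.  Photon
counts per 10 µs bin are Poisson with mean
$[F e^{-2x^2/\omega_0^2} + B]\,\Delta t_w$; per-bin Poisson generation
(rather than exact thinning) is adequate because the rate changes by $<2\%$
per bin at the stated speeds.  Photon arrival ticks (10 ns clock) are
placed uniformly within their bin — they are only consumed by the
correlator at lags far above 10 ns.

**Frames.** The molecule position $x_m$ lives in the capillary frame.  The
stage *scan coordinate* $s(t)$ is defined as the capillary-frame position
currently imaged at the focus, so the molecule's offset from the focus is
$x_m - s(t)$ and a burst occurs when the scan crosses the molecule.  The
controller's centre $X(i)$ (piezo units, 0.458 nm/unit) estimates $x_m$ in
this same frame.

## 2. Burst detection

Counts are correlated with Gaussian matched-filter weights
$w = A\,e^{-t^2/2\sigma_t^2}$, $A = 128$, sampled every 10 µs over
$\pm 3\sigma_t$ (capturing $>99.7\%$ of the template mass; the kernel is
forced to an odd tap count so its mode lies on a sample).  Each maximal
run of WSS values above threshold yields exactly one burst at the run's
maximum, earliest bin on ties; runs touching the data edges are emitted and
flagged.  The default threshold is $8\times$ the expected background level
$B\,\Delta t_w \sum w$ — operator-adjustable in practice, so it is a
configuration parameter.

The WSS is computed in the *centred* convention, which makes the peak an
unbiased estimate of the transit midpoint for the symmetric template; the
streaming variant used inside the control loop carries run state across
chunks and produces bitwise-identical events (tested).  Its unavoidable
real-time latency is half a kernel plus one bin; the offline replay
(`run_controller(kernel = )`) can reproduce that information set exactly.

Timing precision of the peak scales as $\sigma_t/\sqrt{N_{\rm phot}}$; at
the default $F = 10^5$ s$^{-1}$ this is $\approx 60\,\mu$s, i.e. a 120 nm
position noise at $v = 2$ mm/s — an order of magnitude below the
per-cycle diffusion spread, so detection noise inflates $\hat D$ by well
under 1%.

## 3. Recycling feedback

Each cycle lasts exactly the reversal delay $\Delta t$ (the stage reverses
on schedule *even when no burst is detected*).  The stage launches from
$X(i) - \mathrm{dir}\,X_t$, translates at $v$ through the centre to
$X(i) + \mathrm{dir}\,X_t$, dwells, repositions to the next launch point
once the centre update is known, and reverses.  The update is a
proportional correction on the transit-time innovation,
$X(i+1) = ((t_w - t_p) - m)\,C + X(i)$, with $m$ the running mean transit
time over the last 20 detected cycles (initialised to the nominal
$X_t/v$).  Three design choices deserve comment:

- **Sign of the correction.** A late transit means the molecule lies
  further along the *current scan direction*, so the controller applies
  $C$ with the scan parity.  A fixed-sign correction anti-corrects on
  alternate passes and cannot track (verified in simulation —
  the negative-control test).
- **Default gain.** $C = v$ expressed in piezo units per millisecond.
  With this gain the update places the new centre exactly at the scan
  position where the burst peaked — a deadbeat controller; the tracking
  error is then one cycle's diffusion step plus detection noise.
- **Late detections and the decision point.** The reposition move is short
  (at most $X_t/v \approx 2.3$ ms at the default gain, and the applied
  correction is capped accordingly), so the decision is scheduled *late*
  in the cycle, at $\Delta t - \text{delay} - X_t/v$.  A molecule that
  drifted past the turnaround and fires while the stage dwells still
  recentres the loop: its effective transit time is clamped to the
  translation window, which places the centre at the parked scan position
  — exactly where the focus saw it.  Without this, tracking is lost within
  a few seconds whenever the molecule out-runs one scan.

Missed cycles freeze the centre; stage commands beyond the travel limits
(±100 µm, a 200 µm stage) are clamped and flagged.  Tracking can still be
lost when the molecule out-diffuses the ±4.58 µm scan range for several
consecutive cycles — the real experiment then loads a new molecule, and the
acceptance pipeline does the analogous thing (molecules with fewer than 100
detected cycles are not pooled).

## 4. Speed calibration by autocorrelation

The multi-tau correlator (16 lags per octave, factor-two coarsening,
symmetric normalization) computes
$g(\tau)=\langle n(t)n(t+\tau)\rangle/\langle n\rangle^2$.  The 1D
flow-plus-diffusion model
$$g(\tau) = a_0 + \frac{a_1}{1+a_3\tau}
  \exp\!\left(-\frac{a_2\tau^2}{1+a_3\tau}\right),$$
with $a_1 = F^2/(F+B)^2$, $a_2=(v/\omega_0)^2$ and $a_3 = 4D/\omega_0^2$,
is fitted by bounded nonlinear least squares; any parameter may be fixed
(for an immobilized bead, $a_3=0$).  Two open points are resolved as
follows: $a_0$ is always a *free* parameter (the theoretical $g(\infty)=1$
only holds for an infinitely long stationary record — a periodically
recycled bead settles to a different baseline), and the fit window excludes
lags beyond the first decay by default (`max_fit_lag`) so the periodic
recycle peaks at multiples of $\Delta t$ — which the model does not
describe — do not enter.  The calibrated speed follows from
$v = \omega_0/(2\sigma_t) = \omega_0\sqrt{a_2}$.

A note on exactness: multi-tau estimates at coarse octaves depend on where
the factor-two coarsening truncates an odd-length record, so exact
time-reversal symmetry holds when the record length is divisible by the
deepest coarsening factor (the property test uses such a length).

## 5. Maximum-likelihood diffusivity

For one displacement the likelihood of $D$ is the Gaussian density of the
free-diffusion propagator and its maximizer is
$\hat D = \Delta x^2/(2T)$ (`ml_single()`; verified against a brute-force
likelihood scan).  Although the propagator is sometimes written on
$x\in(0,\infty)$, displacements are signed and the full-line Gaussian is
used.  Per-cycle positions are reconstructed as
$$X_m(i) = X(i) + \mathrm{dir}(i)\,\big[v\,(t_w(i)-t_p(i)) - X_t\big],$$
the grouping (with $X_t$ inside the bracket) being the one that reproduces
the displacement identity
$X_m(i{+}1)-X_m(i) = X(i{+}1)-X(i) -
\mathrm{dir}(i)[\Delta X(i{+}1)+\Delta X(i)-2X_t]$
exactly — a property test asserts it to $10^{-12}$ relative.  Pooling
gives $\hat D = \frac{1}{2NT}\sum_i \Delta_i^2$, each term proportional to
a $\chi^2_1$ variate, hence the predicted relative standard deviation
$\sqrt{2/N}$ — the ±10% at $N=200$ recycles.  $T$ is the nominal reversal
delay by default; `use_measured_intervals = TRUE` substitutes the measured
burst-to-burst gaps.

**Cycle filtering and censoring.**  Following the experimental procedure,
the histogram of transit times $t_w-t_p$ is fitted with a Gaussian (least
squares, 0.1 ms bins; fallback median ± 3 MAD with a warning) and cycles
outside 3σ of its centre are rejected.  Two refinements, both defaults in
`estimate_diffusivity()` and both switchable off:

- *Censoring*: the focus physically never points outside
  $[X-X_t,\,X+X_t]$, so transit displacements are censored (winsorized) to
  $[0, 2X_t]$, and the 3σ selection operates on the censored times.  A
  detection outside the translation window then records the molecule at
  the window edge rather than being discarded or extrapolated.
- *Fallback binding*: a cycle with no burst of its own claims the last
  unassigned event of the previous window (a molecule parked near the
  launch point fires during the preceding dwell).

The rationale is bias control.  Detection itself truncates the displacement
distribution at the scan half-range ($2.65\sigma_\Delta$ at the default
operating point), which biases $\hat D$ low by ~6% — an unavoidable floor
for this measurement geometry.  Discarding out-of-window detections
(truncation) roughly triples that bias; keeping them censored nearly
cancels it, because a censored measurement retains the information that the
displacement was at least the window edge.  The end-to-end recovery test
(median over 20 seeded runs within 10% of truth) and acceptance target t4
quantify the residual.

## 6. What the synthetic world does and does not emulate

The generator reproduces: 1D Brownian motion at $D \sim 5\times10^{-11}$
m²/s, the Gaussian focus (ω₀ = 1 µm), Poisson photons with peak rate far
above background ($F=10^5$, $B=10^3$ s⁻¹ by default — bright 40 nm beads
under confocal detection), constant-velocity stage motion at 2 mm/s with a
1 ms actuation delay and ±100 µm travel, the 30 ms reversal delay,
exponential-photon-budget photobleaching, and optional second-molecule
intrusions (Poisson arrivals entering near the scan position, off by
default).

It does *not* emulate: 3D optics (pinhole, PSF tails, detector afterpulsing
or dead time), radial diffusion and the brightness fluctuations it causes,
surface sticking, stage vibration or nonlinearity, or electrophoretic
drive.  A green recovery test therefore establishes the correctness of the
algorithm chain under the stated 1D model, not the accuracy of the
instrument; in particular the real experiment's speed-calibration
discrepancy (commanded versus ACF-fitted speed, which enter the position
reconstruction linearly) is represented only as separately configurable
speeds, not resolved.

## 7. Numerical choices and degenerate inputs

- Integration step equals the 10 µs sampling bin; positions are evaluated
  at bin starts.  Burst times are reported on the bin grid.
- The WSS accumulates tap-by-tap in fixed order, so results are bitwise
  reproducible and equal to the naive double loop exactly.
- Seeds: all randomness flows through R's global RNG; a fixed seed makes
  every simulator output bit-identical (tested).
- Degenerate inputs: $t\le 0$ in the propagator, non-positive $T$ in the
  estimator, unresolvable kernels ($\sigma_t < \Delta t_w$), a reversal
  delay shorter than the translation, inconsistent direction parity, and
  fewer than 20 cycles in the filter all raise immediate errors.
- `D = 0` limits are exact (no spurious noise), and constant streams give
  $g \equiv 1$ in the correlator.

## 8. Known limitations

- The pooled estimator's small residual bias (order −5%) from
  detection-window truncation is inherent to the scan geometry; it shrinks
  with larger $X_t/\sqrt{2D\Delta t}$.
- Tracking loss by out-diffusion is possible and expected (~2 runs in 10 at
  the default operating point); downstream code must be prepared for
  sparsely detected cycle records.
- The correlator's statistical errors per lag are not propagated into the
  ACF fit by default (unweighted least squares); per-lag weighting is a
  documented extension point.
- File formats are plain text only (CSV/JSON/YAML); binary containers were
  deliberately left out.
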