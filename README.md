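# smrkit

Simulation and analysis toolkit for **single-molecule recycling (SMR) in a
capillary microchannel**.

## The problem

A single fluorescent molecule diffusing freely in solution crosses a
confocal laser focus in about a millisecond — far too briefly to watch
processes such as ligand binding, which reveal themselves as changes in the
molecule's diffusion coefficient.  SMR extends the observation time: the
molecule is confined to the axis of a ~2 µm bore capillary, and a piezo
stage translates the capillary back and forth through the fixed focus.
After each detected passage the stage waits a fixed *reversal delay*
Δt and drives the molecule back through the focus, so one molecule is
observed hundreds of times before photobleaching while spending most of its
time in the dark.

Because the axial motion is one-dimensional Brownian motion, each pair of
consecutive passages measures a free-diffusion displacement accrued over
Δt, and the diffusion coefficient follows by maximum likelihood.

## The model and estimator

- **Diffusion**: 1D Fokker–Planck (drift–diffusion); the Green's function is
  Gaussian with mean *vt* and standard deviation √(2Dt).
- **Detection**: photon counts binned at Δt<sub>w</sub> = 10 µs are passed
  through a *weighted sliding sum* (WSS) — a matched filter with Gaussian
  weights `w(t) = A·exp(−t²/2σ_t²)`, σ<sub>t</sub> = ω₀/(2v), A = 128 — and
  each above-threshold run yields one burst at its maximum.
- **Control**: the recycling centre (the running estimate of the molecule
  position, in piezo units) is updated each cycle by a proportional
  correction on the transit-time innovation,
  `X(i+1) = ((t_w − t_p) − m)·C + X(i)`,
  where `m` is the running-mean transit time and `C` converts milliseconds
  into piezo units; the stage launches each pass a prescheduled offset
  X<sub>t</sub> = 10,000 units (4.58 µm) from the centre.
- **Estimation**: molecule positions are reconstructed per cycle from the
  records, `X_m(i) = X(i) + dir(i)·[v(t_w−t_p) − X_t]`; cycles are selected
  by a 3σ window around the Gaussian peak of the transit-time histogram;
  and the pooled ML estimate is
  `D̂ = (1/2NT) Σ [X_m(i+1) − X_m(i)]²`, with predicted relative standard
  deviation √(2/N) — about ±10% at N = 200 recycles.

The closed-loop simulator reproduces the whole experiment (Brownian
dynamics, Poisson photon emission from the Gaussian focus, streaming WSS
detection, the feedback loop with actuation delay and travel limits,
photobleaching, optional second-molecule intrusions), so the analysis chain
can be validated by parameter recovery against known ground truth.

## Worked example

```r
library(smrkit)
set.seed(42)

diff  <- diffusion_model(D = 5e-11)   # m^2/s, a 40 nm bead in 50% methanol
beam  <- beam_model()                 # waist 1 um, F = 1e5 /s, B = 1e3 /s
stage <- stage_model()                # 0.458 nm/unit, v = 2e-3 m/s

run <- run_experiment(diff, beam, stage, recycling_config(), duration = 6)
run
#> <smr_run> 200 cycles (200 detected, 0 missed), 26231 photons

est <- estimate_diffusivity(run$cycles, v = stage$v_trans, T = 0.03)
est
#> <smr_estimate> D_hat = 5.071e-11 m^2/s from N = 199 intervals (T = 0.03 s)
#>   predicted relative precision sqrt(2/N) = 0.1
#>   transit-time filter: center 2.441 ms, sigma 0.8913 ms (gaussian), 0 rejected
```

The molecule was recycled 200 times in 6 s; the pooled estimate recovers
the generating 5×10⁻¹¹ m²/s within 1.4%, inside the √(2/199) ≈ 10%
single-molecule precision.  The transit-time histogram centres near the
nominal X<sub>t</sub>/v = 2.29 ms with width √(2DΔt)/v ≈ 0.87 ms
(diffusion between recycles dominates).

Speed calibration from an immobilized-bead autocorrelation fit:

```r
speed_from_transit(sigma_t = 0.47e-3, w0 = 1e-6)
#> [1] 0.00106383            # ~1.1e-3 m/s
```

## Command line

```sh
Rscript inst/scripts/smrkit simulate --config cfg.yaml --seed 1 --out run1/
Rscript inst/scripts/smrkit detect   --counts run1/counts.csv --sigma-t 2.5e-4 --threshold 640 --out bursts.csv
Rscript inst/scripts/smrkit acf      --photons run1/photons.json --fit --fix a3=0 --out acf.csv
Rscript inst/scripts/smrkit estimate --cycles run1/cycles.csv --v 2e-3 --T 0.03 --out est.yaml
Rscript inst/scripts/smrkit recover  --seed 7 --out rec/   # end-to-end truth-vs-estimate report
```

The YAML config mirrors the model constructors; an empty file gives the
experiment defaults (Δt = 30 ms, X<sub>t</sub> = 10,000 units, A = 128,
Δt<sub>w</sub> = 10 µs, ω₀ = 1 µm).

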