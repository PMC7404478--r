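---
title: "Validating a running power meter: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a running power meter: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Foot-mounted running power meters report external mechanical power (PO),
ground contact time (GCT) and leg spring stiffness (LSS) at 1 Hz from an
inertial sensor, through proprietary algorithms. Assessing their validity
requires laboratory references: force platforms for kinetics, optical motion
capture for stride timing, and a breath-by-breath metabolic analyser for the
energetic side. `stridepower` implements that whole reference chain and the
Bayesian agreement framework used to compare the device against it, together
with a spring-mass session simulator that provides ground truth, so every
stage of the analysis is testable without access to raw laboratory
recordings.

# The reference biomechanics chain

**Contact detection.** A contact opens at the first force sample with
`Fz >= threshold` and closes at the first subsequent sample below it. The
threshold is not standardised in the validity literature; the package default
is 20 N with a 10 ms debounce, conventional for 500 Hz platforms. Raising the
threshold can only shorten detected contacts (a tested monotonicity
property).

**External power by energy summation.** The centre-of-mass acceleration is
`Az = (Fz - m g)/m`, `Ax = Fx/m` with `g = 9.80665` m/s² exactly; the
medio-lateral axis is omitted as negligible on a straight track. Velocities
and displacements come from cumulative trapezoidal integration at the native
2 ms step. The recursion needs integration constants the source method leaves
unstated; the package initialises the horizontal speed at the prescribed
stage speed (pacing is externally enforced in the protocol) and chooses the
vertical constant so the stride-mean vertical velocity is zero — steady-state
running has no net vertical drift. Per stride (ipsilateral strike to the next
strike),

* `Wp = m g (max Dz - min Dz)`,
* `Wk = m/2 (max Sx² - min Sx²)`,
* `Wt = Wp + Wk` (no energy-transfer term, by construction),
* `W_ext = Wt · ω`, and `Cm = W_ext / (Sx̄ m)`.

Whether the work extrema should be taken over the contact only or the full
stride is not specified by the reference method; the package uses the full
stride window and documents that choice rather than assuming intent.

**Stride timing.** Under an equal-limb assumption the stride time is half the
interval between consecutive heel strikes of the instrumented foot,
`Ts = (C2 - C1)/2`, and `ω = 1/Ts`. Numerically this ω is a step frequency;
the package implements the formula exactly as the reference analysis prints
it and notes the reading here without asserting intent.

**Leg stiffness.** The spring-mass estimate is `kleg = F̂z / ΔL` with
`ΔL = Δy + L (1 - cos θ)` and `L = 0.53 · height`. The printed angle
expression `θ = sin(v Tc / 2L)` is dimensionally inconsistent; the geometry
of the underlying model implies `sin θ = v Tc / (2 L)`, so the package uses
`θ = arcsin(v Tc / (2 L))` and keeps the literal reading as an explicit
opt-in compatibility mode (`theta_mode = "literal"`). Δy — whose estimation
procedure the reference analysis does not state — is obtained by double
trapezoidal integration of `Az` over the contact, started from the
stride-consistent touchdown velocity; this is standard practice for the
platform-based method.

**Metabolic side.** Breath-by-breath VO2 is linearly interpolated to 1 Hz,
smoothed with a five-sample centred moving average ("fifth order" read as a
5-tap FIR, equivalent to 5 s bins at 1 Hz; centred rather than trailing to
avoid phase lag when regressing VO2 on power), truncated of its first minute
(uptake lags the instantaneous rise of power), and converted with
`W_met = VO2 · m / 60 · 21.1` J per ml O2. Net mechanical efficiency is
`ME = W_ext / ΔW_met · 100` against a resting baseline, a configuration field
(default 5 ml·kg⁻¹·min⁻¹) because no measured baseline is available. Whether
stage-mean or instantaneous ratios are intended is unstated; both are
available and the stage-mean is the default, computed over the final 20 s of
each stage where first-order kinetics are closest to steady state. Filter
edges use a shrinking window so no samples are discarded.

# The synthetic session generator

The simulator reduces the runner to a point mass on a linear leg spring. One
stride cycle of period `T` contains a single half-sine vertical contact of
duration `Tc = d · T` (duty factor `d`) followed by ballistic flight;
whole-cycle impulse balance fixes the peak force

`F̂z = m g (π/2) (T / Tc)`.

Every derived quantity then has a closed form — the COM dip during contact,
the flight rise, the works, the external power and the implied `kleg` — which
is what lets the generator serve as an oracle: the reference pipeline run on
noiseless synthetic traces must recover GCT within one sample, `W_ext` within
2% and `kleg` within 5%, and does.

Key defaults, chosen once as study conditions:

* **Protocol:** 200 m laps with a 9 m platform span at the lap start, speed
  `initial + 0.5 km/h` per 60 s stage (10 km/h start for men, 8 km/h for
  women), 500/400/1 Hz sampling. Desk-scale sessions default to 10 stages;
  the test suite uses 4-8 stages and 6 subjects, the acceptance script 8
  stages — sizes chosen to keep simulated studies comparable to a single
  laboratory cohort.
* **Duty factor:** decreases linearly with speed, 0.38 at 2.2 m/s to 0.28 at
  5.5 m/s, reproducing the negative GCT-versus-speed trend seen on the
  track.
* **Stride period:** solved at each stage speed so the implied leg stiffness
  equals `kleg_true` (default 10 kN/m, cohort draws 9-11.5 kN/m). This lands
  stride periods near 0.72 s and contact times of 0.20-0.28 s, both
  realistic.
* **Device bias:** `PO_pod = PO_true - 210 - 26 · v + noise`, i.e. roughly
  -300 W at mid-test speeds with an error growing with speed; GCT and LSS
  carry zero offset (the validity picture for such devices: power biased,
  timing and stiffness unbiased). Channel noise SDs (90 W, 20 ms,
  1.7 kN/m at 1 Hz) are scaled so per-lap means spread like the residual
  SDs a six-runner reference study reports (≈52 W, ≈0.010 s, ≈0.97 kN/m).
* **Oxygen uptake:** first-order kinetics (`τ = 30` s, a physiological onset
  constant) toward a steady state affine in mass-specific power (slope 2.7
  ml·kg⁻¹·min⁻¹ per W/kg), saturating at VO2max; breaths are a gamma renewal
  process whose mean interval shrinks from 4 s at rest to 1.5 s near maximal
  intensity. The slope was calibrated once so a default ramp approaches
  VO2max near its final stages, emulating a maximal-aerobic-speed test.
* **Noise:** no instrument noise model is reported for any of the reference
  systems, so all noise parameters are configuration, not claims.

One RNG stream per output channel is derived from the master seed, so adding
noise to one channel never perturbs another, and identical seeds give
bit-identical sessions.

**What the generator does not emulate, and a known consequence.** Real
running alternates two legs: two contacts per ipsilateral stride cycle each
carry roughly half the body-weight impulse. The generator's single-support
convention (one contact per cycle, fixed by its impulse-balance definition)
doubles the per-contact impulse and vertical excursion relative to two-legged
running. Combined with the halved stride time entering `ω`, the default
configuration yields a mechanical cost around 4-5 J·kg⁻¹·m⁻¹ — above the
1.5-3.5 range typical of human running, which the session builder logs as a
warning rather than asserts. The implied net efficiency is correspondingly
above physiological values. All validity conclusions the package draws are
*recovery* properties (estimator versus ground truth, device versus
reference) and are unaffected by this scale inflation; absolute energetic
realism is a documented limitation. The generator also omits passive impact
peaks (the half-sine profile admits closed-form oracles; notably, the device
under study is itself reported to miss the passive peak), lateral forces,
track curvature, wind, slope, stride-to-stride variability within a stage
and fatigue. Passing tests therefore demonstrate correctness of the
computational chain, not robustness to every artefact of real recordings.

# Alignment and the comparison table

The platforms occupy the first 9 m of each 200 m lap, so lap k's device
window holds the 1 Hz pod samples whose cumulative distance lies in
`[k·200, k·200 + 9)` — a half-open window in distance space, making boundary
tie-breaks deterministic. Whether the window starts at the lap line or 9 m
before it is ambiguous in the source description; the start-of-lap convention
is adopted and configurable. Laps with no pod sample are kept and flagged
missing, mirroring the unbalanced designs the mixed model must tolerate. Pod
distance is taken as reliable (as the reference analysis assumed); a drift
stress is available through the bias model but defaults off.

The long comparison table carries one row per (subject, lap, device, metric)
with a standardised speed copy. The device indicator stays 0/1 rather than
being standardised with the other covariates, so the device effect remains in
measurement units (watts, seconds, kN/m) as in the published tables; a
standardised binary would rescale it by its own SD.

# The Bayesian agreement framework

The agreement model per metric is

`y_ijk = β0 + S0_i + β1 device_k + (β2 + S1_i) speed_j + β3 (speed_j device_k) + ε_ijk`

with subject random intercepts and speed slopes. Priors follow the validity
analysis: `β0 ~ t(3, 0, 10)`; for power `β1 ~ N(0, 1000)`, `β2 ~ N(0, 200)`;
for GCT `β1, β2 ~ N(0, 1)`; for LSS `β1 ~ N(0, 10)`, `β2 ~ N(0, 1)`. The
interaction prior is unstated in the source and receives the speed-term
prior of its metric. Where the source is silent, the package uses
half-t(3, 0, 2.5 sd(y)) priors on the residual and random-effect standard
deviations and an LKJ(2) prior on the intercept-slope correlation — the
conventions of the modelling stack the analysis was built on.

**Sampling.** Models are sampled with JAGS (4 chains × 2000 iterations, 1000
warm-up, fixed seeds; the random-effect pair is non-centred and the simple
regression is covariate-centred for mixing). Split-R̂ and effective sample
sizes are recorded for every parameter; any split-R̂ above 1.01 flags the fit
non-converged. A tiny truncation floor (`1e-6 ·` prior scale) on the residual
SD keeps conditional densities finite on degenerate zero-noise inputs, which
are otherwise rightly flagged by the R̂ guard. Chains start from
data-informed values (OLS fixed effects and a residual-based variance
split): the vague-location intercept prior admits a spurious posterior mode
in which the grand mean migrates into the random intercepts with an inflated
between-subject SD, and chains initialised from the prior can be trapped
there; the non-centred scheme started in the data-supported basin stays
there without any change to the model. The residual cost is slow mixing
along the weakly identified intercept-versus-random-mean direction: the
intercept and random-intercept SD carry low effective sample sizes and can
trip the conservative convergence flag even when every scientifically
interpreted quantity (device, speed, interaction, residual SD) mixes well —
inspect the per-parameter R̂ and ESS that every fit records.

**Bayes factors.** `BF10` for a term compares the full model against the
model without that term via bridge-sampled marginal likelihoods. The bridge
runs warp-III (moment-matched and symmetrised) on the unconstrained scale,
with the mixed model's random effects integrated out analytically (the
Gaussian-LMM marginal is multivariate normal per subject; Woodbury identities
keep every solve at 2×2), so the bridge operates in the low-dimensional
space the sampler actually explored. The iterative optimal-bridge estimator
reports an iid-approximation relative standard error; above 10% it falls
back to normalised importance sampling with a warning. Evidence labels
follow the Jeffreys scale (≥100 extreme, 30-100 very strong, 10-30 strong,
3-10 moderate, 1-3 anecdotal, with the inverse scale below 1).

**ICC.** With random slopes the intraclass correlation is evaluated at the
covariate reference point (standardised speed 0), where the slope variance
drops out: per posterior draw, `ICC = σ²_subject / (σ²_subject + σ²_res)`,
summarised by its median and 95% credible interval.

**Correlation.** The pairwise Bayesian correlation test uses the Jeffreys
analysis in closed form: the posterior of ρ proportional to
`(1-ρ²)^((n-1)/2) (1-ρr)^(-(n-3/2))` on a fine grid, with the Bayes factor
against ρ = 0 by numerical integration. No MCMC is involved; the computation
is exact to grid resolution (8001 points).

**Bland-Altman.** Bias is `mean(device - reference)`, limits of agreement
`bias ± 1.96 sd`, confidence intervals by the standard normal-theory
formulas, plus a proportional-error slope of differences on pair means.

**R².** Credible intervals for R² are reported from a posterior-predictive
(draw-wise `var(fit)/(var(fit)+σ²)`) definition; the source does not define
its Bayesian R² variant, and no claim is made that this is the same one.

**Correction function.** The linear map from device to reference power,
`f(x) = a x + b`, is fitted by least squares on per-speed (0.5 km/h bin)
averages. The published coefficients for this map are descriptive of a
particular six-runner cohort; the package recomputes them for whatever data
it is given.

# Numerical choices, degenerate inputs

* Trapezoidal rule everywhere (second-order; verified against closed forms
  at 0.1%).
* Contacts shorter than the 10 ms debounce are discarded; a trailing contact
  that never closes is dropped.
* Strike detection on the marker: strict local minima below the 10th
  percentile + 5 mm, minimum separation 0.25 s; flat minima take the first
  sample of the run.
* Non-physical stiffness inputs (`v Tc / 2L ≥ 1`, `ΔL ≤ 0`) and non-physical
  stride parameters (duty outside (0,1), non-positive speeds) raise
  validation errors rather than producing numbers.
* The grid correlation posterior uses log-space normalisation, so degenerate
  `r = ±1` inputs yield finite (huge) Bayes factors instead of overflow.

# Known limitations

* Single-support stride geometry inflates absolute power and cost (above);
  device/reference *differences* and all recovery properties are unaffected.
* The flight-time estimate from a smooth marker model is coarse and is
  reported for inspection only.
* Bridge-sampling standard errors use an iid approximation over MCMC draws
  and modestly understate uncertainty for autocorrelated chains.
* With six subjects, random-effect SDs and the ICC are wide by design; tests
  assert recovery at correspondingly wide tolerances.
* FIT-file ingestion is out of scope; CSV is the canonical interchange
  format, with schemas validated on read.
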