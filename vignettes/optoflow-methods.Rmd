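---
title: "Models and methods behind optoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoflow)
```

## The system

Bundled microtubule networks driven by clustered kinesin motors form an
*active fluid*: extensile stresses along aligned bundles drive spontaneous
flows and, in confinement, a bend instability of the aligned state. When the
motor clusters are held together by a light-induced dimer, the active stress
can be switched on and off with illumination, dosed by intensity, and
confined to patterned regions. optoflow quantifies such experiments from
time-lapse fluorescence images and provides seeded generators that emulate
the microscopy, so every analysis stage can be validated against programmed
ground truth.

All lengths are in µm, times in s, intensities in µW/mm², and images use
array coordinates: row = y (downward), column = x (rightward), with x the
initial alignment direction and angles measured CCW from +x. Orientations
are nematic (θ and θ ± π are identical).

## Flow measurement (PIV)

`piv_pair()` tiles a frame pair into interrogation windows (default
32 px with 16 px overlap, matched to textures whose across-bundle
correlation length is 4–8 px) and takes each window's displacement from the
peak of the *normalized* cross-correlation, computed with per-lag overlap
means and variances (Lewis-style). The full normalization matters here:
fluorescence textures are strongly correlated along the bundles, and the
plain zero-padded FFT correlation is biased toward zero lag for such
textures. The peak is refined per axis by a three-point Gaussian fit
(falling back to a parabolic fit when a neighbour is non-positive), giving
roughly 0.1 px accuracy. The search radius defaults to a quarter window —
the usual PIV dynamic-range rule; larger displacements need a shorter frame
interval or larger windows.

Spurious vectors are handled by `filter_outliers()`, a normalized median
test on 3×3 node neighbourhoods: the vector-magnitude residual about the
neighbourhood median is normalized by the neighbourhood's mean residual
plus a regularization ε (default 0.1 µm/s) and compared with a threshold
(default 2). The mean residual is used as the scale estimate because with
only 8 neighbours the median residual is noisy enough to flag ~20% of a
featureless field; the mean keeps that false-flag rate under ~10%. Nodes
without full 8-neighbour support (grid borders, neighbours of invalid
nodes) pass through untested. Flagged vectors are replaced by the
neighbourhood median and marked. `mean_speed()` excludes invalid nodes
rather than zero-filling them, which would bias the mean downward, and
`speed_trace()` timestamps each pair at its midpoint.

## Photoswitching kinetics

Across dark/light cycles the mean speed follows first-order switching
kinetics. On activation,

$$\langle|v(t)|\rangle = v_{max}\,(1 - e^{-t/\tau_{on}}),$$

fitted by nonlinear least squares jointly over $(v_{max}, \tau_{on})$
(`fit_activation()`; a fixed-$v_{max}$ mode exists because either
convention is defensible — the joint fit is the default). On deactivation
the normalized speed follows a logistic decay, implemented as

$$\hat v(t) = \frac{2}{1 + e^{+t/\tau_{off}}},$$

which satisfies $\hat v(0) = 1$ and decays to 0; the commonly printed form
with $e^{-t/\tau_{off}}$ *rises* from 1 to 2 and contradicts the measured
decay, so we treat it as a sign typo and fit the decaying branch
(`fit_deactivation()`). Deactivation traces are normalized by the mean of
the last three on-state samples before the transition
(`normalize_deactivation()`): the model's right side is dimensionless with
value 1 at the transition. Per-cycle plateau and dark speeds use medians
over the last half of each interval for robustness to PIV spikes, and the
dark-speed trend is an ordinary regression over cycles
(`cycle_summaries()`). The intensity–speed response summarises plateau
speeds per intensity; since saturation is described qualitatively in the
literature, `intensity_response()` exposes a rule — the smallest intensity
reaching 95% of the sweep maximum — with the fraction configurable.

## Bend-angle analysis

`orientation_field()` computes the structure tensor from Gaussian-derivative
gradients (σ_grad, default 1 px) smoothed at a larger window scale
(σ_window, default 4 px). The dominant eigenvector points across the
filaments, so angles are rotated by π/2 to the filament direction;
coherence $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ masks texture-free
pixels (default threshold 0.3; the mask and a signed-average option are
exposed because neither choice is canonical). The mean deviation angle is
the mean *absolute* nematic deviation from the initial director — bend is
sign-symmetric, and the absolute value keeps the trace non-negative.

After deactivation the angle follows a two-timescale model,

$$\langle\theta\rangle(t) = e^{-t/\tau}\,\dot\gamma\,t + C\,e^{-t/r},$$

the product of activity-driven linear growth $\dot\gamma t$ with the
exponential unbinding of the light-induced clusters (τ), plus elastic
recovery of the passive network (r, amplitude C). `fit_relaxation()` fixes
$\dot\gamma$ (measured separately as the on-state slope, `growth_rate()`),
initialises τ at 24 s — the independently reported unbinding time of the
light-induced dimer — and fits (τ, r, C). C is refit per off-interval
rather than pinned to the angle at deactivation (it is a scaling
parameter; continuity only informs the starting value). When
$\dot\gamma = 0$ the unbinding term vanishes and τ is structurally
unidentifiable: the fit drops to the elastic term alone and is flagged, as
it is whenever the (τ, r) estimate correlation exceeds 0.99.

## Strain analysis and regimes

Displacements accumulate Eulerian-ly on the fixed PIV grid
(`accumulate_displacement()`): $u(t_k) = \sum_{j\le k} v(t_j)\,\Delta t$,
with invalid nodes contributing zero increments (counted per node). This
matches the PIV output structure and is exact for affine flows; for the
order-one strains of strong buckling it is an approximation, which we
document rather than replace with Lagrangian tracking. Normal strains
$\gamma_{xx} = \langle\partial u_x/\partial x\rangle$ and
$\gamma_{yy} = \langle\partial u_y/\partial y\rangle$ come from central
differences, averaged over the activated region after eroding it by one
interrogation window so boundary-straddling windows never contribute.

Regimes are classified from the raw strain traces
(`classify_regime()`): *buckling* if the net transverse change
$\Delta\gamma_{yy}$ exceeds 0.5%, else *sliding* if the final
$\gamma_{xx}$ exceeds 0.5%, else *quiescent*. The slow negative
$\gamma_{yy}$ drift from depletion-induced contraction is deliberately not
subtracted — the threshold rule is applied to the raw net change, matching
how the 0.5%-in-17-min criterion is used experimentally (the activation
window is a configurable parameter, defaulted to 17 min in the pipeline).
`threshold_intensity()` returns the smallest tested intensity whose
$\Delta\gamma_{yy}$ exceeds the criterion, with an explicit "not reached"
sentinel.

## Confinement threshold model

The aligned state goes unstable when a dimensionless activity reaches a
geometric bound set by the activated region (length L along the alignment,
width W) and chamber height H:

$$\alpha_{eff} = \begin{cases}
\pi^2 L^2\left(\frac{1}{L^2}+\frac{1}{W^2}+\frac{1}{H^2}\right)^2, &
\frac{1}{L^2} > \frac{1}{W^2}+\frac{1}{H^2}\\[4pt]
4\pi^2\left(\frac{1}{W^2}+\frac{1}{H^2}\right), & \text{otherwise.}
\end{cases}$$

The branches coincide at the boundary (we return the saturated branch
there; the choice is numerically irrelevant), the bound is non-increasing
in L, symmetric in W ↔ H, and saturates as L → ∞. As written the right
side carries units of µm⁻² even though the group is referred to as
dimensionless; we adopt the literal form and keep the unit conversion of
the fitted coefficient to the user (the nW⁻¹ convention used alongside
intensities in µW/mm² is not reconcilable from the main-text definitions
alone, so `fit_activity_coefficient()` reports the raw slope in the user's
intensity units per µm⁻²).

Assuming the light-induced stress is proportional to intensity,
$I = a\,\alpha_{eff}$, the coefficient is the least-squares slope through
the origin (inverse-variance weighted when standard errors are present; an
optional intercept mode exists for diagnostics only). The phenomenological
comparison fit $I = g_A/L^2 + g_C$ (`fit_generic_scaling()`) describes
noiseless model data over typical L ranges nearly as well — the two fits
discriminate poorly there, which we document rather than assert as a
difference.

## The synthetic generators

The generators define the conditions under which the package is tested.

* **Texture** (`gen_texture()`): an anisotropic band-pass Gaussian random
  field elongated 6× along the director (across-bundle correlation length
  4–8 px in typical use), mixed with 35% fine isotropic speckle (1.5 px)
  emulating fluorophore granularity. The speckle is what real PIV relies
  on along the bundle direction; without it, displacement along smooth
  bundles is ill-posed. Frames are periodic (built in Fourier space) and
  normalized to [0, 1].
* **Rendering** (`render_sequence()`): backward-mapping warp with bilinear
  interpolation of the time-integrated flow, gated by the illumination
  schedule in time and (through the region) space. Periodic boundary
  handling is the default because the textures are periodic — under large
  integrated displacements the warp then never runs out of texture.
  The bend mode programs the local director tilt directly as
  $(\pi/2)\dot\gamma t\sin(kx)$ and integrates its tangent into a
  transverse displacement profile, so the mean absolute tilt grows at
  exactly $\dot\gamma$ — a shear-displacement parameterisation would
  under-deliver tilt through the arctangent. Optional features, both off
  by default: post-deactivation relaxation of the accumulated displacement
  (`relax_r`), and dimmed inflow from outside the activated region
  (`background_dim`) so sustained outflow visibly drains the region.
* **Traces** (`gen_speed_trace()`, `gen_angle_trace()`): piecewise closed
  forms of the kinetics above, with seeded additive Gaussian noise. Noise
  defaults in the tests are 10% of the plateau (speed) and 0.005 rad
  (angle), chosen once from the visual roughness of typical measured
  traces; trace-noise statistics are not reported quantities. An optional
  linear dark-speed creep emulates the slow rise of dark-state flows.
* **Threshold data** (`gen_threshold_dataset()`): $I^* = a\,\alpha_{eff}$
  with multiplicative Gaussian noise.

What the generators do **not** emulate: motor stepping and network
mechanics (flows are kinematic), Poisson shot noise (the PIV and
structure-tensor operators are insensitive to the additive/Poisson
distinction at tested SNR), out-of-plane motion (the analysis treats the
system as quasi-2D throughout), hysteresis, and the mechanism of
depletion-induced contraction (only its signature drifts are available as
options). Passing tests therefore demonstrate correctness of the
*measurement and fitting chain* under realistic image statistics, not a
physical simulation of the experiment.

## Problem sizes and numerical choices

The validation suite runs on 128–256 px frames, 6–13 frame sequences,
traces sampled at 1 s over 80–400 s, and 7–10 geometry threshold
datasets — sizes at which every stage's ground truth is still programmed
exactly and the full suite completes in well under a minute of compute.
Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with positivity
bounds and the initialisations given above; activation fits start τ_on at
the observed half-rise time over ln 2. Degenerate inputs are flagged
rather than silently fitted: constant activation traces (no resolvable
rise), monotone-wrong-direction transients, zero-variance PIV windows,
and texture-free orientation pixels all produce explicit flags or errors.

## Reproducibility

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state; `run_pipeline()` refuses a simulate stage without one.
Rerunning a pipeline config reproduces trace CSVs byte for byte, and the
run report records parameters, outputs, package version and a config hash.
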