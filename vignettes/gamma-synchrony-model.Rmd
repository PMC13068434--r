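---
title: "A weakly coupled oscillator model of V1 gamma synchrony and figure-ground segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A weakly coupled oscillator model of V1 gamma synchrony and figure-ground segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gammatongue)
```

## The model

`gammatongue` models a patch of primary visual cortex responding to a
texture of Gabor annuli as a sheet of N = n² weakly coupled phase
oscillators,

θ̇ᵢ = ωᵢ + (1/N) Σⱼ Kᵢⱼˢ sin(θⱼ − θᵢ),

where each oscillator stands for a neural assembly whose gamma-band
oscillation frequency is set by the contrast it sees and whose lateral
coupling to other assemblies decays with cortical distance. The theory
of weakly coupled oscillators predicts synchronization when coupling
overcomes detuning; in stimulus terms, contrast heterogeneity ζ (the
width of the uniform distribution, centred on 0.5, from which annulus
contrasts are drawn) controls detuning, while grid coarseness ρ (a
multiplier on annulus spacing) controls, through retinotopy, cortical
distance and hence coupling. The map of synchrony over the (ζ, ρ) grid
is an Arnold tongue; linked to two-alternative forced-choice accuracy
through a logistic psychometric function, it predicts where observers
can report the orientation of a texture-defined figure.

The chain from stimulus to synchrony is:

1. **Stimulus.** A √45° ≈ 6.7° square patch at 7° eccentricity (the area
   of the 9° × 5° figure used behaviourally), tiled with non-overlapping
   Gabor annuli (diameter 0.7°, 5.7 cycles/degree, mean luminance equal
   to the 60.76 cd/m² background) on a jittered regular grid.
2. **Afferent drive.** Per-oscillator local contrast is the weighted RMS
   contrast over an isotropic Gaussian receptive field; intrinsic
   frequency is ν = 25 + 0.25·C Hz with C in percent, spanning the
   physiological 25–50 Hz gamma range.
3. **Dynamics.** One second of Kuramoto dynamics per trial from uniform
   random initial phases; synchrony is the Kuramoto order parameter
   magnitude averaged over the second half of the trial; pairwise
   phase-locking values (PLV) are computed over the same window
   subsampled to 50 timepoints.
4. **Plasticity.** Between sessions, coupling relaxes toward
   experience-scaled functional connectivity:
   K^{s+1} = e^{−E} Kˢ + (1 − e^{−E}) γ Qˢ, with Qˢ the
   correctness-weighted mean of the session's PLV matrices. Correctness
   weights come from the psychometric link P_c = 1/(1 + e^{−μ₀−μ₁r})
   fitted on session-1 data; the effective learning rate E is estimated
   against session-2 behaviour by a coarse-to-fine grid search.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n` | 20 | – | sheet side; N = 400 oscillators |
| `a`, `alpha` | 0.7, 0.9 | deg, cm | monopole retinotopy w = α·log(z + a) |
| `mm_per_unit` | 10 | mm/unit | expresses map distance in millimetres |
| `gamma` | 24.63 | rad/s | maximum coupling strength |
| `lambda` | 0.22 | 1/mm | coupling decay with cortical distance |
| ν intercept, slope | 25, 0.25 | Hz, Hz/% | contrast–frequency mapping |
| RF diameter | max(0.172e − 0.25, 1) | deg | threshold-linear eccentricity scaling; σ = diameter/4 |
| `duration`, `dt` | 1, 0.001 | s | trial integration window and output grid |
| `subsample_points` | 50 | – | PLV timepoints (second half of trial) |
| `base_spacing` | 0.9 | deg | annulus grid spacing at ρ = 1 |
| `E_range` | [10⁻³, 10] | – | first grid of the learning-rate search |

γ and λ are constants taken from macaque electrophysiology and are not
fitted here; μ₀, μ₁ and E are the model's only free parameters and are
fitted from sessions 1–2 only, with sessions 3–8 reserved for
prediction (enforced by the leave-one-out harness in
`loo_cross_validate()`).

### The cortical distance unit

The monopole map with the generic human constants a = 0.7, α = 0.9 spans
about 1.1 units across the modelled patch. The coupling decay λ = 0.22
originates from recordings in which cortical distance is measured in
millimetres. We therefore read the map output as centimetres and express
pairwise distances in millimetres (`mm_per_unit = 10` in
`retinotopy_params()`), giving the patch a cortical extent of ≈ 11 mm —
the same order as the classical human magnification estimate (≈ 16 mm
between 3.7° and 10.4° eccentricity). This reading matters: with raw map
units the exponential decay is negligible across the patch, coupling is
effectively uniform at ≈ 22 rad/s, and the sheet synchronizes at every
heterogeneity level — no Arnold tongue forms. In millimetres the model
reproduces the expected regime: synchrony at low ζ on dense grids, a
synchronization cutoff near ζ ≈ 0.25 at ρ = 1 (the packaged sweep in
`scripts/acceptance.R` reports 0.21–0.26 depending on the seed at ten
trials per level), and a triangular tongue that shrinks with ρ. The unit
conversion is exposed as a parameter so other conventions can be
explored.

### Other choices the design left open

- **Annulus luminance profile.** A "Gabor annulus" is realised as a
  radial carrier cos(2πf·r) windowed by an annular Gaussian envelope
  (ring radius d/4, envelope SD d/8, hard cutoff at d/2), then shifted
  to zero mean over its support and normalised to unit peak. The
  zero-mean shift makes every annulus exactly equiluminant with the
  background, which is the property the model consumes (only the RMS
  contrast reaching a receptive field matters downstream).
- **Contrast units.** The weighted RMS of relative luminance deviations
  is dimensionless; it is scaled by 100 before the frequency mapping so
  that C spans percent and ν spans 25–50 Hz. The factor is exposed in
  `weighted_rms_contrast()`.
- **Grid spacing.** The centre-to-centre spacing at ρ = 1 is 0.9°
  (larger than the 0.7° diameter, leaving jitter room); the jitter
  radius is uniform on [0, (spacing − diameter)/2], which guarantees
  non-overlap by construction.
- **Experience-matrix normalization.** Correctness-weighted PLV sums are
  divided by the summed weights (a weighted mean), which keeps Q in
  [0, 1], preserves the K ≤ γ bound of the convex update and the γQ
  fixed point. A per-trial-count normalization was considered and
  rejected: it dilutes Q below the session-1 coupling level and makes
  coupling *decay* across sessions instead of growing.
- **Per-fold pooling.** Fitting uses the across-participant mean
  accuracy tongue of the held-in group.
- **Psychometric surface.** The 2D accuracy surface for the 75% contour
  is a chance-floored logistic, acc = 0.5 + 0.5·logistic(β₀ + β₁ζ +
  β₂ρ + β₃ζρ), fitted by binomial maximum likelihood (`optim`, BFGS,
  numeric-Hessian standard errors).
- **Initial phases** are i.i.d. uniform on [0, 2π) per trial, from a
  named random stream; every stochastic step derives its own stream
  from the master seed via `derive_seed()`, so results are independent
  of execution order.

## Numerical choices

The trial integrator is a compiled fixed-step classical Runge–Kutta
scheme (RcppArmadillo) on the 1 ms output grid, with a configurable
number of substeps (default 2). The phase system is non-stiff with
|ω| ≤ 100π rad/s, so the local error per 0.5 ms step is ≈ (ωh)⁵/120 ≈
10⁻⁷ rad and the global phase error over a trial is far below the
Monte-Carlo variability of the synchrony readout; the test suite checks
the integrator against `deSolve::ode` (lsoda, rtol 10⁻¹⁰) to better than
10⁻⁴ rad over a full trial, and against the closed-form linear drift at
zero coupling exactly. A fixed grid makes trials bit-reproducible and is
roughly two orders of magnitude faster than an adaptive integrator
called from R, which the learning-rate grid search (125 session
re-simulations) requires.

Degenerate inputs are handled explicitly: constant maps are rejected by
min-max normalization and Pearson similarity; two all-zero maps have
weighted Jaccard 1; Simpson integration requires three points per axis
and closes an even-count axis with a trapezoid panel; grid-search ties
resolve to the smallest candidate learning rate (parsimony); a
perfectly separated psychometric fit is flagged rather than silently
returned.

## The synthetic behavioural generator

`generate_cohort()` emulates the structure of the human dataset the
analysis pipeline expects: 8 participants × 9 sessions (8 training plus
one transfer) × 30 blocks × 25 conditions, one trial per condition per
block, with per-trial correctness drawn from
max(0.5, (1 − lapse)·P_c(r)) at the participant's own psychometric
parameters and learning rate. Subject-level heterogeneity uses normal
intercept offsets (SD 0.3), log-normal slope scales (log-SD 0.2),
log-normal learning rates (median 0.15, log-SD 0.3 — a rate that
produces gradual, roughly linear tongue growth across eight sessions
rather than early saturation) and uniform lapse rates on [0, 0.05].
The transfer session reuses the session-1 synchrony tongue: learning in
the model is retinotopically local, so moving the figure to an untrained
quadrant resets performance.

What the generator does *not* emulate: sequential effects and
within-session learning, fixation breaks and aborted-trial repetition,
reaction times, and any deviation of real observers from the logistic
synchrony–accuracy link. Tests that pass on synthetic cohorts therefore
validate the estimation machinery (identifiability, leakage-freedom,
protocol counts), not the model's adequacy for human data.

## Known limitations

- **Learning-rate identifiability.** The effective learning rate is
  estimated, following the original procedure, by maximizing the
  weighted Jaccard similarity between the min-max normalised behavioural
  tongue and the raw session-2 synchrony tongue. Because normalised
  accuracy spans [0, 1] while the synchrony tongue under the
  macaque-calibrated coupling peaks well below 1, raising E (which
  raises synchrony everywhere) increases the overlap monotonically over
  several decades, and the search tends to the upper end of its range
  regardless of the generating rate. A Pearson objective on the same
  tongues peaks at the generating rate, showing the shape information is
  present; the packaged estimator nevertheless implements the weighted
  Jaccard objective as specified, and the corresponding
  parameter-recovery test documents the failure rather than masking
  it. Users fitting real data should inspect the search trace
  (`estimate_learning_rate()$trace`) for boundary solutions.
- **Figure-only simulation.** The background texture is not simulated;
  background synchrony is equated with the figure at ζ = 1, and the
  rate-difference readout uses feedforward frequencies only.
- **Static stimuli, no attention.** One second of stationary drive per
  trial; attentional gain and within-trial dynamics of the stimulus are
  out of scope.
- **Problem sizes in the test suite.** The packaged tests run the full
  20 × 20 sheet for the session-1 cutoff sweep (21 ζ levels × 10
  trials), the 5 × 5 tongue (12 blocks) and the 8-session learning run
  (5 blocks per session), and a 10 × 10 sheet for the cohort-recovery
  pipeline — sizes chosen so the whole suite completes in minutes on a
  single CPU while keeping the full-sheet physics for the headline
  properties. The full experimental protocol (30 blocks, 8 + 1
  sessions, 8 participants) is available through `experiment_config()`
  defaults.
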