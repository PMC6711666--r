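---
title: "Models and methods behind tonothal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tonothal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tonothal` implements the computations of a 7T fMRI study design for the
auditory thalamus: tonotopic mapping and parcellation of the medial
geniculate body (MGB), hierarchical Bayesian modelling of one-back task
behaviour, group-level brain–behaviour correlation under permutation-based
small-volume control, and a random-effects meta-analysis. This vignette
documents the models, the parameters that matter, the numerical choices, and
the places where a design decision was genuinely open.

## Frequency features and the encoding design

Waveforms are analysed by a bank of 128 overlapping bandpass filters equally
spaced in log-frequency over 180–7040 Hz (5.29 octaves), realized as
triangular weights on the log2 axis applied to the Welch-averaged power
spectrum. The filterbank is constant-Q (bandwidth proportional to centre
frequency, default half-width two filter spacings); each filter's output is
a weight-normalized average, so a flat power spectrum yields flat band
energies. Cochlear nonlinearities (lateral inhibition, adaptation) are not
modelled: downstream analysis consumes only time-averaged band energies, for
which a linear constant-Q analysis is sufficient. The energy convention is
power (squared magnitude).

The tonotopic axis is divided into 12 equal octave bins
(Δ = log2(7040/180)/12 ≈ 0.4408 octaves; bin 1 ends at ~244 Hz). Only bins
1–10 are retained, because bin 10's upper edge (~3.82 kHz) is the highest
band inside the linear response range of MR-compatible headphones (~4 kHz).
Bins *average* the filter energies they contain (summing would re-weight
bins by filter count; averaging keeps the flat-spectrum property).

**Z-scoring.** Feature columns are standardized across sounds (mean 0, SD 1
per bin), the standard encoding-model practice that stops energy-rich low
bins from dominating the fit. The alternative reading — normalizing each
sound across its bins — is available as `direction = "acrossBins"`.

**HRF.** Canonical double-gamma (response peak 6 s, undershoot 16 s,
peak:undershoot 6), unit peak, microtime resolution 0.1 s. Point events are
delta approximations (a unit impulse contributes a unit-peak HRF regardless
of `dt`); epochs are boxcars with integral semantics. Sparse (clustered)
acquisition is modelled by placing events at their true presentation times
inside the silent gap and sampling the convolved regressor at the
acquisition-window midpoints (`sparseFrameTimes`); the midpoint is a
convention — the acquisition moment is not defined more precisely by the
sequence — and is configurable.

## First-level GLM

Estimation is voxelwise ordinary least squares via a QR decomposition;
rank-deficient designs are rejected naming the dependent columns, and
residual df equals volumes minus design rank. Serial-correlation
prewhitening (AR(1)+REML as in common SPM practice) is intentionally not
applied: the package's synthetic data have white noise by construction, and
the quantities of interest are coefficient and contrast recovery. The
interface keeps the design/fit separation so a prewhitening step can be
inserted before `fitGlm` without touching downstream code. A separable
Gaussian smoothing utility (`smoothVolume`, FWHM in mm) is available but off
by default.

The speech-experiment design codes five HRF-convolved conditions (task ×
change type, plus a 2 s instruction epoch; the instruction's duration
handling is an epoch boxcar, a choice the source design leaves open) and one
response regressor coded 0.5/−0.5/0 for hit/miss/no event, averaged when
several target events share a volume (`codeResponses`). The response
regressor is HRF-convolved by default — it enters the GLM like any other
neural regressor — but the pre-convolution coding is exposed, and
`convolveResponse = FALSE` keeps the raw coding as the regressor.

## Best-frequency maps, gradient angles, parcellation

Each in-mask voxel is labelled with the bin of its largest coefficient; ties
break to the lowest bin (deterministic, and biologically conservative — ties
under noise carry no evidence for the higher frequency). All-NA voxels leave
the mask.

**Gradient estimation.** Angles are computed per sagittal slice as
atan2(∂f/∂y, ∂f/∂x) with central differences (one-sided at mask borders),
zero-gradient voxels excluded, unweighted counts in 5° bins, averaged over
slices then participants. The open question is what field f to difference.
Differencing the raw integer labels quantizes the gradient onto a sparse
lattice of directions: for a planar ramp of ~3 bins/mm on a 1 mm grid the
central differences take a handful of discrete values and the exact planted
direction can be unrepresentable, so histogram maxima land in neighbouring
bins even at zero noise. The default therefore differences the
coefficient-weighted best-frequency centroid (Σ_k k·c_k / Σ_k c_k, negative
coefficients clipped) whenever coefficient volumes are attached to the map.
With the package's triangular tuning curves the centroid is an exactly
linear function of the underlying continuous tonotopic field, so gradient
*directions* are preserved exactly; for any unimodal tuning it is a monotone
transform, which still preserves directions wherever the transform is
locally smooth. `method = "labels"` retains the raw-label estimator.
Angles are binned with a 10⁻⁷-degree guard so that a direction
computed as 129.999999998° by floating point still lands in its own
[130°, 135°) bin.

Local maxima of the circular histogram use wrap-around neighbours with
plateau collapsing (a run of tied bins is one candidate at its first bin)
and a 30° minimum separation, large enough to separate the two MGB
gradients (170° apart) while suppressing side-lobes of one peak.

**Parcellation.** Within each slice, voxels carrying the slice's maximal
label form the high-frequency ridge; every other in-mask voxel is assigned
to the region above or below the ridge, comparing its superior coordinate
with the mean ridge position in its own (or nearest) anterior–posterior
column. This conserves voxels exactly (region1 + region2 + ridge = mask) and
yields two MGB-scale regions (tens of mm³ at the default geometry). Centre
of mass is the unweighted mean of member voxel centres in world mm; volume
is voxel count × voxel volume.

The 90° z-rotation used before slicing is a pure axis permutation with the
matching affine update — no interpolation, bit-exact invertibility.

## The behavioural models

Per-trial outcomes follow
Bernoulli(logit⁻¹(A + B_S·task + B_V·change + B_SV·task·change)), with each
coefficient split into population + participant + run terms. The
4-dimensional participant and run deviation vectors are multivariate normal
with covariance diag(σ)·R·diag(σ): Normal(0, 5) priors on the four fixed
effects, HalfCauchy(2) on the eight scales, and an LKJ prior on each 4×4
correlation matrix. The source notation for the correlation prior couples an
LKJ density with a HalfCauchy scale symbol; it is read here as a
4-dimensional LKJ correlation prior (shape η, default 2) combined with the
HalfCauchy(2) scale priors in a Cholesky-parameterized covariance — the
standard construction that notation points at. Only target (change) trials
are scored; whole-stimulus scoring would mix the button-press decision with
stimulus bookkeeping.

**Sampler.** No gradient-based sampler with an LKJ prior is assumed;
`tonothal` ships its own adaptive Metropolis-within-Gibbs sampler (C++):

* non-centred parameterization (deviations = diag(σ)·L·z with z ~ N(0, I));
* correlation matrices through the C-vine canonical-partial-correlation
  transform, whose LKJ(η) prior is exactly independent shifted-Beta
  densities per partial correlation (shape η + (d−1−k)/2 at tree level k);
* blocks: covariance-adaptive random walks for the fixed effects, scales
  and correlation parameters (Haario-style empirical covariance learned in
  warm-up; scalar scale tuned to 23% acceptance), per-group random walks for
  the z vectors (only that group's trials are re-evaluated);
* likelihood-invariant *translation* moves (shift a fixed effect, compensate
  all z so every effect value is unchanged; accepted on the prior ratio
  alone) and *rescaling* moves (change one σ, rescale the corresponding z
  coordinates; prior × Jacobian e^(−Gδ)); these interweaving moves break the
  two funnels — fixed effect vs deviation mean, and scale vs coordinate
  magnitude — that otherwise dominate the autocorrelation time;
* a 20% mixture of independence proposals from the LKJ prior for the
  correlation blocks, for which the Hastings ratio reduces to the bare
  likelihood ratio; weakly identified correlations (notably run-level ones
  with 5 runs) then mix by prior refreshment.

Split-chain R̂ and a summed-autocorrelation effective sample size are
attached to every fit; any parameter with split-R̂ ≥ 1.01 raises a warning
and flags the fit (`settings$converged`). With short demonstration chains
the flag is typically raised by weakly identified correlation parameters;
fixed effects converge much faster. The default settings reproduce the
original analysis scale (3 chains × 20,000 draws, 5,000 warm-up; an optional
`retain` reproduces the 7,500-draw variant — the source description of
retained draws is internally inconsistent, so the default keeps all
post-warm-up draws).

**Reaction times** use the same random-effect structure with a Student-t
likelihood (ν estimated, Exponential(0.1) prior on ν−2, HalfCauchy(2)
residual scale) on mean-centred reaction times *in seconds*, where the
T(3, 0, 1) fixed-effect priors are weakly informative; the source's
reaction-time equations repeat the Bernoulli likelihood line, which is
treated as a typo for a continuous likelihood. Effects are reported in ms.

**Posterior summaries.** `hpd` returns the narrowest contiguous interval at
the requested mass by a sorted-sample sweep (O(n log n)); clearly multimodal
draw sets (an interior gap exceeding a quarter of the range) are annotated,
not split. `taskHitRates` defaults to population-level rates (random effects
at zero), matching how group rates are usually quoted; a marginal variant
integrates over both random-effect distributions by 21-node Gauss–Hermite
quadrature on the linear predictor.

## Group statistics

The across-participant correlation between contrast values and behavioural
scores is the regression slope t (df = n − 2), interconvertible with Pearson
r via `tToR`; the printed-effect transform t = 2.97 → r happens at df = 32
(0.465) versus df = 31 (0.471) — both are exposed; the model-implied default
is n − 2.

Small-volume FWE control is permutation-based: the null distribution of the
within-mask maximum |t| under covariate shuffles (correlation analyses) or
sign-flips (one-sample contrasts), with exhaustive enumeration whenever the
group size allows (2ⁿ or n! ≤ requested permutations). Corrected p is the
proportion of null maxima at or above the voxel's statistic with the
add-one correction for sampled nulls — valid (P(p ≤ α) ≤ α + 1/(B+1))
without any distributional or smoothness model, which is why a
random-field-theory implementation is not needed at region-of-interest
scale. Ties are compared with a 10⁻¹² slack so that enumerated statistics
equal to the observed one count as at-least-as-large.

Correlation comparisons use Fisher-z tests: independent samples; the
dependent-overlapping case (two correlations sharing one variable) via the
backtransformed-average method with the Pearson–Filon covariance term; and
the dependent-nonoverlapping case, which requires the four linking
cross-correlations. Outlier handling is a single pass: participants more
than k (default 2) SD from the contrast mean are removed once and the
correlation recomputed — no iteration, matching the robustness check it
implements.

## Meta-analysis

d_i ~ Normal(μ, τ² + se_i²) with τ² estimated by the ML fixed point
τ² ← Σw²((d−μ)² − se²)/Σw², floored at zero, iterated to 10⁻¹⁰ (REML adds
the usual 1/Σw correction). ML is the primary method because it is what the
pooled result this package mirrors used; REML is offered for comparison.
τ² = 0 reduces exactly to fixed-effect inverse-variance pooling. The helper
`dFromT` (d = t/√n, se = √(1/n + d²/2n)) is a documented convention for
entering one-sample results; d and se may equally be supplied directly.

## The synthetic-data generator

The generator is the package's ground truth, not a tuning knob. Defaults
encode the study conditions: 33 participants × 5 runs, 6 blocks per
condition per run, 14 stimuli per block with 6 or 7 targets; logit intercept
1.153 and task effect 0.768 (population hit rates 0.872 / 0.760); sparse
timing TR 2.8 s / TA 1.6 s with 2–4 TR jitter and sounds centred in the
1.2 s gap; speech-experiment timing at TR 1.6 s with ~17 s blocks; an
MGB-like ellipsoid (~150 mm³ on a 1 mm grid) with planar gradients meeting
at a high-frequency ridge, 130°/300° by default; contrast–behaviour pairs at
planted r = 0.46 for n = 33; and study tables at pooled d = 0.85 with
between-study variance. Where the study does not state a value the default
is a one-time choice of a realistic magnitude, documented here: change-type
and interaction effects 0.2/−0.1 on the logit scale (small, non-null, so all
four terms are exercised); participant random-effect SDs 0.5 (intercept) and
0.25 (slopes) with compound-symmetric 0.3 correlations — ability varies more
than task-specific skill, and the traits are positively related; run SDs 0.1
(little run-to-run drift); reaction times Normal(600 ms, 100 ms) with a
−30 ms speech-task advantage; tonotopy coefficient noise SD 0.3 against a
unit tuning peak.

Tuning curves are triangular with unit peak and one-bin half-width, centred
on the *continuous* planted frequency; the noiseless argmax then equals the
nearest-bin ground truth, and the coefficient centroid reproduces the
continuous field exactly (the property the gradient estimator relies on).
The ramp slope auto-scales so labels span 1..10 across the nucleus; an
explicit steeper slope is rejected when the implied labels leave that range.

What the generator does **not** emulate: fMRI noise spectra (drift,
physiological aliasing, autocorrelation — noise is white Gaussian), head
motion, registration error, voice acoustics, or attentional drift across
runs. Passing tests therefore demonstrate the correctness and calibration of
the *computations* under their stated assumptions, not robustness to every
artefact of real 7T data.

All generators are pure functions of (config, seed): they save and restore
the caller's RNG state, and the pipeline fans a global seed out as
`seed × 100 + stage index`, so a stage's outputs do not depend on which
other stages run.

## Problem sizes and verification scale

The test suite runs the full study size where it matters and reduced sizes
elsewhere, as the package's own verification design: parameter recovery uses
20 replicates at the full 33 × 5 design with 2 chains × 2,000 draws (800
warm-up) per fit — enough for stable 97% HPDs of the fixed effects —
requiring truth inside the interval in ≥ 90% of replicates; permutation-FWE
calibration uses 1,000 null datasets of 12 participants × 8 voxels at 199
permutations; the angle-recovery sweep covers all 72 planted directions at
zero noise; oracle checks (ML τ² against a 10⁻⁴-step likelihood grid and
against an independent meta-analysis implementation, HPD against the normal
quantile oracle, exhaustive sign-flip enumeration against brute force) are
deterministic. `scripts/acceptance.R` recomputes the headline quantities at
these sizes in a few minutes on one CPU.

## Known limitations

* OLS without prewhitening mis-states t-statistic df on strongly
  autocorrelated real time series; use an external prewhitening step first.
* The sampler is random-walk based: posterior correlations of the
  *correlation* parameters mix an order of magnitude slower than the fixed
  effects; quote them only from long chains (the convergence flag reports
  this honestly).
* Gradient angles on raw integer labels (`method = "labels"`) are direction
  quantized; prefer attaching coefficient volumes.
* The parcellation assumes one contiguous ridge per slice; a disconnected
  ridge still splits by nearest ridge column but the boundary is then only
  piecewise meaningful.
* The WAV reader/writer covers mono PCM 16/32-bit and IEEE float — the
  formats stimuli actually use — not the full RIFF zoo.
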