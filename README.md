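# tonothal

Analysis toolbox for ultra-high-field (7T) fMRI studies of the auditory
thalamus. The medial geniculate body (MGB) is the auditory relay of the
thalamus; its ventral division (vMGB) is tonotopically organized and drives
primary auditory cortex. `tonothal` implements the computational pipeline
such studies need to (i) map tonotopy in the MGB with a frequency-encoding
model, (ii) parcellate the nucleus at its high-frequency ridge into gradient
regions, (iii) model one-back task behaviour hierarchically, (iv) relate
task-dependent BOLD modulation to behaviour across participants with
small-volume family-wise-error control, and (v) pool task effects across
experiments by random-effects meta-analysis. A synthetic-data generator
produces every input from known ground truth, so the full pipeline is
testable end to end on a laptop.

## What it computes

**Tonotopy.** Sounds are passed through a bank of 128 overlapping constant-Q
filters (180–7040 Hz, log-spaced), time-averaged, collapsed into 10 of 12
equal-octave bins, z-scored, and convolved with the canonical HRF to form the
encoding design W = [sounds × 10 bins], sampled at the sparse (clustered)
acquisition times (TR 2.8 s, TA 1.6 s). Voxelwise OLS coefficients give each
voxel a best-frequency label b(v) = argmax_k beta_k(v) ∈ {1..10}. In-plane
gradient directions of the best-frequency field are accumulated in 5°
circular histograms (per slice → per participant → group); their two largest
local maxima define the tonotopic gradients, and the per-slice
highest-frequency ridge splits the nucleus into two regions whose centres of
mass and volumes are reported in world mm.

**Behaviour.** Per-trial button presses are Bernoulli with
logit p = A + B_S·task + B_V·change + B_SV·task·change, each coefficient
decomposed into population, participant and run terms; the 4-dimensional
participant and run deviations are MVN with HalfCauchy(2) scale priors and an
LKJ correlation prior. Fitting uses a package-built adaptive
Metropolis-within-Gibbs sampler (C++), with likelihood-invariant translation
and rescaling moves that decorrelate the non-centred parameterization.
Posterior task hit rates are averaged over change types,
p_speech = ½[logit⁻¹(α+β_S) + logit⁻¹(α+β_S+β_V+β_SV)], and summarized with
97% highest-posterior-density intervals. A Student-t variant models
mean-centred reaction times.

**Group statistics.** The across-participant correlation between a contrast
(speech vs speaker task) and behavioural scores is a slope t with df = n−2,
converted to r via r = t/√(t²+df). Family-wise error inside a small mask is
controlled nonparametrically with the max-statistic permutation null
(covariate shuffles, or sign-flips for one-sample contrasts; exhaustive
enumeration when feasible). Correlations are compared with Fisher-z tests
(independent, dependent-overlapping, dependent-nonoverlapping).

**Meta-analysis.** Study effects d_i ~ Normal(mu, tau² + se_i²); tau² is the
maximum-likelihood fixed point, weights w_i ∝ 1/(se_i²+tau²), with Wald CI
and z test (REML optional).

## Worked example

```r
library(tonothal)

## behaviour: simulate a 33-participant study at known truth and refit it
trials <- simulateTrials(behaviorSimConfig(betaV = 0, betaSV = 0, seed = 11))
post   <- fitHitModel(trials, chains = 2, draws = 2000, warmup = 800, seed = 11)
rates  <- taskHitRates(post)
```

With the planted logit intercept 1.153 and task effect 0.768 (population
hit rates 0.872 and 0.760), this prints:

```
speech  0.865 [0.818, 0.907]
speaker 0.754 [0.706, 0.798]
diff    0.110 [0.076, 0.147]
```

i.e. the fitted posterior recovers the planted group hit rates and a ~0.11
speech-task advantage whose 97% HPD excludes zero. (Short demonstration
chains can flag slow-mixing correlation parameters via split-Rhat; fixed
effects converge quickly, and longer chains clear the flag.)

```r
## tonotopy: two planted gradients at 130 and 300 degrees
sim  <- simulateTonotopyVolumes(tonotopySimConfig(noiseSd = 0))
bmap <- bestFrequency(sim$coefficients[[1]], sim$mask, sim$affine)
histogramMaxima(gradientHistogram(bmap), k = 2)
#> [1] 130 300
parcellate(bmap)
#> GradientParcellation
#>   region 1: COM (0.0, 0.6, -1.1) mm, volume 70.00 mm^3
#>   region 2: COM (0.0, -0.5, 1.2) mm, volume 72.00 mm^3
#>   ridge: 26.00 mm^3
```

The gradient-angle histogram peaks exactly at the planted angles, and the
ridge parcellation returns two MGB-scale regions (tens of mm³).

An end-to-end demonstration (`runPipeline(outDir, seed = 1)`) chains all
stages — behaviour, tonotopy, localizer GLM, group correlation with
permutation SVC, meta-analysis — and writes a manifest of outputs with MD5
hashes and per-stage seeds. A thin CLI wraps the same functions:
`inst/scripts/tonothal simulate|features|glm|tonotopy|behavior|correlate|meta|run`.

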