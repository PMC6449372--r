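---
title: "Methods: models, estimators and synthetic ground truth in wakewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and synthetic ground truth in wakewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wakewatch)
```

# The scientific problem

Man-made structures in strong tidal channels shed a downstream wake — often
a von Kármán vortex street — that concentrates surface-foraging seabirds
such as terns. Quantifying that association requires four quite different
measurement chains: overhead video of birds over the wake, acoustic Doppler
current profiler (ADCP) transects through the wake, shore-based foraging
counts over the tidal cycle, and a transport model for the prey supply.
`wakewatch` implements all four chains as testable R functions, together
with seeded synthetic-data generators that produce every input class with
known ground truth. All quantitative claims in this vignette are computed
by the package's test suite or by `scripts/acceptance.R`; nothing here is
asserted from memory of real field data.

# Synthetic data as the test harness

Each generator is a study-condition statement, not a tuning knob: its
defaults encode either a published protocol value (806 training chips per
class; counts every 2nd/3rd minute for 15 minutes with a 5-minute rest; a
12.4-h semidiurnal cycle; 1-m ADCP bins on a 1.15-m pole mount; 200
particles per 5-minute release step; vertical dispersion 0.01 m²/s) or a
value chosen once as field-realistic and then left alone.

## Overhead video (`generateWakeVideo`)

The scene model is deliberately minimal: a static mid-grey sea surface with
smooth spatial texture; birds as compact bright Gaussian blobs
(σ = `birdSizePx`/3, contrast 0.35) flying correlated random walks at
constant speed; foam as larger fractal-textured patches with a soft
envelope, shed periodically on alternating sides of the wake midline and
advecting downstream at the channel speed (default 5 m/s, consistent with a
>5 m/s tidal race); and sun glint as 1–2 px single-frame speckles. The
alternating-side shedding at a default 12 eddies per minute (the midpoint
of the 10–14 min⁻¹ range characteristic of such wakes) gives the scene a
genuine vortex-street signature that the tracking chain must recover.

The correlated random walk draws wrapped-normal turning angles with
standard deviation `sqrt(2 log S)` per step for a sinuosity target `S`; this
is a heuristic mapping (exact only in expectation for small angles) and is
treated as such — tests assert the step-length contract and reproducibility,
not the mapping itself. Ground truth lists every rendered object in every
frame, so detection recall and tracking error are measured exactly.

What the scene model deliberately omits: photorealistic water, wave motion,
bird appearance changes (banking, plunge postures), species differences, and
camera motion. Passing tests therefore demonstrate that the algorithms are
correct and well-calibrated on data matching their assumptions — not that
the fixed thresholds would transfer to real 4K footage unchanged.

## Foraging counts (`generateSurveyCounts`)

Counts follow a hurdle process. Presence is Bernoulli with logit-scale
linear predictor `intercept + a sin(2πt/T) + b cos(2πt/T)` per site plus
AR1-correlated latent noise within each survey; positive counts are
zero-truncated negative binomial with a log-scale mean of the same form and
dispersion θ. The first-harmonic parameterisation makes the truth
basis-independent: any cyclic smoother can represent it, so recovery tests
do not hinge on matching spline bases. The latent AR1 (default ρ = 0.4,
sd 0.8) is injected on the link scale of the presence process, matching the
usual treatment of serial correlation "within locations"; it spans block
boundaries within a survey, which is how the fitting side treats surveys
too. Sampling of the truncated distribution uses the inverse-CDF on
`[P(0), 1)`, exact for any θ including the Poisson limit θ → ∞.

## ADCP transects (`generateADCPTransect`)

The true cross-stream speed profile is
`u(y) = U (1 − f·W(y))` with `W` a Gaussian bump whose full width at half
maximum *is* the configured `deficitWidth` (default 45 m, fraction
f = 0.5, U = 5 m/s), so the half-maximum extent estimator has an exact
target. The wake's elevated backscatter (default +10 dB, uniform over the
water column as a bubble plume would be) is injected through the inverse of
the sonar equation's count term — anomaly divided by the RSSI scale Kc — so
converting the synthetic counts back through `computeSv` must return the
anomaly to within 0.1 dB in the noiseless case. Echo counts are stored as
real numbers; quantisation to integer counts would add ±0.5 count
(≈0.2 dB) of rounding noise that the round-trip contract excludes.
Bottom-track velocity is stored as the instrument reports it (the apparent
seabed velocity, i.e. minus the boat velocity), so the correction is a
plain subtraction.

## Channel flow (`generateFlowField`)

A steady log-law profile `u(h) = (u*/κ) ln(h/z0)` over height-above-bed
`h ∈ [z0, depth]`, clipped at zero and clamped to `h = z0` below the
roughness length. Horizontal dispersion is `scaling × baseDh` with the
conventional scaling constant 1.0; vertical dispersion is the constant
0.01 m²/s.

# The analysis chain

## Detection (`frameDifference`, `segmentMask`, `sizeFilter`, `detectTargets`)

Differencing uses consecutive frames only (no background model), an
absolute threshold, and an optional 3×3 morphological opening that
suppresses single-pixel glint. Segmentation is 8-connected (components via
the pixel-adjacency graph) with exact pixel-count areas and
intensity-weighted centroids. The size filter keeps areas in
`[0.25, 4] × birdSizePx²` by default.

Two practical refinements live in `detectTargets`, both documented because
they are where a naive differencing pipeline fails: a moving blob marks the
mask twice (leading and trailing crescents), so (1) components whose mean
intensity sits at background level are dropped (`brightOnly`), and (2) each
surviving detection is re-localised at the brightness-weighted centroid of
the current frame in a small window, after which near-duplicate detections
merge. On noiseless scenes this brings per-frame position error below half
a pixel, which the tracker tests rely on. Foam, being large, bright and
persistent, is detected separately by `detectSurfaceFeatures` — Gaussian
smoothing, intensity thresholding, and a large-area filter — rather than by
differencing.

## Bag-of-features classification (`computeDescriptors` … `evaluateClassifier`)

Chips are 32-px squares normalised to [0, 1]. Descriptors are dense
magnitude-weighted gradient-orientation histograms (8 signed bins) pooled
over two patch scales (8 px / stride 4 and 16 px / stride 8), each
L2-normalised; the two scales separate smooth blob-like terns from rough
foam texture better than either alone, and the descriptor grid is centred
so a 180° chip rotation permutes orientation bins by exactly half a turn —
a property the tests exploit. The vocabulary is k-means (k = 200,
k-means++ seeding, fixed seed, Lloyd iterations capped) and chips encode as
L1-normalised hard-assignment histograms; a degenerate (constant) chip
encodes as the uniform histogram and is flagged. The classifier is a linear
soft-margin SVM (cost C = 1) on the histograms. The descriptor, k, and
classifier family are design choices — the field's standard "bag of
features" recipe — since only the recipe name and the training balance (806
chips per class) are protocol facts. Accuracy is reported as the macro
(per-class mean) percentage, matching a class-balanced training design.

## Tracking (`kalmanStep`, `associateDetections`, `compileTracks`)

A constant-velocity Kalman filter with white-acceleration process noise
(default q = 1 m²/s³) and isotropic observation noise (default
r = 0.25 m). Association is the globally cost-minimal one-to-one
assignment (an O(n³) Hungarian solver, verified against brute-force
permutation minima) on gated Euclidean distances; unmatched detections
spawn tracks and tracks close after `maxMisses` (default 5) consecutive
misses. The duration filter is strictly greater-than ("over 2 s"), and
sinuosity is the path/chord ratio with the degenerate zero-chord case
flagged as infinite. Shedding frequency counts distinct foam tracks
crossing a fixed cross-stream line — once per track identity, however many
times a track re-crosses — divided by the observation time.

## ADCP processing (`computeSv`, `correctVelocity`, `gridSection`, `wakeDeficitExtent`)

The working sonar equation per beam and bin is

    Sv = C + 10 log10((Tx + 273.16) R²) − 10 log10(L) − P_DBW + 2αR + Kc (E − Er)

with slant range `R = (B + (L+D)/2 + (n−1)D + D/4)/cos(θ)`, water
absorption α from the Ainslie–McColm (1998) seawater model (the absorption
model is a package choice, recorded in the profile flags, since the sonar
equation's sources do not fix one), and a 40-bin processing cap. `Sv_max`
is the per-bin maximum over the four beams. Instrument constants default to
Workhorse-600-class values (C = −139.3 dB, Kc = 0.45 dB/count,
Er = 40 counts, 9 dBW) and must be overridden with unit calibrations for
real data; every test that carries scientific weight (count linearity,
round trips) is constant-free. Counts below the noise floor still convert
(a negative contribution) but flag the profile.

Sections are bin-averages on a regular (y, z) grid with per-cell sample
counts retained. The deficit extent estimator depth-averages the speed,
takes the reference as the mean of the outer 20% of the cross-stream
profile (10% from each end) unless supplied, and measures the width of the
contiguous interval around the deficit peak where the deficit exceeds the
configured fraction of its maximum, linearly interpolating the crossings; a
deficit-free profile returns 0 with a warning.

## Hurdle model (`fitPresence`, `fitAbundance`, `predictHurdle`, `termFTest`)

The model is the standard hurdle decomposition: a binomial part for
P(count > 0) and a zero-truncated negative binomial for the positives, fit
independently — their log-likelihoods add exactly to the full hurdle
likelihood, an identity the tests assert. Both parts share one design:
site intercepts plus a per-site cyclic cubic smooth of tidal state on six
evenly spaced knots over the 12.4-h cycle (sum-to-zero constrained, built
with `mgcv::smoothCon`, four free coefficients per smooth).

*Presence.* Penalized IRLS. Smoothing parameters (one per site smooth) are
selected by a Laplace-approximate REML criterion on the independence fit;
the implementation agrees with an `mgcv::gam` REML fit of the same model to
within 10⁻² on the probability scale, which the tests check as an
independent cross-validation of the machinery. Serial correlation is then
handled GEE-style: the AR1 correlation is estimated from lag-1 working
residuals within surveys and the penalized normal equations are re-solved
with AR1-whitened rows, iterating to a 10⁻⁶ fixed point (at most 10
cycles). Smoothing parameters are not re-estimated inside the AR1 loop;
re-deriving REML under the working correlation would add complexity far in
excess of its effect at these smoothing levels. Complete separation within
a site is flagged and absorbed by the ridge component of the penalty.

*Abundance.* mgcv has no zero-truncated negative-binomial family, so this
part is fit by direct penalized maximum likelihood: analytic gradient in
(β, log θ), BFGS, a single shared smoothing parameter selected by the same
Laplace criterion with the observed information approximated from finite
differences of the analytic score. AR1 handling mirrors the presence part,
using the truncated distribution's mean and variance for the working model
and re-profiling θ each cycle. The coefficient covariance is the Bayesian
(penalized observed-information) inverse in both parts.

*Inference.* `termFTest` forms a Wald-type F statistic for a coefficient
block — site-intercept differences for "among sites", a smooth's four
coefficients for a tidal effect — in the Bayesian covariance, with
denominator df equal to n minus the model's effective df. Under a null
simulation its size is within two standard errors of the nominal 0.05
(asserted over 500 replicates at fixed smoothing, which isolates the test's
calibration from smoothing-parameter noise). Predictions map link-scale
estimates and standard errors through the inverse links; the abundance
prediction is the truncated mean μ/(1 − P0) with a delta-method SE.

*Recovery criterion.* Raw smooth coefficients are not estimable (they
depend on identifiability constraints), so "parameter recovery" is checked
on estimable functionals: the fitted linear predictor is projected onto the
constant, sine and cosine harmonics of the cycle — exactly the quantities
the generator draws — each a linear functional of the coefficients with an
exact SE. Over 100 replicates at roughly 2 000 observation-minutes per site
(ρ = 0), at least 95% of the 3-SE intervals must cover the truth; nominal
coverage of a 3-SE interval is 99.7%, so the bound is demanding but fair to
an honestly calibrated fit.

*Tidal bins.* Eight equal states of a 12.4-h cycle are 1 h 33 min wide.
(Quoting eight states as "1 h 20 min" would imply a 10 h 40 min cycle; the
package keeps the bin count configurable and the width period-consistent.)

## Particle transit (`stepParticles`, `runRelease`, `transitSummary`)

Euler–Maruyama integration of the Langevin update
`x += u(x,z) dt + sqrt(2 Dh dt) ξ`, `z += sqrt(2 Dv dt) ξ` with a default
5-s step, mirror reflection at the surface and bed, and first-crossing
arrival times interpolated linearly within the step to avoid dt-granular
bias. The trickle release emits a batch at 0, 5, …, up to and including the
end of the flood window (a 70-minute window gives 15 events). Exact
invariants — particle-count conservation and containment in [0, depth] —
are asserted at every step, and the diffusion law Var(z) = 2 Dv t is
recovered from a 10-point variance-growth regression within 10%. The
flood-only gate is a window length, not a tidal-harmonic model, and the
horizontal dispersion accepts any constant (a full eddy-viscosity field
from a hydrodynamic model is out of scope).

# Orchestration and reproducibility

`runPipeline()` executes the simulate→detect→track, ADCP, hurdle and
transit chains from a nested-list or YAML configuration (an annotated
example ships in `inst/extdata/pipeline-example.yaml`), writes CSV/JSON
outputs and a manifest of md5-hashed files. Per-stage seeds are derived
from the global seed and the stage *name* via an md5 hash, so adding or
reordering stages cannot silently shift another stage's random stream;
identical configuration and seed give identical output hashes. All
randomness everywhere flows through R's RNG under explicit seeds; every
generator is bit-reproducible. The package's only file formats are plain
text (PNG frames aside): frames as 8-bit PNG with a JSON sidecar,
detections/tracks/counts/ensembles/sections as documented CSV schemas.

# Problem sizes

The shipped test and acceptance runs use desk-scale problem sizes chosen as
the package's own defaults: 32-px chips with 806 training and 1 600
validation chips per class; a five-minute 120×180-px vortex-street scene at
5 fps for shedding recovery; a 201-ping, 20-bin transect for the wake
section; two-site surveys of ≈2 000 observation-minutes per site for
recovery studies (100 replicates) and ≈600-minute null datasets for size
studies (500 replicates); 10⁴ particles for the diffusion law. These sizes
put Monte-Carlo error well inside every stated tolerance.

# Known limitations

* The scene generator's appearance model is schematic; classifier accuracy
  on it calibrates the pipeline, not real-world performance.
* Default ADCP instrument constants are class-typical, not calibrated;
  absolute Sv from defaults is only internally comparable.
* The AR1 treatment is a working-correlation approximation, not a full
  mixed-model likelihood; its rho estimate is attenuated on the response
  scale for binary data (tests assert ordering, not equality, of rho).
* The transit simulator is 1-D horizontal over a steady profile; it cannot
  reproduce a real lough's transit time, which depends on a full
  hydrodynamic model.
* `binTidalState` and the cyclic basis assume a fixed 12.4-h period; real
  tidal series with mixed constituents need external phase assignment.
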