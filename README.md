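# wakewatch

Tools for quantifying how the wake of a man-made tidal structure creates a
predictable seabird foraging hotspot. The package implements the full
analysis chain used in fine-scale studies of tern foraging over
tidal-turbine wakes, plus seeded synthetic-data generators with attached
ground truth so every stage is testable end to end without field data:

* **Video detection** — frame-to-frame differencing, 8-connected
  segmentation, size filtering, and chip extraction from overhead
  (UAV-style) image sequences.
* **Bag-of-features classification** — dense gradient-orientation
  descriptors over two patch scales, a k-means visual vocabulary,
  L1-normalised histogram encoding, and a linear SVM separating terns from
  foam.
* **Kalman multi-target tracking** — constant-velocity filtering with
  globally optimal (Hungarian) gated association, a strict "over 2 s"
  duration filter, trajectory metrics (speed, turning, sinuosity =
  path/chord), and surface-eddy shedding-frequency estimation from foam
  tracks crossing a fixed line.
* **ADCP processing** — the working sonar equation converting raw echo
  intensity to volume backscatter `Sv` (with Ainslie–McColm water
  absorption and a 40-bin cap), `Sv_max` across the four beams,
  bottom-track velocity correction, cross-stream section gridding, and a
  half-maximum estimator of the wake velocity-deficit extent.
* **Hurdle count models** — a binomial part for the probability of
  encountering foraging terns and a zero-truncated negative binomial for
  their number when encountered, each with site intercepts and per-site
  cyclic cubic smooths of tidal state (6 knots over a 12.4-h cycle),
  AR1-aware GEE-style inference, predictions with standard errors, and
  Wald-type term F tests.
* **Langevin particle transit** — trickle releases advected through a
  log-law channel flow with Gaussian dispersion (`x += u dt + sqrt(2 D dt) ξ`),
  reflecting boundaries, and first-crossing transit-time statistics.

The core model in the count chain is the two-part hurdle

> P(N = 0) = 1 − p,  P(N = n) = p · NB(n; μ, θ) / (1 − NB(0; μ, θ)) for n ≥ 1,
>
> logit(p) = α_s + f_s(t),  log(μ) = β_s + g_s(t),

with `s` the site, `t` hours after high water, and `f_s`, `g_s` cyclic
cubic splines; the sonar equation in the acoustic chain is

> Sv = C + 10 log₁₀((Tx + 273.16) R²) − 10 log₁₀(L) − P_DBW + 2αR + Kc (E − Er).

## Worked example

```r
library(wakewatch)

## simulate an overhead scene with 3 terns, detect and track them
cfg <- sceneConfig(duration = 20, nFoamPatches = 0L, sheddingFrequency = 0,
                   seed = 1L)
scene <- generateWakeVideo(cfg)
scene$frames
#> FrameSequence: 100 frames of 180 x 240 px, 5 fps, gsd 0.5 m/px (20.0 s)

detections <- detectTargets(scene$frames, diffThreshold = 0.05)
tracks <- filterTracksByDuration(
  compileTracks(detections, fps = frameRate(scene$frames),
                scale = groundSampleDistance(scene$frames), gateRadius = 3), 2)
trackSetMetrics(tracks)[, c("track_id", "duration", "mean_speed", "sinuosity")]
#>   track_id duration mean_speed sinuosity
#> 1        1     19.6       3.94      3.19
#> 2        2      8.0       3.97      2.55
#> 3        3     19.6       4.22     11.52
#> 4        4     10.4       3.88      1.96
```

The three birds fly at a true 4 m/s with sinuous search paths; the tracker
recovers their speeds within a few percent. One bird's track fragments into
tracks 2 and 4 where two birds pass within a blob diameter of each other —
their detections merge for a few frames, the track exceeds its miss budget,
and a new identity spawns once they separate.

```r
## train the tern-vs-foam chip classifier at protocol scale
train <- c(generateChips(806, "tern", seed = 101),
           generateChips(806, "foam", seed = 102))
model <- trainBoF(train, rep(c("tern", "foam"), each = 806), k = 200, seed = 11)
val <- c(generateChips(1600, "tern", seed = 103),
         generateChips(1600, "foam", seed = 104))
report <- evaluateClassifier(model, val, rep(c("tern", "foam"), each = 1600))
report$confusion
#>          truth
#> predicted foam tern
#>      foam 1494   22
#>      tern  106 1578
sprintf("macro accuracy: %.1f%%", report$averageAccuracy)
#> [1] "macro accuracy: 96.0%"

## ADCP: recover the wake's cross-stream extent from a synthetic transect
adcp <- generateADCPTransect(adcpSimConfig(seed = 1L))
section <- gridSection(adcp$transect, yBin = 2)
wakeDeficitExtent(section)      # true full width at half maximum: 45 m
#> [1] 44.5

## hurdle model of foraging counts over tidal state
survey <- generateSurveyCounts(surveyConfig(seed = 1L))
fit <- fitHurdle(survey$counts)
fit
#> HurdleFit: 4 sites, cyclic tidal smooth (6 knots, period 12.40 h)
#>   presence: n = 1819, AR1 rho = 0.042
#>   abundance: n = 790 positives, theta = 1.51, AR1 rho = 0.020
termFTest(fit, "s(tide):StructureNorth", "presence")
#>                     term     part     F df_num df_den         p
#> 1 s(tide):StructureNorth presence 13.57      4   1807 6.653e-11
```

The F test confirms a strong tidal dependence of encounter probability at
the structure's north (flood-wake) site — the generator's steepest cyclic
effect — and `predictHurdle(fit, "StructureNorth", seq(0, 12.39, 0.1))`
returns the predicted encounter probability and expected positive count
across the tidal cycle with standard errors.

End-to-end runs (simulate → detect → track; ADCP; hurdle; transit) are
orchestrated by `runPipeline()`; an annotated YAML configuration ships in
`inst/extdata/pipeline-example.yaml`.

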