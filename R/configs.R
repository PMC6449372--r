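#' SceneConfig: parameters of the synthetic overhead-video generator
#'
#' Defaults emulate a hover survey over a structure's flood wake: a textured
#' sea surface, a handful of terns rendered as compact bright blobs flying
#' correlated random walks, large deforming foam patches shed periodically on
#' alternating sides of the wake midline (a von Karman vortex-street
#' signature) and advecting downstream, and single-frame sun-glint speckles.
#'
#' @slot frameSize integer (rows, cols) in pixels.
#' @slot fps frames per second.
#' @slot duration seconds.
#' @slot gsd ground-sample distance, m per pixel.
#' @slot nBirds number of birds.
#' @slot birdSizePx nominal bird diameter, px.
#' @slot birdSpeed flight speed, m/s.
#' @slot birdSinuosity path/chord ratio target, >= 1.
#' @slot nFoamPatches ambient foam patches (in addition to shed eddies).
#' @slot foamSizePx nominal foam diameter, px (should exceed `birdSizePx`).
#' @slot glintRate expected glint speckles per frame.
#' @slot advectionSpeed surface advection of foam, m/s.
#' @slot sheddingFrequency eddies shed per minute.
#' @slot seed RNG seed.
#' @export
setClass("SceneConfig",
  representation(frameSize = "integer", fps = "numeric", duration = "numeric",
                 gsd = "numeric", nBirds = "integer", birdSizePx = "numeric",
                 birdSpeed = "numeric", birdSinuosity = "numeric",
                 nFoamPatches = "integer", foamSizePx = "numeric",
                 glintRate = "numeric", advectionSpeed = "numeric",
                 sheddingFrequency = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@fps <= 0) return("fps must be > 0")
    if (object@duration <= 0) return("duration must be > 0")
    if (object@birdSizePx >= object@foamSizePx)
      return("birdSizePx must be < foamSizePx")
    if (object@sheddingFrequency < 0) return("sheddingFrequency must be >= 0")
    if (object@birdSinuosity < 1) return("birdSinuosity must be >= 1")
    TRUE
  })

#' Construct a SceneConfig
#'
#' @param frameSize (rows, cols) px.
#' @param fps frames per second.
#' @param duration seconds.
#' @param gsd m per pixel.
#' @param nBirds,birdSizePx,birdSpeed,birdSinuosity bird appearance/motion.
#' @param nFoamPatches,foamSizePx ambient foam.
#' @param glintRate expected speckles per frame.
#' @param advectionSpeed surface advection, m/s.
#' @param sheddingFrequency eddies per minute crossing the wake (default 12,
#'   midpoint of the 10-14 per minute range typical of such wakes).
#' @param seed RNG seed.
#' @return a [SceneConfig-class]
#' @export
sceneConfig <- function(frameSize = c(180L, 240L), fps = 5, duration = 20,
                        gsd = 0.5, nBirds = 3L, birdSizePx = 6,
                        birdSpeed = 4, birdSinuosity = 1.3,
                        nFoamPatches = 3L, foamSizePx = 24, glintRate = 5,
                        advectionSpeed = 5, sheddingFrequency = 12,
                        seed = 1L) {
  new("SceneConfig", frameSize = as.integer(frameSize), fps = fps,
      duration = duration, gsd = gsd, nBirds = as.integer(nBirds),
      birdSizePx = birdSizePx, birdSpeed = birdSpeed,
      birdSinuosity = birdSinuosity, nFoamPatches = as.integer(nFoamPatches),
      foamSizePx = foamSizePx, glintRate = glintRate,
      advectionSpeed = advectionSpeed, sheddingFrequency = sheddingFrequency,
      seed = as.integer(seed))
}

#' SurveyConfig: parameters of the synthetic foraging-count generator
#'
#' Counts follow the shore-based vantage-point protocol: counts every
#' `countInterval` minutes for `blockLength` minutes, then a `restLength`
#' minute pause, repeated until the survey length is reached. The underlying
#' process is a hurdle: presence is Bernoulli on the logit scale with a
#' per-site intercept, a per-site cyclic tidal effect and AR1-correlated
#' latent noise; positive counts are zero-truncated negative binomial with a
#' log-scale site + cyclic tidal mean.
#'
#' Per-site cyclic effects are parameterised as first-harmonic sinusoids,
#' `a * sin(2*pi*tide/period) + b * cos(2*pi*tide/period)`, so the truth is
#' basis-independent and recoverable by any cyclic smoother.
#'
#' @slot sites character site labels.
#' @slot countInterval minutes between counts within a block (2 or 3).
#' @slot blockLength minutes of counting per block (15).
#' @slot restLength rest minutes between blocks (5).
#' @slot surveyLengthMean mean survey length, minutes.
#' @slot nSurveys surveys per site.
#' @slot tidalPeriod hours (12.4, semidiurnal M2).
#' @slot presenceCoefs matrix sites x (intercept, a, b) on the logit scale.
#' @slot abundanceCoefs matrix sites x (intercept, a, b) on the log scale.
#' @slot nbDispersion negative-binomial theta > 0.
#' @slot ar1Rho latent AR1 correlation, |rho| < 1.
#' @slot latentSd sd of the latent AR1 noise on the logit scale.
#' @slot seed RNG seed.
#' @export
setClass("SurveyConfig",
  representation(sites = "character", countInterval = "numeric",
                 blockLength = "numeric", restLength = "numeric",
                 surveyLengthMean = "numeric", nSurveys = "integer",
                 tidalPeriod = "numeric", presenceCoefs = "matrix",
                 abundanceCoefs = "matrix", nbDispersion = "numeric",
                 ar1Rho = "numeric", latentSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nbDispersion <= 0) return("nbDispersion (theta) must be > 0")
    if (abs(object@ar1Rho) >= 1) return("|ar1Rho| must be < 1")
    if (nrow(object@presenceCoefs) != length(object@sites) ||
        nrow(object@abundanceCoefs) != length(object@sites))
      return("coefficient matrices must have one row per site")
    if (object@blockLength <= 0 || object@restLength < 0 ||
        object@countInterval <= 0)
      return("block/rest/interval must be positive")
    TRUE
  })

#' Construct a SurveyConfig
#'
#' Default sites and effect sizes emulate four tidal-channel sites of which
#' one (the structure's north wake) has both high encounter probability and
#' strong tidal dependence.
#'
#' @param sites site labels.
#' @param countInterval,blockLength,restLength protocol minutes (counts every
#'   2-3 min for 15 min with a 5 min rest).
#' @param surveyLengthMean mean survey length in minutes (129).
#' @param nSurveys surveys per site.
#' @param tidalPeriod hours after high water wrap, default 12.4.
#' @param presenceCoefs,abundanceCoefs sites x 3 matrices (intercept,
#'   sin, cos); defaults give site-varying intercepts and tidal amplitude.
#' @param nbDispersion NB theta.
#' @param ar1Rho latent AR1 correlation.
#' @param latentSd latent noise sd (logit scale).
#' @param seed RNG seed.
#' @return a [SurveyConfig-class]
#' @export
surveyConfig <- function(sites = c("StructureNorth", "StructureSouth",
                                   "RoutenWheel", "WaltersRock"),
                         countInterval = 2.5, blockLength = 15,
                         restLength = 5, surveyLengthMean = 129,
                         nSurveys = 11L, tidalPeriod = 12.4,
                         presenceCoefs = NULL, abundanceCoefs = NULL,
                         nbDispersion = 1.5, ar1Rho = 0.4, latentSd = 0.8,
                         seed = 1L) {
  ns <- length(sites)
  if (is.null(presenceCoefs)) {
    presenceCoefs <- cbind(intercept = seq(1.0, -1.5, length.out = ns),
                           a = seq(1.2, 0.2, length.out = ns),
                           b = seq(-0.8, 0.3, length.out = ns))
    rownames(presenceCoefs) <- sites
  }
  if (is.null(abundanceCoefs)) {
    abundanceCoefs <- cbind(intercept = seq(1.6, 0.4, length.out = ns),
                            a = seq(0.8, 0.1, length.out = ns),
                            b = seq(-0.5, 0.2, length.out = ns))
    rownames(abundanceCoefs) <- sites
  }
  new("SurveyConfig", sites = sites, countInterval = countInterval,
      blockLength = blockLength, restLength = restLength,
      surveyLengthMean = surveyLengthMean, nSurveys = as.integer(nSurveys),
      tidalPeriod = tidalPeriod, presenceCoefs = presenceCoefs,
      abundanceCoefs = abundanceCoefs, nbDispersion = nbDispersion,
      ar1Rho = ar1Rho, latentSd = latentSd, seed = as.integer(seed))
}

#' InstrumentConfig: ADCP instrument constants for the sonar equation
#'
#' Defaults describe a 600 kHz Workhorse-class broadband profiler deployed on
#' a 1.15 m pole mount with 1 m vertical bins. The instrument constant `C`,
#' RSSI scale `Kc` and noise floor `Er` vary by unit and must be overridden
#' with calibration values when converting real data.
#'
#' @slot frequency kHz.
#' @slot beamAngle degrees from vertical.
#' @slot binSize m.
#' @slot blank m (blanking distance).
#' @slot pulseLength m.
#' @slot powerDbw transmit power, dB re 1 W.
#' @slot instrumentConstant instrument constant C, dB.
#' @slot Kc RSSI scale, dB per count (per beam; scalar or per-beam vector).
#' @slot Er noise floor, counts (scalar or per-beam vector).
#' @slot transducerDepth m below surface.
#' @slot maxBins bins processed (40).
#' @export
setClass("InstrumentConfig",
  representation(frequency = "numeric", beamAngle = "numeric",
                 binSize = "numeric", blank = "numeric",
                 pulseLength = "numeric", powerDbw = "numeric", instrumentConstant = "numeric",
                 Kc = "numeric", Er = "numeric", transducerDepth = "numeric",
                 maxBins = "integer"),
  validity = function(object) {
    if (any(object@Kc <= 0)) return("Kc must be > 0")
    if (object@binSize <= 0) return("binSize must be > 0")
    if (object@beamAngle <= 0 || object@beamAngle >= 90)
      return("beamAngle must be in (0, 90)")
    TRUE
  })

#' Construct an InstrumentConfig
#'
#' @param frequency kHz (600).
#' @param beamAngle degrees (20).
#' @param binSize vertical bin size, m (1).
#' @param blank blanking distance, m.
#' @param pulseLength transmit pulse length, m (defaults to bin size).
#' @param powerDbw transmit power, dB re 1 W.
#' @param C instrument constant, dB (typical Workhorse-class value; override
#'   with the unit's calibration).
#' @param Kc RSSI scale, dB/count.
#' @param Er noise floor, counts.
#' @param transducerDepth m (1.15 for a pole mount).
#' @param maxBins number of bins converted (40).
#' @return an [InstrumentConfig-class]
#' @export
instrumentConfig <- function(frequency = 600, beamAngle = 20, binSize = 1,
                             blank = 0.88, pulseLength = binSize,
                             powerDbw = 9, C = -139.3, Kc = 0.45, Er = 40,
                             transducerDepth = 1.15, maxBins = 40L) {
  new("InstrumentConfig", frequency = frequency, beamAngle = beamAngle,
      binSize = binSize, blank = blank, pulseLength = pulseLength,
      powerDbw = powerDbw, instrumentConstant = C, Kc = Kc, Er = Er,
      transducerDepth = transducerDepth, maxBins = as.integer(maxBins))
}

#' ADCPSimConfig: parameters of the synthetic wake-transect generator
#'
#' @slot nBins bins per ensemble.
#' @slot instrument an [InstrumentConfig-class].
#' @slot transectSpan cross-stream span, m (ensembles from -span/2 to span/2).
#' @slot pingSpacing m between ensembles along the transect.
#' @slot deficitCenter m.
#' @slot deficitWidth full width at half maximum of the deficit, m.
#' @slot deficitFraction peak fractional velocity deficit, \[0, 1\].
#' @slot wakeSvAnomaly backscatter anomaly at the wake centre, dB.
#' @slot upstreamSpeed m/s.
#' @slot noiseSdVelocity m/s.
#' @slot noiseSdCounts counts.
#' @slot temperature deg C.
#' @slot salinity PSU.
#' @slot boatSpeed m/s along the transect.
#' @slot seed RNG seed.
#' @export
setClass("ADCPSimConfig",
  representation(nBins = "integer", instrument = "ANY",
                 transectSpan = "numeric", pingSpacing = "numeric",
                 deficitCenter = "numeric", deficitWidth = "numeric",
                 deficitFraction = "numeric", wakeSvAnomaly = "numeric",
                 upstreamSpeed = "numeric", noiseSdVelocity = "numeric",
                 noiseSdCounts = "numeric", temperature = "numeric",
                 salinity = "numeric", boatSpeed = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@deficitFraction < 0 || object@deficitFraction > 1)
      return("deficitFraction must be in [0, 1]")
    if (object@deficitWidth >= object@transectSpan)
      return("deficitWidth must be < transectSpan")
    TRUE
  })

#' Construct an ADCPSimConfig
#'
#' Defaults mirror the study conditions: a near-laminar ~5 m/s upstream flow
#' with a mid-channel wake whose velocity deficit has a 45 m cross-stream
#' full width at half maximum and a peak fractional deficit of 0.5, plus an
#' elevated-backscatter signature in the wake.
#'
#' @param nBins bins (20 of 1 m in a ~20 m channel).
#' @param instrument an [InstrumentConfig-class].
#' @param transectSpan,pingSpacing transect geometry, m.
#' @param deficitCenter,deficitWidth,deficitFraction wake deficit truth.
#' @param wakeSvAnomaly dB at wake centre.
#' @param upstreamSpeed m/s.
#' @param noiseSdVelocity,noiseSdCounts Gaussian noise levels.
#' @param temperature,salinity water properties.
#' @param boatSpeed transect boat speed, m/s.
#' @param seed RNG seed.
#' @return an [ADCPSimConfig-class]
#' @export
adcpSimConfig <- function(nBins = 20L, instrument = instrumentConfig(),
                          transectSpan = 200, pingSpacing = 1,
                          deficitCenter = 0, deficitWidth = 45,
                          deficitFraction = 0.5, wakeSvAnomaly = 10,
                          upstreamSpeed = 5, noiseSdVelocity = 0.1,
                          noiseSdCounts = 2, temperature = 14,
                          salinity = 34, boatSpeed = 2, seed = 1L) {
  new("ADCPSimConfig", nBins = as.integer(nBins), instrument = instrument,
      transectSpan = transectSpan, pingSpacing = pingSpacing,
      deficitCenter = deficitCenter, deficitWidth = deficitWidth,
      deficitFraction = deficitFraction, wakeSvAnomaly = wakeSvAnomaly,
      upstreamSpeed = upstreamSpeed, noiseSdVelocity = noiseSdVelocity,
      noiseSdCounts = noiseSdCounts, temperature = temperature,
      salinity = salinity, boatSpeed = boatSpeed, seed = as.integer(seed))
}

#' Construct a FlowFieldConfig and build the flow field
#'
#' See [FlowField-class]. The horizontal dispersion is
#' `scaling * baseDh`; the default scaling of 1.0 follows standard
#' hydrodynamic-model practice for scaled eddy viscosity, and the default
#' vertical dispersion is a constant 0.01 m^2/s.
#'
#' @param channelLength m (domain length; stored in meta by callers).
#' @param waterDepth m.
#' @param ustar bed friction velocity, m/s.
#' @param z0 roughness length, m.
#' @param kappa von Karman constant.
#' @param scaling horizontal eddy-viscosity scaling (1.0).
#' @param baseDh unscaled horizontal dispersion, m^2/s.
#' @param Dv vertical dispersion, m^2/s (0.01).
#' @return arguments for [generateFlowField()] as a named list
#' @export
flowFieldConfig <- function(channelLength = 3000, waterDepth = 20,
                            ustar = 0.2, z0 = 0.005, kappa = 0.41,
                            scaling = 1.0, baseDh = 0.01, Dv = 0.01) {
  list(channelLength = channelLength, waterDepth = waterDepth, ustar = ustar,
       z0 = z0, kappa = kappa, scaling = scaling, baseDh = baseDh, Dv = Dv)
}

#' ReleaseSchedule: trickle-release plan for particle transit runs
#'
#' @slot particlesPerStep particles per release event (200).
#' @slot stepMin minutes between releases (5).
#' @slot activeWindowMin length of the active (flood) window, minutes;
#'   releases occur at 0, step, ..., up to and including the window end.
#' @slot releaseX release x, m.
#' @slot releaseZ release depth, m below surface (10).
#' @export
setClass("ReleaseSchedule",
  representation(particlesPerStep = "integer", stepMin = "numeric",
                 activeWindowMin = "numeric", releaseX = "numeric",
                 releaseZ = "numeric"),
  validity = function(object) {
    if (object@particlesPerStep < 0) return("particlesPerStep must be >= 0")
    if (object@stepMin <= 0) return("stepMin must be > 0")
    TRUE
  })

#' Construct a ReleaseSchedule
#'
#' @param particlesPerStep particles per event (200).
#' @param stepMin minutes between events (5).
#' @param activeWindowMin flood-gate window length, minutes.
#' @param releaseX release x position, m.
#' @param releaseZ release depth, m (10, roughly mid water column).
#' @return a [ReleaseSchedule-class]
#' @export
releaseSchedule <- function(particlesPerStep = 200L, stepMin = 5,
                            activeWindowMin = 70, releaseX = 0,
                            releaseZ = 10) {
  new("ReleaseSchedule", particlesPerStep = as.integer(particlesPerStep),
      stepMin = stepMin, activeWindowMin = activeWindowMin,
      releaseX = releaseX, releaseZ = releaseZ)
}

#' Descriptor grid parameters for the bag-of-features stage
#'
#' `patch` and `stride` may be vectors of equal length: descriptors are then
#' pooled over several patch scales (the default mixes a fine 8 px and a
#' coarse 16 px grid, which separates smooth blob-like targets from rough
#' foam texture better than either scale alone).
#'
#' @param patch square patch side(s), px.
#' @param stride grid stride(s), px (recycled against `patch`).
#' @param nBins gradient orientation bins over \[0, 2*pi).
#' @param chipSide expected chip side, px.
#' @return named list used by [computeDescriptors()]
#' @export
descriptorSpec <- function(patch = c(8L, 16L), stride = c(4L, 8L),
                           nBins = 8L, chipSide = 32L) {
  stride <- rep_len(as.integer(stride), length(patch))
  list(patch = as.integer(patch), stride = stride,
       nBins = as.integer(nBins), chipSide = as.integer(chipSide))
}
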