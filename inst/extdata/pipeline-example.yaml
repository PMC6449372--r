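# Example configuration for runPipeline(). Every block is optional; omitted
# parameters fall back to the package defaults, which mirror the study
# conditions. Per-stage seeds are derived from the global seed passed to
# runPipeline(), never set here.

video:
  frameSize: [120, 180]     # rows, cols (px)
  fps: 5                    # frames per second
  duration: 60              # seconds
  gsd: 0.5                  # metres per pixel
  nBirds: 3                 # terns in the scene
  birdSpeed: 4              # m/s
  birdSinuosity: 1.3        # path/chord target (1 = straight)
  sheddingFrequency: 12     # eddies per minute
  diffThreshold: 0.05       # frame-differencing threshold

adcp:
  nBins: 20                 # 1 m depth bins
  transectSpan: 200         # m cross-stream
  deficitWidth: 45          # m, full width at half maximum
  deficitFraction: 0.5      # peak fractional velocity deficit
  upstreamSpeed: 5          # m/s
  wakeSvAnomaly: 10         # dB at the wake centre

hurdle:
  nSurveys: 11              # vantage-point surveys per site
  nbDispersion: 1.5         # negative-binomial theta
  ar1Rho: 0.4               # latent AR1 correlation

transit:
  flow:
    waterDepth: 20          # m
    ustar: 0.2              # bed friction velocity, m/s
    z0: 0.005               # roughness length, m
    Dv: 0.01                # vertical dispersion, m^2/s
    scaling: 1.0            # horizontal eddy-viscosity scaling
  schedule:
    particlesPerStep: 200   # trickle release batch
    stepMin: 5              # minutes between releases
    activeWindowMin: 70     # flood gate length, minutes
    releaseZ: 10            # release depth, m
  targetX: 2000             # arrival boundary, m downstream
  totalTime: 14400          # seconds simulated
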