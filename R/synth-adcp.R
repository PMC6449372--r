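# Smooth wake-deficit bump: Gaussian with full width at half maximum equal
# to 'width', so the half-maximum extent estimator recovers 'width' exactly
# in the noiseless limit.
wakeBump <- function(y, center, width) {
  exp(-4 * log(2) * (y - center)^2 / width^2)
}

#' Generate a synthetic cross-stream ADCP wake transect with known truth
#'
#' Ensembles are laid out along a cross-stream transect. The true streamwise
#' water speed is `upstreamSpeed * (1 - deficitFraction * W(y))` where `W` is
#' a Gaussian bump whose full width at half maximum equals `deficitWidth`.
#' Echo-intensity counts carry a wake backscatter anomaly of
#' `wakeSvAnomaly * W(y)` dB, injected through the inverse of the sonar
#' equation's count term (i.e. divided by the RSSI scale `Kc`), uniformly
#' over the water column as a bubble plume would be. The recorded
#' (instrument-relative) velocities include the boat motion; the bottom-track
#' velocity is stored as the instrument reports it (minus the boat velocity),
#' so [correctVelocity()] recovers the true water velocity.
#'
#' @param config an [ADCPSimConfig-class].
#' @return list with `transect` (an [ADCPTransect-class]) and `trueWake`
#'   (center, width, fraction, svAnomaly, upstreamSpeed).
#' @export
generateADCPTransect <- function(config) {
  stopifnot(is(config, "ADCPSimConfig"))
  validObject(config)
  set.seed(config@seed)
  ins <- config@instrument
  nb <- config@nBins
  ys <- seq(-config@transectSpan / 2, config@transectSpan / 2,
            by = config@pingSpacing)
  kc <- if (length(ins@Kc) == 4) ins@Kc else rep(ins@Kc[1], 4)
  er <- if (length(ins@Er) == 4) ins@Er else rep(ins@Er[1], 4)
  # baseline count profile decaying with range, comfortably above the floor
  baseCounts <- pmax(er[1] + 90 - 1.8 * (seq_len(nb) - 1), er[1] + 5)
  ens <- vector("list", length(ys))
  for (i in seq_along(ys)) {
    y <- ys[i]
    wk <- wakeBump(y, config@deficitCenter, config@deficitWidth)
    uTrue <- config@upstreamSpeed * (1 - config@deficitFraction * wk)
    water <- cbind(u = rep(uTrue, nb), v = 0, w = 0) +
      matrix(rnorm(3 * nb, 0, config@noiseSdVelocity), nb, 3)
    boat <- c(0, config@boatSpeed)          # boat runs cross-stream (v axis)
    bt <- -boat                             # instrument-reported bottom track
    measured <- water
    measured[, 1] <- measured[, 1] + bt[1]
    measured[, 2] <- measured[, 2] + bt[2]
    anomCounts <- config@wakeSvAnomaly * wk / kc  # per beam
    echo <- matrix(rep(baseCounts, each = 4), 4, nb) + anomCounts +
      matrix(rnorm(4 * nb, 0, config@noiseSdCounts), 4, nb)
    echo <- pmax(echo, 0)
    colnames(measured) <- c("u", "v", "w")
    ens[[i]] <- new("ADCPEnsemble",
                    pingTime = (y + config@transectSpan / 2) / config@boatSpeed,
                    y = y, echoCounts = echo, velocity = measured,
                    bottomTrack = bt, temperature = config@temperature,
                    salinity = config@salinity)
  }
  list(transect = new("ADCPTransect", ensembles = ens, instrument = ins),
       trueWake = list(center = config@deficitCenter,
                       width = config@deficitWidth,
                       fraction = config@deficitFraction,
                       svAnomaly = config@wakeSvAnomaly,
                       upstreamSpeed = config@upstreamSpeed))
}
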