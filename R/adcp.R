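#' Along-beam slant range to the middle of a depth bin
#'
#' `R = (blank + (pulseLength + binSize)/2 + (n - 1) * binSize +
#' binSize/4) / cos(beamAngle)` for 1-based bin index `n`.
#'
#' @param bin bin index (1-based, >= 1), may be a vector.
#' @param cfg an [InstrumentConfig-class].
#' @return slant range, m.
#' @export
slantRange <- function(bin, cfg) {
  assertThat(all(bin >= 1), "bin index must be >= 1")
  D <- cfg@binSize
  (cfg@blank + (cfg@pulseLength + D) / 2 + (bin - 1) * D + D / 4) /
    cos(cfg@beamAngle * pi / 180)
}

# Vertical depth (m below surface) of bin centres: the vertical projection of
# the along-beam geometry plus the transducer depth.
binDepth <- function(bin, cfg) {
  D <- cfg@binSize
  cfg@transducerDepth + cfg@blank + (cfg@pulseLength + D) / 2 +
    (bin - 1) * D + D / 4
}

#' Seawater sound absorption coefficient
#'
#' Ainslie & McColm's (1998) simplified formula: boric-acid and magnesium-
#' sulphate relaxation terms plus pure-water viscous absorption, as a
#' function of temperature, salinity, depth and frequency (pH fixed at 8).
#'
#' @param temperature deg C, in \[-6, 35\].
#' @param salinity PSU, in \[0, 50\].
#' @param depth m, in \[0, 7000\].
#' @param frequency kHz, in \[0.1, 1000\].
#' @param pH acidity (default 8).
#' @return absorption, dB per metre.
#' @export
waterAbsorption <- function(temperature, salinity, depth, frequency, pH = 8) {
  if (temperature < -6 || temperature > 35)
    stop("temperature out of the formula's validity range [-6, 35] C",
         call. = FALSE)
  if (salinity < 0 || salinity > 50)
    stop("salinity out of range [0, 50] PSU", call. = FALSE)
  if (depth < 0 || depth > 7000) stop("depth out of range [0, 7000] m",
                                      call. = FALSE)
  if (frequency < 0.1 || frequency > 1000)
    stop("frequency out of range [0.1, 1000] kHz", call. = FALSE)
  Tt <- temperature; S <- salinity; zkm <- depth / 1000; f <- frequency
  f1 <- 0.78 * sqrt(S / 35) * exp(Tt / 26)
  f2 <- 42 * exp(Tt / 17)
  boric <- 0.106 * (f1 * f^2 / (f^2 + f1^2)) * exp((pH - 8) / 0.56)
  mgso4 <- 0.52 * (1 + Tt / 43) * (S / 35) *
    (f2 * f^2 / (f^2 + f2^2)) * exp(-zkm / 6)
  water <- 0.00049 * f^2 * exp(-(Tt / 27 + zkm / 17))
  (boric + mgso4 + water) / 1000   # dB/km -> dB/m
}

#' Volume backscattering strength from raw echo intensity
#'
#' Applies the working sonar equation per beam and bin:
#' `Sv = C + 10 log10((Tx + 273.16) R^2) - L_DBM - P_DBW + 2 a R +
#' Kc (E - Er)` with `L_DBM = 10 log10(pulseLength)`, slant range `R` from
#' [slantRange()] and absorption `a` from [waterAbsorption()] (evaluated at
#' the ensemble's temperature/salinity and each bin's depth). Bins beyond
#' `cfg@maxBins` are excluded. `Sv_max` is the per-bin maximum over beams.
#' Counts below the noise floor still convert (negative contribution) but
#' the profile is flagged.
#'
#' @param ens an [ADCPEnsemble-class].
#' @param cfg an [InstrumentConfig-class].
#' @return an [SvProfile-class]; `flags` records the absorption model and
#'   any below-noise-floor counts.
#' @export
computeSv <- function(ens, cfg) {
  nb <- min(ncol(ens@echoCounts), cfg@maxBins)
  assertThat(nb >= 1, "no bins present")
  E <- ens@echoCounts[, seq_len(nb), drop = FALSE]
  nbeam <- nrow(E)
  kc <- if (length(cfg@Kc) == nbeam) cfg@Kc else rep(cfg@Kc[1], nbeam)
  er <- if (length(cfg@Er) == nbeam) cfg@Er else rep(cfg@Er[1], nbeam)
  bins <- seq_len(nb)
  R <- slantRange(bins, cfg)
  alpha <- vapply(bins, function(n)
    waterAbsorption(ens@temperature, ens@salinity, binDepth(n, cfg),
                    cfg@frequency), numeric(1))
  Ldbm <- 10 * log10(cfg@pulseLength)
  base <- cfg@instrumentConstant + 10 * log10((ens@temperature + 273.16) * R^2) - Ldbm -
    cfg@powerDbw + 2 * alpha * R
  sv <- matrix(NA_real_, nbeam, ncol(ens@echoCounts))
  for (b in seq_len(nbeam))
    sv[b, bins] <- base + kc[b] * (E[b, ] - er[b])
  flags <- "absorption: Ainslie-McColm 1998"
  if (any(sweep(E, 1, er) < 0))
    flags <- c(flags, "counts below noise floor present")
  new("SvProfile", sv = sv,
      svMax = apply(sv[, bins, drop = FALSE], 2, max), flags = flags)
}

#' Correct measured velocities by the bottom track
#'
#' True water velocity is the instrument-relative measured velocity minus
#' the instrument-reported bottom-track velocity (the apparent seabed
#' motion), per bin and component. An invalid (NA) bottom track flags the
#' ensemble so sections exclude it.
#'
#' @param ens an [ADCPEnsemble-class].
#' @return bins x 3 matrix (u, v, w) of water velocity, m/s, with attribute
#'   `valid` (FALSE when the bottom track is missing).
#' @export
correctVelocity <- function(ens) {
  v <- ens@velocity
  ok <- all(is.finite(ens@bottomTrack))
  if (ok) {
    v[, 1] <- v[, 1] - ens@bottomTrack[1]
    v[, 2] <- v[, 2] - ens@bottomTrack[2]
  } else v[] <- NA_real_
  attr(v, "valid") <- ok
  v
}

#' Grid a transect into a cross-stream velocity/backscatter section
#'
#' Bottom-track-corrects every valid ensemble, converts echo counts to Sv,
#' and bin-averages horizontal speed, vertical velocity and Sv_max onto a
#' regular (y, z) grid with z taken from the bin-depth geometry. Cells
#' retain their sample counts; empty cells are NA.
#'
#' @param transect an [ADCPTransect-class].
#' @param yBin cross-stream cell width, m.
#' @return a [VelocitySection-class].
#' @export
gridSection <- function(transect, yBin = 2) {
  ens <- transect@ensembles
  assertThat(length(ens) >= 1, "need at least one ensemble")
  cfg <- transect@instrument
  nb <- min(ncol(ens[[1]]@echoCounts), cfg@maxBins)
  z <- binDepth(seq_len(nb), cfg)
  ys <- vapply(ens, function(e) e@y, numeric(1))
  edges <- seq(floor(min(ys) / yBin) * yBin, max(ys) + yBin, by = yBin)
  yc <- edges[-length(edges)] + yBin / 2
  acc <- array(0, dim = c(nb, length(yc), 4))  # speed, sv, w, n
  for (e in ens) {
    w <- correctVelocity(e)
    if (!attr(w, "valid")) next
    sv <- computeSv(e, cfg)
    j <- findInterval(e@y, edges, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(yc))
    spd <- sqrt(w[seq_len(nb), 1]^2 + w[seq_len(nb), 2]^2)
    acc[, j, 1] <- acc[, j, 1] + spd
    acc[, j, 2] <- acc[, j, 2] + sv@svMax
    acc[, j, 3] <- acc[, j, 3] + w[seq_len(nb), 3]
    acc[, j, 4] <- acc[, j, 4] + 1
  }
  asMat <- function(k) matrix(acc[, , k], nb, length(yc))
  n <- asMat(4)
  div <- ifelse(n > 0, n, NA)
  new("VelocitySection", y = yc, z = z,
      speed = asMat(1) / div, svMax = asMat(2) / div,
      w = asMat(3) / div, n = n)
}

#' Cross-stream extent of the wake velocity deficit
#'
#' Depth-averages the section's speed, forms the deficit relative to a
#' reference speed (default: mean of the outer 20% of the cross-stream
#' profile), and measures the width of the contiguous interval around the
#' deficit maximum where the deficit is at least `fraction` of its maximum,
#' linearly interpolating the crossings. A flat or deficit-free profile
#' returns 0 with a warning.
#'
#' @param section a [VelocitySection-class].
#' @param referenceSpeed reference, m/s; `NULL` for the outer-20% mean.
#' @param fraction threshold fraction of the peak deficit (default 0.5,
#'   i.e. full width at half maximum).
#' @return extent, m.
#' @export
wakeDeficitExtent <- function(section, referenceSpeed = NULL,
                              fraction = 0.5) {
  prof <- colMeans(section@speed, na.rm = TRUE)
  y <- section@y
  ok <- is.finite(prof)
  prof <- prof[ok]; y <- y[ok]
  assertThat(length(y) >= 3, "profile too short")
  if (is.null(referenceSpeed)) {
    nOut <- max(1L, ceiling(0.1 * length(y)))
    referenceSpeed <- mean(c(head(prof, nOut), tail(prof, nOut)))
  }
  deficit <- referenceSpeed - prof
  dmax <- max(deficit)
  if (dmax <= 0) {
    warning("no velocity deficit in the section; extent = 0")
    return(0)
  }
  thr <- fraction * dmax
  imax <- which.max(deficit)
  crossAt <- function(i1, i2) {   # linear interpolation of deficit == thr
    y[i1] + (thr - deficit[i1]) * (y[i2] - y[i1]) /
      (deficit[i2] - deficit[i1])
  }
  iL <- imax
  while (iL > 1 && deficit[iL - 1] >= thr) iL <- iL - 1
  yl <- if (iL == 1) y[1] else crossAt(iL - 1, iL)
  iR <- imax
  while (iR < length(y) && deficit[iR + 1] >= thr) iR <- iR + 1
  yr <- if (iR == length(y)) y[length(y)] else crossAt(iR + 1, iR)
  yr - yl
}

#' Turbulent vertical-velocity fluctuation statistic
#'
#' Removes a centred running mean of window length `window` from each depth
#' level's vertical-velocity series and reports an upper quantile of the
#' absolute fluctuation over an optional region mask.
#'
#' @param w matrix (depth x position) of vertical velocity, m/s, or a
#'   [VelocitySection-class] (its `w` grid is used).
#' @param window running-mean window length, samples (<= series length).
#' @param mask logical matrix selecting cells to include (default: all).
#' @param probs quantile of |w'| reported (default 0.95).
#' @return fluctuation statistic, m/s.
#' @export
verticalVelocityFluctuation <- function(w, window = 5, mask = NULL,
                                        probs = 0.95) {
  if (is(w, "VelocitySection")) w <- w@w
  assertThat(window <= ncol(w), "window longer than the series")
  runmean <- function(x) {
    n <- length(x)
    out <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - floor(window / 2))
      hi <- min(n, i + floor(window / 2))
      mean(x[lo:hi], na.rm = TRUE)
    }, numeric(1))
    out
  }
  wp <- t(apply(w, 1, function(x) x - runmean(x)))
  if (!is.null(mask)) wp <- wp[mask]
  as.numeric(quantile(abs(wp), probs = probs, na.rm = TRUE))
}
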