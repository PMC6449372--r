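test_that("slant range follows the documented geometry", {
  cfg <- instrumentConfig(blank = 1.6, pulseLength = 1, binSize = 1,
                          beamAngle = 20)
  expect_equal(slantRange(1, cfg), (1.6 + 1 + 0.25) / cos(20 * pi / 180),
               tolerance = 1e-12)
  r <- slantRange(1:10, cfg)
  expect_equal(unique(round(diff(r), 12)), 1 / cos(20 * pi / 180))
  cfg0 <- instrumentConfig(blank = 1.6, pulseLength = 1, binSize = 1,
                           beamAngle = 1e-9)
  expect_equal(slantRange(3, cfg0), 1.6 + 1 + 2 + 0.25, tolerance = 1e-9)
  expect_error(slantRange(0, cfg), "bin")
})

test_that("water absorption matches an independent recomputation", {
  # independent implementation of the same published seawater model
  oracle <- function(T, S, z, f, pH = 8) {
    zk <- z / 1000
    f1 <- 0.78 * sqrt(S / 35) * exp(T / 26)
    f2 <- 42 * exp(T / 17)
    a1 <- 0.106 * f1 * f^2 / (f^2 + f1^2) * exp((pH - 8) / 0.56)
    a2 <- 0.52 * (1 + T / 43) * (S / 35) * f2 * f^2 / (f^2 + f2^2) *
      exp(-zk / 6)
    a3 <- 0.00049 * f^2 * exp(-(T / 27 + zk / 17))
    (a1 + a2 + a3) / 1000
  }
  expect_equal(waterAbsorption(10, 35, 10, 600), oracle(10, 35, 10, 600),
               tolerance = 1e-6)
  expect_gt(waterAbsorption(10, 35, 10, 600), waterAbsorption(10, 0, 10, 600))
  for (T in c(0, 10, 20)) for (f in c(300, 600, 1000))
    expect_gt(waterAbsorption(T, 33, 5, f), 0)
  expect_error(waterAbsorption(50, 35, 10, 600), "temperature")
  expect_error(waterAbsorption(10, 80, 10, 600), "salinity")
  expect_error(waterAbsorption(10, 35, 10, 0.01), "frequency")
})

test_that("Sv follows the sonar equation with exact count linearity", {
  cfg <- instrumentConfig()
  nb <- 10L
  E <- matrix(cfg@Er, 4, nb)      # counts at the noise floor
  ens <- new("ADCPEnsemble", pingTime = 0, y = 0, echoCounts = E,
             velocity = matrix(0, nb, 3), bottomTrack = c(0, 0),
             temperature = 12, salinity = 34)
  sv <- computeSv(ens, cfg)
  # direct arithmetic for bin 3
  R <- slantRange(3, cfg)
  alpha <- waterAbsorption(12, 34, wakewatch:::binDepth(3, cfg), cfg@frequency)
  expected <- cfg@instrumentConstant +
    10 * log10((12 + 273.16) * R^2) - 10 * log10(cfg@pulseLength) -
    cfg@powerDbw + 2 * alpha * R
  expect_equal(sv@sv[1, 3], expected, tolerance = 1e-12)

  # +10 counts raises Sv by exactly 10 * Kc
  ens2 <- ens; ens2@echoCounts <- E + 10
  sv2 <- computeSv(ens2, cfg)
  expect_equal(sv2@sv - sv@sv, matrix(10 * cfg@Kc, 4, nb), tolerance = 1e-12)

  # sv_max is the per-bin max over beams
  E3 <- E; E3[, 5] <- cfg@Er + c(20, 25, 10, 15)
  sv3 <- computeSv(new("ADCPEnsemble", pingTime = 0, y = 0, echoCounts = E3,
                       velocity = matrix(0, nb, 3), bottomTrack = c(0, 0),
                       temperature = 12, salinity = 34), cfg)
  expect_equal(sv3@svMax[5], max(sv3@sv[, 5]))
  expect_true(all(sweep(sv3@sv, 2, sv3@svMax) <= 1e-12))

  # below-noise-floor counts are converted but flagged
  E4 <- E; E4[1, 1] <- cfg@Er - 5
  sv4 <- computeSv(new("ADCPEnsemble", pingTime = 0, y = 0, echoCounts = E4,
                       velocity = matrix(0, nb, 3), bottomTrack = c(0, 0),
                       temperature = 12, salinity = 34), cfg)
  expect_true(any(grepl("noise floor", sv4@flags)))
  expect_lt(sv4@sv[1, 1], sv4@sv[2, 1])

  # bins beyond the configured maximum are excluded
  cfgM <- instrumentConfig(maxBins = 5L)
  sv5 <- computeSv(ens, cfgM)
  expect_true(all(is.na(sv5@sv[, 6:nb])))
  expect_equal(length(sv5@svMax), 5)
})

test_that("bottom-track correction recovers true water velocity", {
  nb <- 4L
  mkEns <- function(vel, bt) new("ADCPEnsemble", pingTime = 0, y = 0,
    echoCounts = matrix(50, 4, nb), velocity = vel, bottomTrack = bt,
    temperature = 12, salinity = 34)
  # stationary water under a boat moving at (2, 0): the instrument reports a
  # bottom track of (-2, 0) and measured water of (-2, 0)
  v <- correctVelocity(mkEns(matrix(rep(c(-2, 0, 0), each = nb), nb), c(-2, 0)))
  expect_equal(unname(v[, 1:2]), matrix(0, nb, 2))
  # zero boat velocity: identity
  vel <- matrix(rnorm(nb * 3), nb)
  v2 <- correctVelocity(mkEns(vel, c(0, 0)))
  expect_equal(unname(v2), unname(vel), ignore_attr = TRUE)
  # invalid bottom track flags the ensemble
  v3 <- correctVelocity(mkEns(vel, c(NA_real_, 0)))
  expect_false(attr(v3, "valid"))
  expect_true(all(is.na(v3)))
})

test_that("synthetic transects round-trip through Sv and velocity", {
  sim <- generateADCPTransect(adcpSimConfig(noiseSdVelocity = 0,
                                            noiseSdCounts = 0))
  tr <- sim$transect
  ys <- vapply(tr@ensembles, function(e) e@y, numeric(1))
  ctr <- which.min(abs(ys - sim$trueWake$center))
  svC <- computeSv(tr@ensembles[[ctr]], tr@instrument)
  svE <- computeSv(tr@ensembles[[1]], tr@instrument)
  expect_lt(max(abs((svC@svMax - svE@svMax) - sim$trueWake$svAnomaly)), 0.1)
  w <- correctVelocity(tr@ensembles[[ctr]])
  expect_equal(as.numeric(sqrt(w[1, 1]^2 + w[1, 2]^2)),
               sim$trueWake$upstreamSpeed * (1 - sim$trueWake$fraction),
               tolerance = 1e-9)
  # deficit-free, noiseless: identical speeds everywhere
  sim0 <- generateADCPTransect(adcpSimConfig(deficitFraction = 0,
                                             noiseSdVelocity = 0,
                                             noiseSdCounts = 0))
  spd <- vapply(sim0$transect@ensembles, function(e) {
    v <- correctVelocity(e); sqrt(v[1, 1]^2 + v[1, 2]^2)
  }, numeric(1))
  expect_equal(spd, rep(sim0$trueWake$upstreamSpeed, length(spd)),
               tolerance = 1e-9)
  expect_error(adcpSimConfig(deficitFraction = 1.5), "deficitFraction")
})

test_that("gridded sections average cells and reproduce the deficit shape", {
  sim <- generateADCPTransect(adcpSimConfig(noiseSdVelocity = 0,
                                            noiseSdCounts = 0))
  e1 <- sim$transect@ensembles[[1]]
  single <- new("ADCPTransect", ensembles = list(e1),
                instrument = sim$transect@instrument)
  sec1 <- gridSection(single)
  expect_equal(sum(sec1@n > 0), sum(!is.na(sec1@speed)))
  expect_equal(sum(colSums(sec1@n) > 0), 1)   # one occupied column

  # two ensembles in one cell average arithmetically
  e2 <- e1; e2@y <- e1@y + 0.1
  e2@velocity <- e1@velocity + 1
  two <- new("ADCPTransect", ensembles = list(e1, e2),
             instrument = sim$transect@instrument)
  sec2 <- gridSection(two, yBin = 2)
  occ <- which(sec2@n[1, ] == 2)
  s1 <- sqrt(sum(correctVelocity(e1)[1, 1:2]^2))
  s2 <- sqrt(sum(correctVelocity(e2)[1, 1:2]^2))
  expect_equal(sec2@speed[1, occ], (s1 + s2) / 2)

  # noisy transect: gridded speeds track the true field within 2 x noise sd
  cfgN <- adcpSimConfig(noiseSdVelocity = 0.1, seed = 12L)
  simN <- generateADCPTransect(cfgN)
  secN <- gridSection(simN$transect, yBin = 2)
  prof <- colMeans(secN@speed, na.rm = TRUE)
  uTrue <- cfgN@upstreamSpeed *
    (1 - cfgN@deficitFraction *
       wakewatch:::wakeBump(secN@y, cfgN@deficitCenter, cfgN@deficitWidth))
  # cell means of many bin-samples sit well inside twice the per-sample
  # noise sd
  expect_lt(max(abs(prof - uTrue)), 2 * cfgN@noiseSdVelocity)
})

test_that("wake deficit extent: flat, triangular, and synthetic profiles", {
  mkSec <- function(y, prof) new("VelocitySection", y = y, z = 1:3,
    speed = rbind(prof, prof, prof), svMax = rbind(prof, prof, prof) * 0,
    w = rbind(prof, prof, prof) * 0, n = rbind(prof, prof, prof) * 0 + 1)
  flat <- mkSec(seq(-50, 50, 2), rep(3, 51))
  expect_warning(e0 <- wakeDeficitExtent(flat), "no velocity deficit")
  expect_equal(e0, 0)

  # triangular deficit with base 40: half-maximum width is 20
  y <- seq(-100, 100, by = 1)
  deficit <- pmax(0, 1 - abs(y) / 20)
  tri <- mkSec(y, 5 - deficit)
  expect_equal(wakeDeficitExtent(tri, referenceSpeed = 5, fraction = 0.5), 20,
               tolerance = 1e-9)

  simN <- generateADCPTransect(adcpSimConfig(seed = 3L))
  ext <- wakeDeficitExtent(gridSection(simN$transect, yBin = 2))
  expect_lt(abs(ext - simN$trueWake$width), 3)
})

test_that("vertical velocity fluctuation statistic", {
  w <- matrix(0.3, 5, 60)
  expect_equal(verticalVelocityFluctuation(w, window = 9), 0)
  # sinusoid: statistic equals the brute-force quantile of |w - runmean(w)|
  x <- seq_len(200)
  ws <- rbind(0.6 * sin(x / 3), 0.6 * sin(x / 3 + 1))
  stat <- verticalVelocityFluctuation(ws, window = 41, probs = 0.95)
  rm41 <- function(v) vapply(seq_along(v), function(i)
    mean(v[max(1, i - 20):min(length(v), i + 20)]), numeric(1))
  resid <- rbind(ws[1, ] - rm41(ws[1, ]), ws[2, ] - rm41(ws[2, ]))
  expect_equal(stat, as.numeric(quantile(abs(resid), 0.95)))
  # masking restricts the statistic to selected cells
  mask <- matrix(FALSE, 2, 200); mask[1, ] <- TRUE
  statM <- verticalVelocityFluctuation(ws, window = 41, mask = mask)
  expect_equal(statM, as.numeric(quantile(abs(resid[1, ]), 0.95)))
  expect_error(verticalVelocityFluctuation(ws, window = 500), "window")
})
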