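test_that("log-law flow field: hand value, monotonicity, clamping", {
  fl <- generateFlowField(flowFieldConfig(waterDepth = 20, ustar = 0.1,
                                          z0 = 0.001))
  expect_equal(logLawSpeed(fl, 1), (0.1 / 0.41) * log(1000), tolerance = 1e-12)
  h <- seq(0.001, 20, length.out = 200)
  expect_true(all(diff(logLawSpeed(fl, h)) >= 0))
  # below z0 the profile is evaluated at z0
  expect_equal(logLawSpeed(fl, 1e-6), logLawSpeed(fl, 0.001))
  # zero friction velocity gives zero flow
  fl0 <- generateFlowField(flowFieldConfig(ustar = 0))
  expect_true(all(logLawSpeed(fl0, h) == 0))
  # depth-averaged speed agrees with numerical quadrature
  num <- integrate(function(z) logLawSpeed(fl, z), 0.001, 20)$value /
    (20 - 0.001)
  expect_equal(depthAveragedSpeed(fl), num, tolerance = 1e-6)
  expect_error(generateFlowField(flowFieldConfig(z0 = 25, waterDepth = 20)),
               "z0")
})

test_that("pure advection: exact displacement and release accounting", {
  fl <- generateFlowField(flowFieldConfig(waterDepth = 20, ustar = 0.2,
                                          z0 = 0.005, Dv = 0, baseDh = 0))
  u10 <- speedAtDepth(fl, 10)
  sched <- releaseSchedule(particlesPerStep = 200L, stepMin = 5,
                           activeWindowMin = 70, releaseZ = 10)
  ens <- runRelease(sched, fl, targetX = u10 * 4200, totalTime = 4200 * 2,
                    dt = 60, seed = 1)
  p <- particleStates(ens)
  expect_equal(length(unique(p$release_s)), 15)   # 0, 5, ..., 70 min
  expect_equal(nrow(p), 3000)
  arr <- p[p$status == "arrived", ]
  expect_true(all(abs((arr$arrival_s - arr$release_s) - 4200) < 1e-9))
  # z untouched without vertical dispersion
  expect_true(all(p$z == 10))
  # zero particles per step gives an empty ensemble without error
  e0 <- runRelease(releaseSchedule(particlesPerStep = 0L), fl, 100, 60)
  expect_equal(nrow(particleStates(e0)), 0)
})

test_that("vertical dispersion grows variance like 2 D t", {
  fl <- generateFlowField(flowFieldConfig(waterDepth = 1e6, ustar = 0,
                                          Dv = 0.01, baseDh = 0))
  n <- 1e4
  sched <- releaseSchedule(particlesPerStep = as.integer(n), stepMin = 5,
                           activeWindowMin = 0, releaseZ = 5e5)
  set.seed(3)
  ens <- runRelease(sched, fl, targetX = Inf, totalTime = 1000, dt = 5,
                    seed = 3)
  v <- var(particleStates(ens)$z)
  target <- 2 * 0.01 * 1000
  # chi-square sampling bound: sd(var) ~ target * sqrt(2/(n-1))
  expect_lt(abs(v - target), 3 * target * sqrt(2 / (n - 1)))
})

test_that("reflection keeps particles in the water column, mirror-exact", {
  expect_equal(wakewatch:::reflectDepth(-0.2, 20), 0.2)
  expect_equal(wakewatch:::reflectDepth(20.3, 20), 19.7)
  expect_equal(wakewatch:::reflectDepth(c(5, -1, 21), 20), c(5, 1, 19))
  # particle at z = 0.1 stepped by -0.3 reflects to 0.2
  expect_equal(wakewatch:::reflectDepth(0.1 - 0.3, 20), 0.2)

  fl <- generateFlowField(flowFieldConfig(waterDepth = 2, ustar = 0.1,
                                          Dv = 0.05, baseDh = 0))
  sched <- releaseSchedule(particlesPerStep = 500L, stepMin = 5,
                           activeWindowMin = 0, releaseZ = 1)
  ens <- runRelease(sched, fl, targetX = Inf, totalTime = 600, dt = 5,
                    seed = 4)
  z <- particleStates(ens)$z
  expect_true(all(z >= 0 & z <= 2))
})

test_that("particle counts are conserved through every step", {
  fl <- generateFlowField(flowFieldConfig(waterDepth = 20, ustar = 0.3,
                                          z0 = 0.005, Dv = 0.01,
                                          baseDh = 0.01))
  sched <- releaseSchedule(particlesPerStep = 100L, stepMin = 5,
                           activeWindowMin = 20, releaseZ = 10)
  ens <- new("ParticleEnsemble", particles = data.frame(
    id = 1:500, x = 0, z = 10,
    release_s = rep(seq(0, 1200, 300), each = 100),
    status = "in_transit", arrival_s = NA_real_), meta = list())
  t <- 0
  for (i in 1:60) {
    ens <- stepParticles(ens, fl, dt = 10, targetX = 800, tNow = t)
    t <- t + 10
    p <- particleStates(ens)
    expect_equal(nrow(p), 500)
    expect_equal(sum(p$status %in% c("in_transit", "arrived", "outside")), 500)
    expect_true(all(is.na(p$arrival_s) | p$arrival_s >= p$release_s))
  }
  expect_gt(sum(particleStates(ens)$status == "arrived"), 0)
})

test_that("transit summaries match sort-based oracles", {
  mkEns <- function(tt) new("ParticleEnsemble", particles = data.frame(
    id = seq_along(tt), x = 100, z = 5, release_s = 0,
    status = "arrived", arrival_s = tt), meta = list())
  s <- transitSummary(mkEns(rep(4200, 10)))
  expect_equal(s$median, 4200)
  expect_equal(s$mean, 4200)
  expect_equal(s$fractionArrived, 1)
  set.seed(5)
  tt <- runif(101, 100, 900)
  s2 <- transitSummary(mkEns(tt))
  expect_equal(unname(s2$median), sort(tt)[51])
  expect_equal(unname(s2$quantiles), unname(quantile(tt, c(0.25, 0.5, 0.75, 0.9))))
  # no arrivals: fraction 0 with NA statistics
  none <- new("ParticleEnsemble", particles = data.frame(
    id = 1, x = 0, z = 5, release_s = 0, status = "in_transit",
    arrival_s = NA_real_), meta = list())
  s3 <- transitSummary(none)
  expect_equal(s3$fractionArrived, 0)
  expect_true(is.na(s3$median))
})

test_that("advection consistency: transit equals quadrature within one step", {
  fl <- generateFlowField(flowFieldConfig(waterDepth = 20, ustar = 0.25,
                                          z0 = 0.01, Dv = 0, baseDh = 0))
  zRel <- 7
  u <- speedAtDepth(fl, zRel)
  target <- 350
  sched <- releaseSchedule(particlesPerStep = 5L, stepMin = 5,
                           activeWindowMin = 0, releaseZ = zRel)
  ens <- runRelease(sched, fl, targetX = target, totalTime = 2000, dt = 5,
                    seed = 6)
  arr <- particleStates(ens)
  expect_true(all(abs(arr$arrival_s - target / u) < 5))
})
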