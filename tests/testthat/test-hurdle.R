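test_that("cyclic basis wraps with continuous value and zero-penalty constant", {
  tide <- seq(0, 12.4 - 1e-6, length.out = 200)
  b <- buildCyclicBasis(tide, nKnots = 6, period = 12.4)
  expect_equal(ncol(b$X), 5)
  # wrap continuity: basis at 0 and at period - eps agree to eps order
  b0 <- mgcv::PredictMat(b$sm, data.frame(tide = 0))
  b1 <- mgcv::PredictMat(b$sm, data.frame(tide = 12.4 - 1e-7))
  expect_equal(as.numeric(b0), as.numeric(b1), tolerance = 1e-5)
  # partition of unity: rows sum to a constant
  rs <- rowSums(b$X)
  expect_lt(diff(range(rs)), 1e-10)
  # second-derivative penalty annihilates the constant function
  ones <- rep(1, ncol(b$X))
  expect_lt(abs(t(ones) %*% b$S %*% ones), 1e-10)
  expect_error(buildCyclicBasis(c(1, 13)), "wrap")
})

test_that("presence fit matches an mgcv reference on independent data", {
  cfg <- surveyConfig(sites = c("A", "B"), nSurveys = 14L, ar1Rho = 0,
                      latentSd = 0.5, seed = 21L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitPresence(sim$counts, estimateRho = FALSE)
  d <- countData(sim$counts)
  d$y <- as.numeric(d$count > 0); d$site <- factor(d$site)
  ref <- mgcv::gam(y ~ 0 + site + s(tide, bs = "cc", k = 6, by = site),
                   data = d, family = binomial(), method = "REML",
                   knots = list(tide = seq(0, 12.4, length.out = 6)))
  grid <- seq(0, 12.39, length.out = 25)
  for (s in c("A", "B")) {
    mine <- plogis(as.numeric(
      wakewatch:::predictDesign(fit, s, grid) %*% fit$coef))
    theirs <- as.numeric(predict(ref,
      newdata = data.frame(tide = grid, site = factor(s, levels = c("A", "B"))),
      type = "response"))
    expect_lt(max(abs(mine - theirs)), 0.01)
  }
})

test_that("row duplication leaves independence point estimates unchanged", {
  cfg <- surveyConfig(sites = c("A", "B"), nSurveys = 8L, ar1Rho = 0,
                      seed = 22L)
  sim <- generateSurveyCounts(cfg)
  d <- countData(sim$counts)
  doubled <- new("CountSeries",
                 data = rbind(d, transform(d, survey_id = paste0(survey_id, "_b"))),
                 period = sim$counts@period)
  f1 <- fitPresence(sim$counts, estimateRho = FALSE, lambda = 1)
  f2 <- fitPresence(doubled, estimateRho = FALSE, lambda = 2)
  # penalty doubles with the data so the penalized estimate is identical
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
})

test_that("an all-zero site drives its predicted probability to zero", {
  cfg <- surveyConfig(sites = c("A", "B"),
                      presenceCoefs = cbind(c(1, -Inf), c(0.5, 0), c(0.2, 0)),
                      nSurveys = 8L, seed = 23L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitPresence(sim$counts, estimateRho = FALSE)
  expect_true("B" %in% fit$separated)
  pB <- plogis(as.numeric(
    wakewatch:::predictDesign(fit, "B", seq(0, 12, 2)) %*% fit$coef))
  expect_true(all(pB < 0.05))
})

test_that("abundance fit recovers ZTNB parameters and degenerates gracefully", {
  cfg <- surveyConfig(sites = c("A", "B"), nSurveys = 25L, ar1Rho = 0,
                      presenceCoefs = cbind(c(2, 2), 0, 0),
                      abundanceCoefs = cbind(c(1.5, 0.8), c(0.6, 0.2),
                                             c(-0.3, 0.1)),
                      nbDispersion = 2, seed = 24L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitAbundance(sim$counts, estimateRho = FALSE)
  expect_gt(fit$theta, 1)
  expect_lt(fit$theta, 4)
  grid <- seq(0, 12.39, length.out = 9)
  ang <- 2 * pi * grid / 12.4
  for (i in 1:2) {
    s <- c("A", "B")[i]
    etaHat <- as.numeric(wakewatch:::predictDesign(fit, s, grid) %*% fit$coef)
    etaTrue <- cfg@abundanceCoefs[i, 1] + cfg@abundanceCoefs[i, 2] * sin(ang) +
      cfg@abundanceCoefs[i, 3] * cos(ang)
    se <- sqrt(rowSums((wakewatch:::predictDesign(fit, s, grid) %*% fit$Vb) *
                         wakewatch:::predictDesign(fit, s, grid)))
    expect_true(all(abs(etaHat - etaTrue) < 4 * se + 0.05))
  }
  # truncation: the fitted distribution is normalised over y >= 1, so it
  # places no probability mass at zero
  pmass <- sum(exp(wakewatch:::ztnbLogLik(1:5000, mu = 2, theta = fit$theta)))
  expect_equal(pmass, 1, tolerance = 1e-8)
  expect_error(fitAbundance(new("CountSeries",
    data = countData(sim$counts)[1:10, ], period = 12.4)), "30 positive")
})

test_that("hurdle log-likelihood decomposes exactly into its two parts", {
  cfg <- surveyConfig(seed = 25L, nSurveys = 6L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitHurdle(sim$counts, estimateRho = FALSE)
  ll <- hurdleLogLik(fit, sim$counts)
  expect_equal(ll$total, ll$presence + ll$abundance, tolerance = 1e-12)
})

test_that("predictions match direct design-row products; SE tracks leverage", {
  cfg <- surveyConfig(sites = c("A", "B"), nSurveys = 10L, seed = 26L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitHurdle(sim$counts, estimateRho = FALSE)
  knot <- 12.4 / 5   # an interior knot of the 6-knot cyclic basis
  pr <- predictHurdle(fit, "A", knot)
  eta <- as.numeric(wakewatch:::predictDesign(fit@presence, "A", knot) %*%
                      fit@presence$coef)
  expect_equal(pr$prob, plogis(eta), tolerance = 1e-12)
  expect_error(predictHurdle(fit, "Nowhere", 1), "unknown site")
  # zero coefficients give probability one half
  f0 <- fit
  f0@presence$coef[] <- 0
  expect_equal(predictHurdle(f0, "A", c(1, 5, 9))$prob, rep(0.5, 3))
})

test_that("single-coefficient Wald F equals the squared z statistic", {
  cfg <- surveyConfig(sites = c("A", "B"), nSurveys = 10L, seed = 27L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitHurdle(sim$counts, estimateRho = FALSE)
  ft <- termFTest(fit, "site", "presence")
  # two sites: the site contrast has one df, F = z^2 for the difference
  cvec <- fit@presence$coef["A"] - fit@presence$coef["B"]
  Vb <- fit@presence$Vb
  vz <- Vb[1, 1] + Vb[2, 2] - 2 * Vb[1, 2]
  expect_equal(ft$F, as.numeric(cvec^2 / vz), tolerance = 1e-10)
  expect_equal(ft$df_num, 1)
  expect_error(termFTest(fit, "s(tide):Nowhere", "presence"), "unknown term")
  fs <- termFTest(fit, "s(tide):A", "abundance")
  expect_gte(fs$F, 0)
  expect_true(fs$p >= 0 && fs$p <= 1)
})

test_that("tidal-state binning partitions the cycle into equal states", {
  expect_equal(binTidalState(0), 1L)
  expect_equal(binTidalState(12.4 - 1e-9), 8L)
  grid <- seq(0, 12.4 - 1e-9, length.out = 8000)
  expect_true(all(abs(table(binTidalState(grid)) - 1000) <= 1))
  expect_equal(binTidalState(5, nBins = 4, period = 10), 3L)
})

test_that("cyclic predictions coincide at tide 0 and tide period", {
  cfg <- surveyConfig(sites = c("A", "B"), nSurveys = 8L, seed = 28L)
  sim <- generateSurveyCounts(cfg)
  fit <- fitHurdle(sim$counts, estimateRho = FALSE)
  p0 <- predictHurdle(fit, "A", 0)
  p1 <- predictHurdle(fit, "A", 12.4 - 1e-9)
  expect_equal(p0$prob, p1$prob, tolerance = 1e-6)
  expect_equal(p0$count, p1$count, tolerance = 1e-6)
})

test_that("AR1 estimation detects correlated presence residuals", {
  cfgHi <- surveyConfig(sites = c("A", "B"), nSurveys = 20L, ar1Rho = 0.85,
                        latentSd = 1.5, seed = 29L)
  cfgLo <- surveyConfig(sites = c("A", "B"), nSurveys = 20L, ar1Rho = 0,
                        latentSd = 1.5, seed = 29L)
  fHi <- fitPresence(generateSurveyCounts(cfgHi)$counts)
  fLo <- fitPresence(generateSurveyCounts(cfgLo)$counts)
  expect_gt(fHi$rho, fLo$rho + 0.03)
})
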