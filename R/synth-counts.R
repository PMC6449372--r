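# Zero-truncated negative binomial sampler by inverse CDF on [P(0), 1).
# theta = Inf gives the zero-truncated Poisson limit.
rztnb <- function(n, mu, theta) {
  if (length(mu) == 1) mu <- rep(mu, n)
  if (is.infinite(theta)) {
    p0 <- exp(-mu)
    u <- p0 + runif(n) * (1 - p0)
    return(stats::qpois(u, lambda = mu))
  }
  p0 <- (theta / (theta + mu))^theta
  u <- p0 + runif(n) * (1 - p0)
  qnbinom(u, mu = mu, size = theta)
}

#' Generate synthetic foraging-count surveys with known hurdle parameters
#'
#' Emulates the vantage-point protocol (counts every 2nd/3rd minute for a
#' 15-minute block, 5-minute rest, repeated over each survey) at several
#' sites. Presence is Bernoulli with logit-scale linear predictor
#' `intercept + a*sin(2*pi*tide/period) + b*cos(2*pi*tide/period)` plus
#' AR1-correlated latent noise within each survey; counts given presence are
#' zero-truncated negative binomial with a log-scale mean of the same form.
#'
#' @param config a [SurveyConfig-class].
#' @return list with `counts` (a [CountSeries-class]) and `trueParams`
#'   (every generating coefficient).
#' @export
generateSurveyCounts <- function(config) {
  stopifnot(is(config, "SurveyConfig"))
  validObject(config)
  set.seed(config@seed)
  period <- config@tidalPeriod
  rho <- config@ar1Rho
  theta <- config@nbDispersion
  rows <- vector("list", 0)
  for (si in seq_along(config@sites)) {
    site <- config@sites[si]
    pc <- config@presenceCoefs[si, ]
    ac <- config@abundanceCoefs[si, ]
    for (sv in seq_len(config@nSurveys)) {
      svLen <- max(30, rnorm(1, config@surveyLengthMean,
                             0.32 * config@surveyLengthMean))
      # observation minutes under the block/rest protocol
      gaps <- if (abs(config@countInterval - 2.5) < 1e-9) c(2, 3) else
        config@countInterval
      obs <- c(); t0 <- 0
      while (t0 < svLen) {
        tb <- t0 + cumsum(c(0, rep_len(gaps,
          ceiling(config@blockLength / min(gaps)))))
        tb <- tb[tb - t0 < config@blockLength & tb < svLen]
        obs <- c(obs, tb)
        t0 <- t0 + config@blockLength + config@restLength
      }
      if (!length(obs)) next
      startTide <- runif(1, 0, period)
      tide <- (startTide + obs / 60) %% period
      ang <- 2 * pi * tide / period
      n <- length(obs)
      e <- numeric(n)
      e[1] <- rnorm(1, 0, config@latentSd)
      if (n > 1) for (i in 2:n)
        e[i] <- rho * e[i - 1] + rnorm(1, 0, config@latentSd * sqrt(1 - rho^2))
      etaP <- pc[1] + pc[2] * sin(ang) + pc[3] * cos(ang) + e
      pres <- rbinom(n, 1, plogis(etaP))
      mu <- exp(ac[1] + ac[2] * sin(ang) + ac[3] * cos(ang))
      cnt <- integer(n)
      if (any(pres == 1)) cnt[pres == 1] <- rztnb(sum(pres), mu[pres == 1], theta)
      rows[[length(rows) + 1]] <- data.frame(
        site = site, t_min = (sv - 1) * 10000 + obs, tide = tide,
        count = cnt, survey_id = paste(site, sv, sep = "_"))
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  list(counts = new("CountSeries", data = d, period = period),
       trueParams = list(presenceCoefs = config@presenceCoefs,
                         abundanceCoefs = config@abundanceCoefs,
                         theta = theta, rho = rho,
                         latentSd = config@latentSd, period = period))
}
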