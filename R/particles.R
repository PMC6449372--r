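# Mirror-reflect depths into [0, depth]; repeats to handle excursions larger
# than the water column.
reflectDepth <- function(z, depth) {
  if (!is.finite(depth)) return(abs(z))
  for (k in 1:20) {
    z <- abs(z)
    over <- z > depth
    if (!any(over)) break
    z[over] <- 2 * depth - z[over]
  }
  clamp(z, 0, depth)
}

#' Advance a particle ensemble by one Langevin step
#'
#' Euler-Maruyama update: `x += u(x, z) dt + sqrt(2 Dh dt) xi_x`,
#' `z += sqrt(2 Dv dt) xi_z` with standard-normal increments drawn from the
#' current RNG stream. Depth is reflected at the surface (`z = 0`) and the
#' bed (`z = depth`). Particles in transit that cross `targetX` during the
#' step arrive, with the crossing time linearly interpolated within the
#' step. Only particles with status `in_transit` move.
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param flow a [FlowField-class].
#' @param dt step, s (> 0).
#' @param targetX arrival boundary, m (`Inf` disables arrivals).
#' @param tNow simulation time at the start of the step, s.
#' @return updated [ParticleEnsemble-class].
#' @export
stepParticles <- function(ensemble, flow, dt, targetX = Inf, tNow = 0) {
  assertThat(dt > 0, "dt must be > 0")
  p <- ensemble@particles
  act <- which(p$status == "in_transit" & p$release_s <= tNow)
  if (!length(act)) return(ensemble)
  x0 <- p$x[act]; z0 <- p$z[act]
  u <- speedAtDepth(flow, clamp(z0, 0, flow@depth))
  if (max(abs(u)) * dt > 50 * flow@depth + 1e5)
    stop("advection step exceeds the domain scale; reduce dt", call. = FALSE)
  n <- length(act)
  x1 <- x0 + u * dt + sqrt(2 * flow@Dh * dt) * rnorm(n)
  z1 <- reflectDepth(z0 + sqrt(2 * flow@Dv * dt) * rnorm(n), flow@depth)
  p$x[act] <- x1
  p$z[act] <- z1
  if (is.finite(targetX)) {
    hit <- which(x0 < targetX & x1 >= targetX)
    if (length(hit)) {
      frac <- (targetX - x0[hit]) / pmax(x1[hit] - x0[hit], 1e-12)
      idx <- act[hit]
      p$status[idx] <- "arrived"
      p$arrival_s[idx] <- tNow + clamp(frac, 0, 1) * dt
      p$x[idx] <- targetX
    }
  }
  new("ParticleEnsemble", particles = p, meta = ensemble@meta)
}

#' Run a trickle-release transit simulation
#'
#' Releases `particlesPerStep` particles every `stepMin` minutes at times
#' `0, step, ..., activeWindowMin` (the flood gate), integrates every
#' particle with [stepParticles()] until `totalTime`, and records
#' first-crossing arrival times at `targetX`.
#'
#' @param schedule a [ReleaseSchedule-class].
#' @param flow a [FlowField-class].
#' @param targetX arrival boundary, m (downstream of the release).
#' @param totalTime simulation length, s.
#' @param dt integration step, s (default 5).
#' @param seed RNG seed.
#' @return a [ParticleEnsemble-class].
#' @export
runRelease <- function(schedule, flow, targetX, totalTime, dt = 5,
                       seed = 1L) {
  assertThat(targetX > schedule@releaseX, "target must be downstream of release")
  set.seed(seed)
  relTimes <- seq(0, schedule@activeWindowMin * 60, by = schedule@stepMin * 60)
  nRel <- length(relTimes) * schedule@particlesPerStep
  if (nRel == 0) {
    return(new("ParticleEnsemble",
               particles = data.frame(id = integer(0), x = numeric(0),
                                      z = numeric(0), release_s = numeric(0),
                                      status = character(0),
                                      arrival_s = numeric(0)),
               meta = list(schedule = schedule, targetX = targetX, dt = dt)))
  }
  p <- data.frame(id = seq_len(nRel),
                  x = schedule@releaseX,
                  z = schedule@releaseZ,
                  release_s = rep(relTimes, each = schedule@particlesPerStep),
                  status = "in_transit",
                  arrival_s = NA_real_)
  ens <- new("ParticleEnsemble", particles = p,
             meta = list(schedule = schedule, targetX = targetX, dt = dt,
                         nReleaseEvents = length(relTimes), seed = seed))
  t <- 0
  while (t < totalTime) {
    step <- min(dt, totalTime - t)
    ens <- stepParticles(ens, flow, step, targetX = targetX, tNow = t)
    t <- t + step
  }
  ens
}

#' Summarise transit times of an ensemble
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param quantiles probabilities reported (default 0.25, 0.5, 0.75, 0.9).
#' @return list: fractionArrived, n, and (when any arrived) mean, median and
#'   quantiles of transit time in seconds, else NA statistics.
#' @export
transitSummary <- function(ensemble,
                           quantiles = c(0.25, 0.5, 0.75, 0.9)) {
  p <- ensemble@particles
  arr <- p[p$status == "arrived", ]
  frac <- if (nrow(p)) nrow(arr) / nrow(p) else 0
  if (!nrow(arr)) {
    return(list(fractionArrived = frac, n = nrow(p), mean = NA_real_,
                median = NA_real_, quantiles = setNames(
                  rep(NA_real_, length(quantiles)), quantiles)))
  }
  tt <- arr$arrival_s - arr$release_s
  list(fractionArrived = frac, n = nrow(p), mean = mean(tt),
       median = median(tt),
       quantiles = quantile(tt, probs = quantiles, names = TRUE))
}
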