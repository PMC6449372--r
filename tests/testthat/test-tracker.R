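test_that("kalman step: prediction, exact-observation limit, matrix oracle", {
  st <- list(m = c(0, 0, 1, 1), P = diag(4))
  pred <- kalmanStep(st, dt = 1)
  expect_equal(pred$m[1:2], c(1, 1))

  upd <- kalmanStep(st, dt = 1, observation = c(3, -2), r = 1e-9)
  expect_equal(upd$m[1:2], c(3, -2), tolerance = 1e-6)

  set.seed(10)
  P0 <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  st2 <- list(m = rnorm(4), P = P0)
  mine <- kalmanStep(st2, dt = 0.2, observation = c(0.5, -0.1), q = 2, r = 0.3)
  oracle <- kalmanOracle(st2$m, st2$P, dt = 0.2, q = 2, r = 0.3,
                         obs = c(0.5, -0.1))
  expect_lt(max(abs(mine$m - oracle$m)), 1e-10)
  expect_lt(max(abs(mine$P - oracle$P)), 1e-10)

  bad <- list(m = rep(0, 4), P = diag(c(1, 1, 1, -1)))
  expect_error(kalmanStep(bad, 1), "positive-definite")
})

test_that("association is gated and globally cost-minimal", {
  expect_equal(associateDetections(matrix(c(0, 0), 1), matrix(c(1, 0), 1), 2), 1L)
  expect_true(is.na(associateDetections(matrix(c(0, 0), 1),
                                        matrix(c(10, 0), 1), 2)))
  set.seed(11)
  for (rep in 1:50) {
    nT <- sample(2:4, 1); nD <- sample(2:4, 1)
    pred <- matrix(runif(nT * 2, 0, 10), nT)
    det <- matrix(runif(nD * 2, 0, 10), nD)
    a <- associateDetections(pred, det, gateRadius = 100)
    cost <- sqrt(outer(pred[, 1], det[, 1], "-")^2 +
                   outer(pred[, 2], det[, 2], "-")^2)
    mine <- sum(cost[cbind(which(!is.na(a)), a[!is.na(a)])])
    expect_equal(mine, bruteAssignmentCost(cost), tolerance = 1e-10)
  }
})

test_that("a single noiseless bird compiles into one accurate track", {
  cfg <- quietScene(duration = 8, nBirds = 1L)
  sim <- generateWakeVideo(cfg)
  det <- detectTargets(sim$frames, diffThreshold = 0.05)
  trk <- compileTracks(det, fps = cfg@fps, scale = cfg@gsd,
                       gateRadius = 2 * cfg@birdSpeed / cfg@fps)
  p <- trackPoints(trk)
  expect_equal(length(unique(p$track_id)), 1)
  bt <- sim$truth@birdTracks
  m <- merge(p, bt, by = "frame")
  rmse <- sqrt(mean((m$x_m.x - m$x_m.y)^2 + (m$y_m.x - m$y_m.y)^2))
  expect_lt(rmse, 1 * cfg@gsd)
  expect_equal(nrow(p), nFrames(sim$frames) - 1)
})

test_that("two crossing birds keep their identities", {
  # deterministic crossing paths fed straight to the tracker
  fps <- 5; scale <- 0.5
  frames <- 1:30
  d1 <- data.frame(frame = frames, x_px = 10 + 2 * (frames - 1), y_px = 20)
  d2 <- data.frame(frame = frames, x_px = 10 + 2 * (frames - 1),
                   y_px = 50 - 1 * (frames - 1))
  det <- rbind(d1, d2)
  trk <- compileTracks(det, fps = fps, scale = scale, gateRadius = 1.2,
                       r = 0.1)
  p <- trackPoints(trk)
  expect_equal(length(unique(p$track_id)), 2)
  for (id in unique(p$track_id)) {
    tr <- p[p$track_id == id, ]
    expect_equal(nrow(tr), 30)
    # y stays on one path: either constant 20*scale or the descending line
    yTrue1 <- rep(20 * scale, 30)
    yTrue2 <- (50 - (frames - 1)) * scale
    err1 <- mean(abs(tr$y_m - yTrue1)); err2 <- mean(abs(tr$y_m - yTrue2))
    expect_lt(min(err1, err2), 0.5)
  }
  expect_equal(nrow(trackPoints(compileTracks(
    data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0)),
    fps = fps, scale = scale))), 0)
  expect_error(compileTracks(det, scale = 0.5), "fps")
})

test_that("duration filter is strict and idempotent", {
  mk <- function(id, dur, fps = 25) {
    n <- round(dur * fps) + 1
    data.frame(track_id = id, frame = seq_len(n), t_s = (seq_len(n) - 1) / fps,
               x_m = seq_len(n), y_m = 0, observed = TRUE)
  }
  ts <- new("TrackSet", points = rbind(mk(1, 1.9), mk(2, 2.0), mk(3, 2.04)),
            fps = 25, scale = 1)
  kept <- filterTracksByDuration(ts, 2)
  expect_equal(unique(trackPoints(kept)$track_id), 3)
  again <- filterTracksByDuration(kept, 2)
  expect_identical(trackPoints(again), trackPoints(kept))
  all3 <- filterTracksByDuration(ts, 0)
  expect_setequal(unique(trackPoints(all3)$track_id), c(1, 2, 3))
})

test_that("trajectory metrics: line, arc, speed, rigid invariance", {
  straight <- data.frame(t_s = 0:10 / 5, x_m = 0:10, y_m = 0)
  m <- trajectoryMetrics(straight)
  expect_equal(m$sinuosity, 1)
  expect_true(all(abs(m$turningAngles) < 1e-12))
  expect_equal(m$meanSpeed, 10 / 2)

  th <- seq(0, pi, length.out = 100)
  arc <- data.frame(t_s = seq_along(th), x_m = cos(th), y_m = sin(th))
  ma <- trajectoryMetrics(arc)
  expect_equal(ma$sinuosity, pi / 2, tolerance = 1e-3)

  fast <- data.frame(t_s = c(0, 0.5), x_m = c(0, 2), y_m = 0)
  expect_equal(trajectoryMetrics(fast)$meanSpeed, 4)
  expect_error(trajectoryMetrics(fast[1, , drop = FALSE]), "2 points")

  # rigid rotation + translation leaves the metrics unchanged
  a <- 0.7; R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  xy <- as.matrix(arc[, c("x_m", "y_m")]) %*% t(R)
  rot <- data.frame(t_s = arc$t_s, x_m = xy[, 1] + 5, y_m = xy[, 2] - 3)
  mr <- trajectoryMetrics(rot)
  expect_equal(mr$pathLength, ma$pathLength)
  expect_equal(mr$sinuosity, ma$sinuosity)
  expect_equal(mr$turningAngles, ma$turningAngles)

  # stationary track flags infinite sinuosity
  still <- data.frame(t_s = 0:2, x_m = c(0, 1, 0), y_m = 0)
  expect_equal(trajectoryMetrics(still)$sinuosity, Inf)
})

test_that("shedding frequency counts distinct crossing tracks once", {
  mk <- function(id, xs, t0 = 0) data.frame(
    track_id = id, frame = seq_along(xs), t_s = t0 + seq_along(xs) * 0.2,
    x_m = xs, y_m = 0, observed = TRUE)
  # 12 tracks crossing x = 5 within 60 s
  pts <- do.call(rbind, lapply(1:12, function(i) mk(i, seq(0, 10, by = 1),
                                                    t0 = i)))
  ts <- new("TrackSet", points = pts, fps = 5, scale = 1)
  expect_equal(estimateSheddingFrequency(ts, 5, 60), 12)
  # a track that re-crosses still counts once
  wob <- mk(13, c(0, 6, 4, 8, 10))
  ts2 <- new("TrackSet", points = rbind(pts, wob), fps = 5, scale = 1)
  expect_equal(estimateSheddingFrequency(ts2, 5, 60), 13)
  # a track that never crosses does not count
  ts3 <- new("TrackSet", points = rbind(pts, mk(14, seq(6, 10))), fps = 5,
             scale = 1)
  expect_equal(estimateSheddingFrequency(ts3, 5, 60), 12)
  expect_error(estimateSheddingFrequency(ts, 5, 0), "duration")
})
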