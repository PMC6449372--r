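# Constant-velocity Kalman filter pieces. State is (x, y, vx, vy) in metres
# and m/s with a 4x4 covariance; process noise is white acceleration with
# spectral density q (m^2/s^3), observation noise is isotropic with sd r (m).

cvMatrices <- function(dt, q) {
  F <- diag(4)
  F[1, 3] <- dt; F[2, 4] <- dt
  q11 <- q * dt^3 / 3; q13 <- q * dt^2 / 2; q33 <- q * dt
  Q <- matrix(0, 4, 4)
  Q[1, 1] <- Q[2, 2] <- q11
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- q13
  Q[3, 3] <- Q[4, 4] <- q33
  list(F = F, Q = Q)
}

newTrackState <- function(x, y, r = 0.5, v0sd = 5) {
  list(m = c(x, y, 0, 0), P = diag(c(r^2, r^2, v0sd^2, v0sd^2)))
}

#' One Kalman predict (and optional update) step
#'
#' Standard constant-velocity predict; if an observation is supplied, the
#' usual Kalman update follows.
#'
#' @param state list with mean `m` (length 4) and covariance `P` (4x4 PD).
#' @param dt time step, s (> 0).
#' @param observation numeric (x, y) in metres, or `NULL` for predict-only.
#' @param q process-noise spectral density, m^2/s^3.
#' @param r observation noise sd, m.
#' @return updated state list (m, P).
#' @export
kalmanStep <- function(state, dt, observation = NULL, q = 1, r = 0.5) {
  assertThat(dt > 0, "dt must be > 0")
  ev <- eigen(state$P, symmetric = TRUE, only.values = TRUE)$values
  assertThat(all(ev > 0), "state covariance must be positive-definite")
  mats <- cvMatrices(dt, q)
  m <- as.numeric(mats$F %*% state$m)
  P <- mats$F %*% state$P %*% t(mats$F) + mats$Q
  if (!is.null(observation)) {
    Hm <- cbind(diag(2), matrix(0, 2, 2))
    R <- diag(2) * r^2
    S <- Hm %*% P %*% t(Hm) + R
    K <- P %*% t(Hm) %*% solve(S)
    m <- m + as.numeric(K %*% (observation - Hm %*% m))
    P <- (diag(4) - K %*% Hm) %*% P
    P <- (P + t(P)) / 2
  }
  list(m = m, P = P)
}

# O(n^3) Hungarian algorithm (Jonker-style shortest augmenting path) on a
# square or rectangular cost matrix. Returns, for each row, the assigned
# column (NA if unassigned, only possible when rows > cols).
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  transposed <- FALSE
  if (n > m) { cost <- t(cost); n <- nrow(cost); m <- ncol(cost)
               transposed <- TRUE }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)           # p[j]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                    # columns are 1-indexed with virtual col 1
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(m + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in 2:(m + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  if (transposed) {
    out <- rep(NA_integer_, m)
    out[assign] <- seq_len(n)
    out
  } else assign
}

#' Gated one-to-one assignment of detections to predicted tracks
#'
#' Solves the globally cost-minimal one-to-one assignment on Euclidean
#' distances (Hungarian algorithm), then voids any match whose distance
#' exceeds the gate. Unmatched detections should spawn new tracks and
#' unmatched tracks accrue a miss (handled by [compileTracks()]).
#'
#' @param predicted matrix (nTracks x 2) of predicted positions, m.
#' @param detections matrix (nDetections x 2) of observed positions, m.
#' @param gateRadius gate, m (> 0).
#' @return integer vector, one entry per track: index of the matched
#'   detection or NA.
#' @export
associateDetections <- function(predicted, detections, gateRadius) {
  assertThat(gateRadius > 0, "gateRadius must be > 0")
  nT <- nrow(predicted); nD <- nrow(detections)
  if (nT == 0 || nD == 0) return(rep(NA_integer_, nT))
  d <- sqrt(outer(predicted[, 1], detections[, 1], "-")^2 +
              outer(predicted[, 2], detections[, 2], "-")^2)
  big <- max(gateRadius * 1e6, 1e9)
  dg <- ifelse(d > gateRadius, big, d)
  a <- hungarian(dg)
  ok <- !is.na(a) & dg[cbind(seq_len(nT), ifelse(is.na(a), 1L, a))] < big
  a[!ok] <- NA_integer_
  a
}

#' Compile detections into tracks with a Kalman filter
#'
#' Runs predict / gated Hungarian association / update frame by frame over
#' tern-labelled detections. Unmatched detections spawn tracks; a track is
#' closed after `maxMisses` consecutive missed frames. Positions are
#' reported in metres via the ground-sample distance.
#'
#' @param detections data.frame with columns `frame`, `x_px`, `y_px`, and
#'   optionally `class` (rows with a class other than `"tern"` are dropped).
#' @param fps frames per second (required).
#' @param scale metres per pixel (required).
#' @param q,r Kalman process / observation noise (see [kalmanStep()]).
#' @param gateRadius association gate, m.
#' @param maxMisses consecutive misses before a track closes (default 5).
#' @return a [TrackSet-class]. Track points are recorded at observed frames
#'   only; `observed` is TRUE for updated points.
#' @export
compileTracks <- function(detections, fps, scale, q = 1, r = 0.25,
                          gateRadius = 5, maxMisses = 5L) {
  if (missing(fps) || is.null(fps)) stop("fps is required", call. = FALSE)
  if (missing(scale) || is.null(scale)) stop("scale (m per px) is required",
                                             call. = FALSE)
  if (!is.null(detections$class))
    detections <- detections[detections$class == "tern", , drop = FALSE]
  empty <- new("TrackSet",
               points = data.frame(track_id = integer(0), frame = integer(0),
                                   t_s = numeric(0), x_m = numeric(0),
                                   y_m = numeric(0), observed = logical(0)),
               fps = fps, scale = scale)
  if (is.null(detections) || nrow(detections) == 0) return(empty)
  dt <- 1 / fps
  frames <- seq(min(detections$frame), max(detections$frame))
  active <- list()   # each: list(id, state, misses, lastFrame)
  nextId <- 1L
  pts <- list()
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    obs <- cbind(det$x_px, det$y_px) * scale
    if (length(active)) {
      pred <- lapply(active, function(tr)
        kalmanStep(tr$state, dt * (f - tr$lastFrame), NULL, q = q, r = r))
      pp <- do.call(rbind, lapply(pred, function(s) s$m[1:2]))
      a <- associateDetections(pp, obs, gateRadius)
      for (i in seq_along(active)) {
        if (!is.na(a[i])) {
          st <- kalmanStep(active[[i]]$state, dt * (f - active[[i]]$lastFrame),
                           obs[a[i], ], q = q, r = r)
          active[[i]]$state <- st
          active[[i]]$misses <- 0L
          active[[i]]$lastFrame <- f
          pts[[length(pts) + 1]] <- data.frame(
            track_id = active[[i]]$id, frame = f, t_s = (f - 1) * dt,
            x_m = st$m[1], y_m = st$m[2], observed = TRUE)
        } else {
          active[[i]]$misses <- active[[i]]$misses + 1L
        }
      }
      active <- Filter(function(tr) tr$misses <= maxMisses, active)
      matched <- a[!is.na(a)]
    } else matched <- integer(0)
    if (nrow(det)) {
      for (j in setdiff(seq_len(nrow(det)), matched)) {
        st <- newTrackState(obs[j, 1], obs[j, 2], r = r)
        active[[length(active) + 1]] <- list(id = nextId, state = st,
                                             misses = 0L, lastFrame = f)
        pts[[length(pts) + 1]] <- data.frame(
          track_id = nextId, frame = f, t_s = (f - 1) * dt,
          x_m = obs[j, 1], y_m = obs[j, 2], observed = TRUE)
        nextId <- nextId + 1L
      }
    }
  }
  p <- do.call(rbind, pts)
  p <- p[order(p$track_id, p$frame), ]
  rownames(p) <- NULL
  new("TrackSet", points = p, fps = fps, scale = scale)
}

#' Keep only trajectories longer than a duration threshold
#'
#' Strict inequality: a track is kept when its duration (last minus first
#' timestamp) exceeds `minDuration` ("over 2 s").
#'
#' @param tracks a [TrackSet-class].
#' @param minDuration seconds (default 2).
#' @return filtered [TrackSet-class].
#' @export
filterTracksByDuration <- function(tracks, minDuration = 2) {
  assertThat(minDuration >= 0, "minDuration must be >= 0")
  p <- tracks@points
  if (!nrow(p)) return(tracks)
  dur <- tapply(p$t_s, p$track_id, function(t) max(t) - min(t))
  keep <- names(dur)[dur > minDuration]
  new("TrackSet", points = p[p$track_id %in% as.numeric(keep), , drop = FALSE],
      fps = tracks@fps, scale = tracks@scale)
}

#' Trajectory metrics for one track
#'
#' @param track data.frame of one track's points (t_s, x_m, y_m), or a
#'   [TrackSet-class] with a single track.
#' @return list: duration (s), pathLength (m), netDisplacement (m),
#'   sinuosity (path/chord; `Inf` when the chord is < 1e-9 m),
#'   meanSpeed (m/s), turningAngles (radians at interior vertices).
#' @export
trajectoryMetrics <- function(track) {
  if (is(track, "TrackSet")) track <- track@points
  assertThat(nrow(track) >= 2, "need at least 2 points")
  track <- track[order(track$t_s), ]
  dx <- diff(track$x_m); dy <- diff(track$y_m)
  seg <- sqrt(dx^2 + dy^2)
  pathLength <- sum(seg)
  net <- sqrt((track$x_m[nrow(track)] - track$x_m[1])^2 +
                (track$y_m[nrow(track)] - track$y_m[1])^2)
  duration <- max(track$t_s) - min(track$t_s)
  turning <- if (nrow(track) >= 3) {
    h <- atan2(dy, dx)
    d <- diff(h)
    atan2(sin(d), cos(d))           # wrap to (-pi, pi]
  } else numeric(0)
  list(duration = duration, pathLength = pathLength, netDisplacement = net,
       sinuosity = if (net < 1e-9) Inf else pathLength / net,
       meanSpeed = pathLength / duration, turningAngles = turning)
}

#' Metrics for every track in a set
#'
#' @param tracks a [TrackSet-class].
#' @return data.frame, one row per track with the scalar metrics.
#' @export
trackSetMetrics <- function(tracks) {
  p <- tracks@points
  ids <- unique(p$track_id)
  do.call(rbind, lapply(ids, function(id) {
    m <- trajectoryMetrics(p[p$track_id == id, ])
    data.frame(track_id = id, duration = m$duration,
               path_length = m$pathLength, net_displacement = m$netDisplacement,
               sinuosity = m$sinuosity, mean_speed = m$meanSpeed,
               mean_abs_turn = if (length(m$turningAngles))
                 mean(abs(m$turningAngles)) else NA_real_)
  }))
}

#' Estimate the surface-eddy shedding frequency from foam tracks
#'
#' Counts distinct tracked surface features whose trajectory crosses a fixed
#' cross-stream line (each track id counted once, however many times it
#' re-crosses) and divides by the observation duration.
#'
#' @param tracks a [TrackSet-class] of surface-feature (foam) tracks.
#' @param lineX the line's streamwise position, m.
#' @param duration observation duration, s (> 0).
#' @return shedding frequency, events per minute.
#' @export
estimateSheddingFrequency <- function(tracks, lineX, duration) {
  assertThat(duration > 0, "duration must be > 0")
  p <- tracks@points
  if (!nrow(p)) return(0)
  crossed <- vapply(split(p, p$track_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    any(diff(sign(tr$x_m - lineX)) != 0)
  }, logical(1))
  sum(crossed) / duration * 60
}
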