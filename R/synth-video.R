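# Rendering primitives shared by the scene generator and the chip generator.
# Appearance model: sea surface = mid-grey with smooth spatial texture; birds
# = compact bright Gaussian blobs (sigma = birdSizePx / 3); foam = larger
# fractal-textured patches with a soft super-Gaussian envelope; glint =
# 1-2 px single-frame bright speckles.

BG_MEAN <- 0.45
BG_TEXTURE_SD <- 0.03
BIRD_CONTRAST <- 0.35
FOAM_BASE_CONTRAST <- 0.18
FOAM_TEXTURE_CONTRAST <- 0.18
GLINT_CONTRAST <- 0.45

renderBackground <- function(H, W) {
  BG_MEAN + BG_TEXTURE_SD * smoothNoise(H, W, roughness = 2)
}

# Add a Gaussian blob centred at (row = cy, col = cx), in place.
addBirdBlob <- function(img, cx, cy, sizePx, contrast = BIRD_CONTRAST) {
  s <- sizePx / 3
  r <- ceiling(3 * s)
  H <- nrow(img); W <- ncol(img)
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(img)
  dy <- rows - cy
  dx <- cols - cx
  blob <- contrast * exp(-(outer(dy^2, dx^2, "+")) / (2 * s^2))
  img[rows, cols] <- img[rows, cols] + blob
  img
}

# Pre-generate one foam patch: a toroidal fractal texture plus envelope
# parameters; the texture window is cyclically shifted over time so the
# patch slowly deforms as it advects.
makeFoamPatch <- function(sizePx) {
  texSide <- as.integer(ceiling(sizePx * 2))
  list(tex = smoothNoise(texSide, texSide, roughness = 1),
       texSide = texSide,
       phase = runif(2, 0, texSide),
       drift = runif(2, 0.1, 0.3) * sample(c(-1, 1), 2, replace = TRUE))
}

# Add a foam patch centred at (cx, cy) at time index 'frame', in place.
addFoamPatch <- function(img, patch, cx, cy, sizePx, frame) {
  r <- sizePx / 2
  rr <- ceiling(1.6 * r)
  H <- nrow(img); W <- ncol(img)
  if (floor(cy - rr) > H || ceiling(cy + rr) < 1 ||
      floor(cx - rr) > W || ceiling(cx + rr) < 1) return(img)
  rows <- max(1L, floor(cy - rr)):min(H, ceiling(cy + rr))
  cols <- max(1L, floor(cx - rr)):min(W, ceiling(cx + rr))
  dy <- rows - cy
  dx <- cols - cx
  env <- exp(-((outer(dy^2, dx^2, "+")) / (2 * (r / 1.5)^2))^1.5)
  ts <- patch$texSide
  ti <- (round(outer(dy, dx * 0, "+") + cy + patch$phase[1] +
                 patch$drift[1] * frame) %% ts) + 1
  tj <- (round(outer(dy * 0, dx, "+") + cx + patch$phase[2] +
                 patch$drift[2] * frame) %% ts) + 1
  tex <- matrix(patch$tex[cbind(as.vector(ti), as.vector(tj))],
                length(dy), length(dx))
  img[rows, cols] <- img[rows, cols] +
    env * (FOAM_BASE_CONTRAST + pmax(tex, 0) * FOAM_TEXTURE_CONTRAST * 1.2)
  img
}

# Correlated-random-walk step angles: wrapped-normal turning with sd derived
# from the target sinuosity (sd = sqrt(2 log S) per step; S = 1 gives
# straight flight). A heuristic mapping, documented in the vignette.
turnSdFromSinuosity <- function(S) sqrt(2 * log(max(S, 1)))

#' Generate a synthetic overhead wake video with ground truth
#'
#' Renders a seeded image sequence emulating a hover survey over a
#' structure's flood wake: birds as compact bright blobs flying correlated
#' random walks at constant speed, foam patches shed periodically on
#' alternating sides of the wake midline and advecting downstream (the
#' vortex-street signature), ambient foam, and single-frame sun-glint
#' speckles. The static textured background is generated first from the
#' seed, so an empty scene with the same seed reproduces the background of a
#' populated one.
#'
#' @param config a [SceneConfig-class].
#' @return list with `frames` (a [FrameSequence-class]) and `truth`
#'   (a [SceneGroundTruth-class]). Bird and foam ids are 0-based.
#' @export
generateWakeVideo <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  H <- config@frameSize[1]; W <- config@frameSize[2]
  nF <- as.integer(round(config@fps * config@duration))
  assertThat(nF >= 1, "fps * duration must give at least one frame")
  set.seed(config@seed)
  bg <- renderBackground(H, W)

  dt <- 1 / config@fps
  stepPx <- config@birdSpeed * dt / config@gsd
  turnSd <- turnSdFromSinuosity(config@birdSinuosity)
  margin <- config@birdSizePx

  # bird paths (px coordinates, x = col, y = row)
  birdX <- matrix(NA_real_, nF, max(config@nBirds, 1))
  birdY <- birdX
  if (config@nBirds > 0) {
    x <- runif(config@nBirds, margin, W - margin)
    y <- runif(config@nBirds, margin, H - margin)
    th <- runif(config@nBirds, 0, 2 * pi)
    for (f in seq_len(nF)) {
      birdX[f, seq_len(config@nBirds)] <- x
      birdY[f, seq_len(config@nBirds)] <- y
      th <- th + rnorm(config@nBirds, 0, turnSd)
      nx <- x + stepPx * cos(th)
      ny <- y + stepPx * sin(th)
      flipx <- nx < margin | nx > W - margin
      flipy <- ny < margin | ny > H - margin
      th[flipx] <- pi - th[flipx]
      th[flipy] <- -th[flipy]
      x <- clamp(x + stepPx * cos(th), margin, W - margin)
      y <- clamp(y + stepPx * sin(th), margin, H - margin)
    }
  }

  # foam: shed eddies (alternating sides of the midline) + ambient patches
  foam <- list()
  if (config@sheddingFrequency > 0) {
    interval <- 60 / config@sheddingFrequency
    sheds <- seq(0, config@duration, by = interval)
    advPx <- config@advectionSpeed / config@gsd
    for (i in seq_along(sheds)) {
      side <- if (i %% 2 == 0) 1 else -1
      foam[[length(foam) + 1]] <- c(makeFoamPatch(config@foamSizePx), list(
        t0 = sheds[i], x0 = 0.05 * W,
        y0 = H / 2 + side * (0.12 * H) + runif(1, -0.02, 0.02) * H,
        vx = advPx, vy = runif(1, -0.05, 0.05) * advPx))
    }
  }
  if (config@nFoamPatches > 0) {
    advPx <- config@advectionSpeed / config@gsd
    for (i in seq_len(config@nFoamPatches)) {
      foam[[length(foam) + 1]] <- c(makeFoamPatch(config@foamSizePx), list(
        t0 = 0, x0 = runif(1, 0, W), y0 = runif(1, 0.1 * H, 0.9 * H),
        vx = advPx, vy = runif(1, -0.05, 0.05) * advPx))
    }
  }

  frames <- array(0, dim = c(H, W, nF))
  birdRows <- list(); foamRows <- list(); glintRows <- list()
  for (f in seq_len(nF)) {
    img <- bg
    tNow <- (f - 1) * dt
    if (config@nBirds > 0) {
      for (b in seq_len(config@nBirds)) {
        img <- addBirdBlob(img, birdX[f, b], birdY[f, b], config@birdSizePx)
        birdRows[[length(birdRows) + 1]] <- c(b - 1, f, birdX[f, b], birdY[f, b])
      }
    }
    for (p in seq_along(foam)) {
      fp <- foam[[p]]
      age <- tNow - fp$t0
      if (age < 0) next
      cx <- fp$x0 + fp$vx * age
      cy <- fp$y0 + fp$vy * age
      if (cx < -config@foamSizePx || cx > W + config@foamSizePx ||
          cy < -config@foamSizePx || cy > H + config@foamSizePx) next
      img <- addFoamPatch(img, fp, cx, cy, config@foamSizePx, f)
      foamRows[[length(foamRows) + 1]] <- c(p - 1, f, cx, cy)
    }
    if (config@glintRate > 0) {
      ng <- rpois(1, config@glintRate)
      if (ng > 0) {
        gx <- runif(ng, 1, W); gy <- runif(ng, 1, H)
        for (g in seq_len(ng)) {
          rows <- round(gy[g]):min(H, round(gy[g]) + sample(0:1, 1))
          cols <- round(gx[g]):min(W, round(gx[g]) + sample(0:1, 1))
          img[rows, cols] <- img[rows, cols] + GLINT_CONTRAST
          glintRows[[length(glintRows) + 1]] <- c(f, gx[g], gy[g])
        }
      }
    }
    frames[, , f] <- clamp(img, 0, 1)
  }

  toDf <- function(rows, nm) {
    if (!length(rows)) {
      return(stats::setNames(data.frame(numeric(0), numeric(0), numeric(0),
                                        numeric(0), numeric(0), numeric(0)), nm))
    }
    m <- do.call(rbind, rows)
    data.frame(id = m[, 1], frame = m[, 2],
               x_m = (m[, 3] - 0.5) * config@gsd,
               y_m = (m[, 4] - 0.5) * config@gsd,
               x_px = m[, 3], y_px = m[, 4])
  }
  nm6 <- c("id", "frame", "x_m", "y_m", "x_px", "y_px")
  glint <- if (length(glintRows)) {
    g <- do.call(rbind, glintRows)
    data.frame(frame = g[, 1], x_px = g[, 2], y_px = g[, 3])
  } else data.frame(frame = numeric(0), x_px = numeric(0), y_px = numeric(0))

  list(frames = new("FrameSequence", pixels = frames, fps = config@fps,
                    gsd = config@gsd),
       truth = new("SceneGroundTruth",
                   birdTracks = toDf(birdRows, nm6),
                   foamTracks = toDf(foamRows, nm6),
                   glintEvents = glint,
                   sheddingFrequency = config@sheddingFrequency))
}

#' Generate labelled target chips for classifier training and validation
#'
#' Renders fixed-side chips with the same appearance model as
#' [generateWakeVideo()] (textured sea-surface background; bird = bright
#' Gaussian blob; foam = fractal-textured patch), centred with small random
#' jitter, and normalised to \[0, 1\] exactly as [extractChip()] normalises
#' detections cut from frames.
#'
#' @param n number of chips.
#' @param class `"tern"` or `"foam"`.
#' @param side chip side, px.
#' @param birdSizePx,foamSizePx object sizes, px.
#' @param seed RNG seed.
#' @return list of `side x side` matrices in \[0, 1\].
#' @export
generateChips <- function(n, class = c("tern", "foam"), side = 32L,
                          birdSizePx = 6, foamSizePx = 24, seed = 1L) {
  class <- match.arg(class)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    img <- renderBackground(side, side)
    c0 <- (side + 1) / 2
    if (class == "tern") {
      img <- addBirdBlob(img, c0 + runif(1, -1.5, 1.5), c0 + runif(1, -1.5, 1.5),
                         birdSizePx)
    } else {
      patch <- makeFoamPatch(foamSizePx)
      img <- addFoamPatch(img, patch, c0 + runif(1, -2, 2), c0 + runif(1, -2, 2),
                          foamSizePx, frame = sample.int(100, 1))
    }
    img <- img + 0.01 * matrix(rnorm(side * side), side, side)
    normalizeChip(img)
  })
}
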