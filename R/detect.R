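#' Frame-to-frame difference mask
#'
#' Marks pixels whose absolute intensity change between two consecutive
#' frames exceeds a threshold, optionally after a small 3x3 morphological
#' opening that suppresses single-pixel glint.
#'
#' @param prev,cur frames as numeric matrices of identical dimensions.
#' @param diffThreshold absolute-difference threshold (same units as pixels).
#' @param open logical; apply a 3x3 binary opening to the mask (default TRUE).
#' @return logical matrix, TRUE where motion was detected.
#' @export
frameDifference <- function(prev, cur, diffThreshold = 0.1, open = TRUE) {
  if (!identical(dim(prev), dim(cur)))
    stop(sprintf("frame dimensions differ: %s vs %s",
                 paste(dim(prev), collapse = "x"),
                 paste(dim(cur), collapse = "x")), call. = FALSE)
  mask <- abs(cur - prev) > diffThreshold
  if (open && any(mask)) {
    kern <- EBImage::makeBrush(3, shape = "box")
    mask <- EBImage::opening(matrix(as.numeric(mask), nrow(mask)), kern) > 0.5
  }
  mask
}

# 8-connected components of a binary mask via the pixel adjacency graph.
# Returns an integer label matrix (0 = background).
labelComponents8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  H <- nrow(mask)
  pos <- match(idx, idx)
  inMask <- logical(length(mask))
  inMask[idx] <- TRUE
  rows <- ((idx - 1) %% H) + 1
  cols <- ((idx - 1) %/% H) + 1
  edges <- list()
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    nr <- rows + d[1]; nc <- cols + d[2]
    ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= ncol(mask)
    nidx <- (nc[ok] - 1) * H + nr[ok]
    keep <- inMask[nidx]
    if (any(keep))
      edges[[length(edges) + 1]] <- cbind(match(idx[ok][keep], idx),
                                          match(nidx[keep], idx))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Segment a motion mask into detections
#'
#' Finds 8-connected components of the mask and summarises each as a
#' detection with exact pixel-count area, an intensity-weighted centroid
#' computed from the current frame, a bounding box and the mean intensity.
#'
#' @param mask logical matrix from [frameDifference()].
#' @param frame the current frame (numeric matrix) for intensity weighting;
#'   if `NULL`, centroids are unweighted pixel means.
#' @param frameIndex frame number recorded in the output.
#' @return data.frame (frame, x_px, y_px, area, x0, y0, x1, y1,
#'   mean_intensity); empty mask gives zero rows.
#' @export
segmentMask <- function(mask, frame = NULL, frameIndex = NA_integer_) {
  lab <- labelComponents8(mask)
  n <- max(lab)
  out <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                    area = integer(0), x0 = integer(0), y0 = integer(0),
                    x1 = integer(0), y1 = integer(0),
                    mean_intensity = numeric(0))
  if (n == 0) return(out)
  idx <- which(lab > 0)
  H <- nrow(mask)
  rows <- ((idx - 1) %% H) + 1
  cols <- ((idx - 1) %/% H) + 1
  comp <- lab[idx]
  w <- if (is.null(frame)) rep(1, length(idx)) else pmax(frame[idx], 1e-12)
  sw <- tapply(w, comp, sum)
  out <- data.frame(
    frame = frameIndex,
    x_px = as.numeric(tapply(w * cols, comp, sum) / sw),
    y_px = as.numeric(tapply(w * rows, comp, sum) / sw),
    area = as.integer(tapply(rep(1L, length(idx)), comp, sum)),
    x0 = as.integer(tapply(cols, comp, min)),
    y0 = as.integer(tapply(rows, comp, min)),
    x1 = as.integer(tapply(cols, comp, max)),
    y1 = as.integer(tapply(rows, comp, max)),
    mean_intensity = if (is.null(frame)) NA_real_ else
      as.numeric(tapply(frame[idx], comp, mean)))
  rownames(out) <- NULL
  out
}

#' Filter detections by pixel area
#'
#' Keeps detections whose area lies in `[minArea, maxArea]`, preserving
#' order. Used to remove single-pixel sun-glint speckles (below `minArea`)
#' and large foam patches (above `maxArea`) before classification.
#'
#' @param detections data.frame from [segmentMask()].
#' @param minArea,maxArea inclusive bounds, px^2.
#' @return filtered data.frame.
#' @export
sizeFilter <- function(detections, minArea, maxArea) {
  assertThat(minArea <= maxArea, "minArea must be <= maxArea")
  detections[detections$area >= minArea & detections$area <= maxArea, ,
             drop = FALSE]
}

# Linear rescale to [0, 1]; a constant patch maps to all zeros.
normalizeChip <- function(chip) {
  rng <- range(chip)
  if (diff(rng) < .Machine$double.eps) return(chip * 0)
  (chip - rng[1]) / diff(rng)
}

#' Cut a square, intensity-normalised chip around a detection
#'
#' Crops a `chipSide` square centred on the detection centroid, zero-padding
#' where the crop extends past the frame border, and linearly rescales
#' intensities to \[0, 1\] (a constant crop maps to zeros).
#'
#' @param frame numeric matrix.
#' @param detection one-row data.frame with `x_px`, `y_px`.
#' @param chipSide chip side, px.
#' @return `chipSide x chipSide` numeric matrix.
#' @export
extractChip <- function(frame, detection, chipSide = 32L) {
  H <- nrow(frame); W <- ncol(frame)
  half <- (chipSide - 1) / 2
  r0 <- round(detection$y_px - half); c0 <- round(detection$x_px - half)
  chip <- matrix(0, chipSide, chipSide)
  rr <- r0:(r0 + chipSide - 1)
  cc <- c0:(c0 + chipSide - 1)
  okR <- rr >= 1 & rr <= H
  okC <- cc >= 1 & cc <= W
  chip[okR, okC] <- frame[rr[okR], cc[okC]]
  normalizeChip(chip)
}

#' Detect bright surface features (foam) frame by frame
#'
#' Surface tracers such as foam patches are large, bright and persistent, so
#' they are detected per frame rather than by differencing: each frame is
#' Gaussian-smoothed (merging holes in the foam texture), thresholded on
#' intensity, segmented, and filtered to components at least `minArea` px^2.
#' Intended input to [compileTracks()] for shedding-frequency estimation.
#'
#' @param frames a [FrameSequence-class].
#' @param intensityThreshold absolute intensity cut (background here is 0.45
#'   grey, so the default 0.5 sits above the textured sea surface).
#' @param minArea smallest component kept, px^2; default a quarter of the
#'   nominal foam area.
#' @param foamSizePx nominal foam diameter used for the default `minArea`.
#' @param smoothSigma Gaussian blur sigma, px (default 3).
#' @return data.frame of detections across all frames.
#' @export
detectSurfaceFeatures <- function(frames, intensityThreshold = 0.52,
                                  minArea = NULL, foamSizePx = 24,
                                  smoothSigma = 3) {
  stopifnot(is(frames, "FrameSequence"))
  if (is.null(minArea)) minArea <- round(pi * (foamSizePx / 2)^2 / 4)
  out <- vector("list", nFrames(frames))
  for (f in seq_len(nFrames(frames))) {
    fr <- frameAt(frames, f)
    sm <- as.matrix(EBImage::gblur(fr, sigma = smoothSigma))
    det <- segmentMask(sm > intensityThreshold, fr, frameIndex = f)
    out[[f]] <- sizeFilter(det, minArea, Inf)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# A difference mask of a slowly moving blob splits into leading and trailing
# crescents, both offset from the target. Re-localise each detection at the
# brightness-weighted centroid of the current frame within a small window,
# then merge detections that refine to (nearly) the same position.
refineDetections <- function(det, frame, radius) {
  if (!nrow(det)) return(det)
  H <- nrow(frame); W <- ncol(frame)
  med <- median(frame)
  r <- ceiling(radius)
  for (i in seq_len(nrow(det))) {
    rows <- max(1, round(det$y_px[i]) - r):min(H, round(det$y_px[i]) + r)
    cols <- max(1, round(det$x_px[i]) - r):min(W, round(det$x_px[i]) + r)
    w <- pmax(frame[rows, cols] - med, 0)
    if (sum(w) <= 0) next
    det$y_px[i] <- sum(outer(rows, cols * 0, "+") * w) / sum(w)
    det$x_px[i] <- sum(outer(rows * 0, cols, "+") * w) / sum(w)
  }
  # greedy dedup: keep the brighter of any pair closer than the radius
  det <- det[order(-det$mean_intensity), , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      j <- (i + 1):nrow(det)
      dd <- sqrt((det$x_px[j] - det$x_px[i])^2 + (det$y_px[j] - det$y_px[i])^2)
      keep[j[dd < radius]] <- FALSE
    }
  }
  det <- det[keep, , drop = FALSE]
  det[order(det$x_px, det$y_px), , drop = FALSE]
}

#' Detect candidate moving targets across a frame sequence
#'
#' Runs frame differencing against the previous frame, 8-connected
#' segmentation and size filtering over every frame pair of a sequence.
#' Default area bounds derive from the nominal bird blob size: birds are
#' kept within `[0.25, 4] x birdSizePx^2`.
#'
#' @param frames a [FrameSequence-class].
#' @param diffThreshold differencing threshold.
#' @param minArea,maxArea area bounds, px^2; defaults from `birdSizePx`.
#' @param birdSizePx nominal bird diameter used for default bounds.
#' @param open apply morphological opening before segmentation.
#' @param brightOnly drop components whose mean intensity in the current
#'   frame is below the frame median plus `diffThreshold`: a moving target
#'   marks the mask twice, at its new (bright) and vacated (background-level)
#'   positions, and the vacated ghost carries no target (default TRUE).
#' @return data.frame of detections (one row per component per frame,
#'   frames numbered from 2).
#' @export
detectTargets <- function(frames, diffThreshold = 0.1,
                          minArea = NULL, maxArea = NULL, birdSizePx = 6,
                          open = TRUE, brightOnly = TRUE) {
  stopifnot(is(frames, "FrameSequence"))
  if (is.null(minArea)) minArea <- max(2, 0.25 * birdSizePx^2)
  if (is.null(maxArea)) maxArea <- 4 * birdSizePx^2
  if (nFrames(frames) < 2)
    return(segmentMask(matrix(FALSE, 1, 1), NULL, NA_integer_))
  out <- vector("list", nFrames(frames) - 1)
  for (f in 2:nFrames(frames)) {
    cur <- frameAt(frames, f)
    mask <- frameDifference(frameAt(frames, f - 1), cur,
                            diffThreshold, open = open)
    det <- segmentMask(mask, cur, frameIndex = f)
    det <- sizeFilter(det, minArea, maxArea)
    if (brightOnly && nrow(det))
      det <- det[det$mean_intensity > median(cur) + diffThreshold, ,
                 drop = FALSE]
    out[[f - 1]] <- refineDetections(det, cur, radius = birdSizePx)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
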