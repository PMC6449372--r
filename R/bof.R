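#' Dense gradient-orientation descriptors for a chip
#'
#' Computes central-difference gradients, assigns each pixel to one of
#' `nBins` signed orientation bins over \[0, 2*pi), and accumulates
#' magnitude-weighted orientation histograms over a dense grid of square
#' patches at each configured scale (sides `spec$patch`, strides
#' `spec$stride`), each descriptor L2-normalised. Patch sums come from
#' per-bin integral images, so the cost is independent of patch size. A
#' constant chip yields all-zero descriptors (flagged via the `degenerate`
#' attribute).
#'
#' @param chip square numeric matrix (side >= `max(spec$patch)`).
#' @param spec descriptor parameters from [descriptorSpec()].
#' @return matrix, one L2-normalised descriptor per row (`nBins` columns),
#'   with attribute `degenerate = TRUE` when all gradients vanish.
#' @export
computeDescriptors <- function(chip, spec = descriptorSpec()) {
  side <- nrow(chip)
  assertThat(side == ncol(chip), "chip must be square")
  assertThat(side >= max(spec$patch),
             "chip side must cover the largest descriptor patch")
  gx <- (cbind(chip[, -1], chip[, side]) - cbind(chip[, 1], chip[, -side])) / 2
  gy <- (rbind(chip[-1, ], chip[side, ]) - rbind(chip[1, ], chip[-side, ])) / 2
  mag <- sqrt(gx^2 + gy^2)
  nb <- spec$nBins
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi / nb)), nb - 1) + 1
  # per-bin integral images (zero-padded top/left)
  integ <- vector("list", nb)
  for (b in seq_len(nb)) {
    m <- mag * (bin == b)
    ii <- apply(m, 2, cumsum)             # cumulative down rows
    ii <- t(apply(ii, 1, cumsum))         # then across columns
    integ[[b]] <- rbind(0, cbind(0, ii))  # zero-padded top/left
  }
  perScale <- vector("list", length(spec$patch))
  for (sc in seq_along(spec$patch)) {
    p <- spec$patch[sc]
    # grid of top-left corners, centred so a 180-degree rotation maps the
    # grid onto itself (required for the rotation property of the multiset)
    starts <- seq(1L, side - p + 1L, by = spec$stride[sc])
    starts <- starts + (side - p + 1L - max(starts)) %/% 2L
    grid <- expand.grid(r = starts, c = starts)
    desc <- matrix(0, nrow(grid), nb)
    for (b in seq_len(nb)) {
      I <- integ[[b]]
      desc[, b] <- I[cbind(grid$r + p, grid$c + p)] -
        I[cbind(grid$r, grid$c + p)] - I[cbind(grid$r + p, grid$c)] +
        I[cbind(grid$r, grid$c)]
    }
    perScale[[sc]] <- desc
  }
  desc <- do.call(rbind, perScale)
  nrm <- sqrt(rowSums(desc^2))
  pos <- nrm > 0
  desc[pos, ] <- desc[pos, , drop = FALSE] / nrm[pos]
  attr(desc, "degenerate") <- !any(pos)
  attr(desc, "spec") <- spec
  desc
}

# k-means++ seeding on the current RNG stream.
kmeansPlusPlus <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    pr <- d2 / sum(d2)
    if (all(d2 == 0)) pr <- rep(1 / n, n)  # all-duplicate degenerate case
    centers[j, ] <- x[sample.int(n, 1, prob = pr), ]
    nd <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' Build a visual vocabulary by seeded k-means
#'
#' Pools descriptors, seeds k-means with k-means++ and runs Lloyd iterations
#' to a fixed cap. Deterministic given the seed.
#'
#' @param descriptorSets list of descriptor matrices from
#'   [computeDescriptors()].
#' @param k vocabulary size (default 200).
#' @param seed RNG seed.
#' @param maxIter Lloyd iteration cap.
#' @param maxDescriptors subsample cap on pooled descriptors (for speed).
#' @param spec the descriptor spec the sets were computed with (stored).
#' @return list (centroids, k, spec, seed).
#' @export
buildVocabulary <- function(descriptorSets, k = 200L, seed = 1L,
                            maxIter = 30L, maxDescriptors = 100000L,
                            spec = descriptorSpec()) {
  x <- do.call(rbind, descriptorSets)
  x <- x[rowSums(x^2) > 0, , drop = FALSE]
  if (nrow(x) < k)
    stop(sprintf("only %d descriptors for k = %d; reduce k", nrow(x), k),
         call. = FALSE)
  set.seed(seed)
  if (nrow(x) > maxDescriptors)
    x <- x[sample.int(nrow(x), maxDescriptors), , drop = FALSE]
  init <- kmeansPlusPlus(x, k)
  # deduplicate identical seeds (degenerate duplicate-descriptor input)
  init <- init + matrix(rnorm(length(init), 0, 1e-9), nrow(init))
  km <- suppressWarnings(kmeans(x, centers = init, iter.max = maxIter,
                                algorithm = "Lloyd"))
  list(centroids = km$centers, k = as.integer(k), spec = spec,
       seed = as.integer(seed))
}

#' Encode a chip's descriptors as a vocabulary histogram
#'
#' Hard-assigns each descriptor to its nearest centroid (squared Euclidean)
#' and returns the L1-normalised assignment histogram. An empty or fully
#' degenerate descriptor set encodes as the uniform histogram, flagged via
#' the `empty` attribute.
#'
#' @param descriptors matrix from [computeDescriptors()].
#' @param vocabulary list from [buildVocabulary()].
#' @return numeric vector of length `k` summing to 1.
#' @export
encodeChip <- function(descriptors, vocabulary) {
  spec <- attr(descriptors, "spec")
  if (!is.null(spec) && !identical(spec, vocabulary$spec))
    stop("descriptor spec does not match the vocabulary's", call. = FALSE)
  d <- descriptors[rowSums(descriptors^2) > 0, , drop = FALSE]
  k <- nrow(vocabulary$centroids)
  if (nrow(d) == 0) {
    h <- rep(1 / k, k)
    attr(h, "empty") <- TRUE
    return(h)
  }
  cent <- vocabulary$centroids
  d2 <- outer(rowSums(d^2), rowSums(cent^2), "+") - 2 * d %*% t(cent)
  a <- max.col(-d2, ties.method = "first")
  h <- tabulate(a, nbins = k)
  h / sum(h)
}

encodeChips <- function(chips, vocabulary) {
  t(vapply(chips, function(ch)
    encodeChip(computeDescriptors(ch, vocabulary$spec), vocabulary),
    numeric(nrow(vocabulary$centroids))))
}

#' Train the linear maximum-margin chip classifier
#'
#' Fits an L2-regularised linear support-vector machine on encoded
#' histograms. Deterministic given the seed (the solver itself is
#' deterministic; the seed is stored for provenance).
#'
#' @param histograms matrix, one encoded chip per row.
#' @param labels factor or character vector with exactly two classes.
#' @param C margin cost (default 1.0).
#' @param seed stored in `trainingMeta`.
#' @param vocabulary the vocabulary the histograms were encoded with.
#' @return a [BoFModel-class].
#' @export
trainClassifier <- function(histograms, labels, C = 1.0, seed = 1L,
                            vocabulary = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("training requires exactly two classes, got ",
         nlevels(labels), call. = FALSE)
  set.seed(seed)
  fit <- e1071::svm(histograms, labels, kernel = "linear", cost = C,
                    scale = FALSE)
  new("BoFModel", vocabulary = if (is.null(vocabulary)) list() else vocabulary,
      svm = fit,
      trainingMeta = list(n = as.list(table(labels)), C = C,
                          seed = as.integer(seed),
                          classes = levels(labels)))
}

#' Train a bag-of-features model end to end from labelled chips
#'
#' @param chips list of chip matrices.
#' @param labels two-class labels, one per chip.
#' @param k vocabulary size.
#' @param C margin cost.
#' @param seed RNG seed (vocabulary seeding and provenance).
#' @param spec descriptor parameters.
#' @return a [BoFModel-class].
#' @export
trainBoF <- function(chips, labels, k = 200L, C = 1.0, seed = 1L,
                     spec = descriptorSpec()) {
  descs <- lapply(chips, computeDescriptors, spec = spec)
  vocab <- buildVocabulary(descs, k = k, seed = seed, spec = spec)
  hist <- t(vapply(descs, encodeChip, numeric(k), vocabulary = vocab))
  trainClassifier(hist, labels, C = C, seed = seed, vocabulary = vocab)
}

#' Classify chips with a trained bag-of-features model
#'
#' @param model a [BoFModel-class] (with its vocabulary).
#' @param chips list of chip matrices.
#' @return factor of predicted labels.
#' @export
classifyChips <- function(model, chips) {
  assertThat(length(model@vocabulary) > 0, "model lacks a vocabulary")
  h <- encodeChips(chips, model@vocabulary)
  predict(model@svm, h)
}

#' Evaluate a classifier on labelled chips
#'
#' Reports the confusion matrix, per-class accuracy and their macro
#' (per-class mean) average.
#'
#' @param model a [BoFModel-class].
#' @param chips list of chip matrices.
#' @param labels true labels.
#' @return list (nValidation, confusion, perClassAccuracy,
#'   averageAccuracy in percent).
#' @export
evaluateClassifier <- function(model, chips, labels) {
  assertThat(length(chips) > 0, "validation set is empty")
  pred <- classifyChips(model, chips)
  truth <- factor(labels, levels = levels(pred))
  confusion <- table(predicted = pred, truth = truth)
  perClass <- 100 * diag(prop.table(confusion, margin = 2))
  list(nValidation = length(chips), confusion = confusion,
       perClassAccuracy = perClass,
       averageAccuracy = mean(perClass))
}
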