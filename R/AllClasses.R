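#' FrameSequence: an overhead grey-scale video as an image stack
#'
#' Pixel values are in \[0, 1\], stored as a `H x W x N` array (rows are the
#' image y axis, columns x). Frame timestamps are `(index - 1) / fps` seconds.
#' World coordinates are metres via the ground-sample distance: the centre of
#' pixel `(row, col)` sits at `x = (col - 0.5) * gsd`, `y = (row - 0.5) * gsd`.
#'
#' @slot pixels numeric array, `H x W x N`, values in \[0, 1\].
#' @slot fps frames per second.
#' @slot gsd ground-sample distance, metres per pixel.
#' @export
setClass("FrameSequence",
  representation(pixels = "array", fps = "numeric", gsd = "numeric"),
  validity = function(object) {
    if (length(dim(object@pixels)) != 3L) return("pixels must be H x W x N")
    if (object@fps <= 0) return("fps must be > 0")
    if (object@gsd <= 0) return("gsd must be > 0")
    rng <- range(object@pixels)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("pixel values outside [0, 1]")
    TRUE
  })

#' SceneGroundTruth: exhaustive per-frame truth for a synthetic scene
#'
#' @slot birdTracks data.frame (id, frame, x_m, y_m, x_px, y_px).
#' @slot foamTracks data.frame, same schema as `birdTracks`.
#' @slot glintEvents data.frame (frame, x_px, y_px).
#' @slot sheddingFrequency true surface-eddy shedding rate, events per minute.
#' @export
setClass("SceneGroundTruth",
  representation(birdTracks = "data.frame", foamTracks = "data.frame",
                 glintEvents = "data.frame", sheddingFrequency = "numeric"))

#' CountSeries: minute-resolution foraging counts by site and tidal state
#'
#' @slot data data.frame (site, t_min, tide, count, survey_id); `tide` is
#'   hours after high water in `[0, period)`, counts are non-negative integers.
#' @slot period tidal period in hours (default semidiurnal M2, 12.4 h).
#' @export
setClass("CountSeries",
  representation(data = "data.frame", period = "numeric"),
  validity = function(object) {
    d <- object@data
    need <- c("site", "t_min", "tide", "count", "survey_id")
    if (!all(need %in% names(d))) return(paste("missing columns:",
      paste(setdiff(need, names(d)), collapse = ", ")))
    if (nrow(d) && any(d$count < 0 | d$count != floor(d$count)))
      return("counts must be non-negative integers")
    if (nrow(d) && any(d$tide < 0 | d$tide >= object@period))
      return("tide must lie in [0, period)")
    TRUE
  })

#' ADCPEnsemble: one ping of a vessel-mounted ADCP
#'
#' `echoCounts` is a beams x bins matrix of raw echo intensity (counts).
#' `velocity` is a bins x 3 matrix (u, v, w) of earth-referenced velocity
#' measured relative to the instrument. `bottomTrack` is the bottom-track
#' velocity as the instrument reports it (the apparent seabed velocity, i.e.
#' minus the boat velocity over ground); true water velocity is
#' `velocity - bottomTrack` (see [correctVelocity()]).
#'
#' @slot pingTime seconds.
#' @slot y position along the cross-stream transect, metres.
#' @slot echoCounts beams x bins matrix, counts >= 0.
#' @slot velocity bins x 3 matrix (u, v, w) m/s.
#' @slot bottomTrack length-2 (u, v) m/s; NA if bottom track invalid.
#' @slot temperature deg C.
#' @slot salinity PSU.
#' @export
setClass("ADCPEnsemble",
  representation(pingTime = "numeric", y = "numeric", echoCounts = "matrix",
                 velocity = "matrix", bottomTrack = "numeric",
                 temperature = "numeric", salinity = "numeric"),
  validity = function(object) {
    if (any(object@echoCounts < 0)) return("echo counts must be >= 0")
    if (ncol(object@velocity) != 3L) return("velocity must be bins x 3")
    if (nrow(object@velocity) != ncol(object@echoCounts))
      return("velocity rows must equal echo bins")
    if (length(object@bottomTrack) != 2L) return("bottomTrack must be (u, v)")
    TRUE
  })

#' ADCPTransect: an ordered collection of ensembles plus instrument metadata
#'
#' @slot ensembles list of [ADCPEnsemble-class] objects.
#' @slot instrument an [InstrumentConfig-class].
#' @export
setClass("ADCPTransect",
  representation(ensembles = "list", instrument = "ANY"))

#' SvProfile: volume backscatter per beam and bin for one ensemble
#'
#' @slot sv beams x bins matrix, dB re 1/m; NA beyond the processed bin limit.
#' @slot svMax per-bin maximum over beams, dB.
#' @slot flags character vector of processing flags.
#' @export
setClass("SvProfile",
  representation(sv = "matrix", svMax = "numeric", flags = "character"))

#' VelocitySection: gridded cross-stream section of speed and backscatter
#'
#' @slot y cross-stream cell centres, m.
#' @slot z depth cell centres, m below surface (positive down).
#' @slot speed length(z) x length(y) matrix of horizontal speed, m/s.
#' @slot svMax matching matrix of Sv_max, dB.
#' @slot w matching matrix of mean vertical velocity, m/s.
#' @slot n matching matrix of per-cell sample counts.
#' @export
setClass("VelocitySection",
  representation(y = "numeric", z = "numeric", speed = "matrix",
                 svMax = "matrix", w = "matrix", n = "matrix"))

#' TrackSet: Kalman-compiled trajectories
#'
#' @slot points data.frame (track_id, frame, t_s, x_m, y_m, observed).
#' @slot fps frames per second of the source video.
#' @slot scale metres per pixel used to convert detections.
#' @export
setClass("TrackSet",
  representation(points = "data.frame", fps = "numeric", scale = "numeric"),
  validity = function(object) {
    p <- object@points
    need <- c("track_id", "frame", "t_s", "x_m", "y_m")
    if (!all(need %in% names(p))) return("points lacks required columns")
    if (nrow(p)) {
      bad <- vapply(split(p$t_s, p$track_id),
                    function(t) any(diff(t) <= 0), logical(1))
      if (any(bad)) return("track times must be strictly increasing")
    }
    TRUE
  })

#' BoFModel: bag-of-features vocabulary plus linear classifier
#'
#' @slot vocabulary list with `centroids` (k x d matrix), `k`, `spec`
#'   (descriptor parameters) and `seed`.
#' @slot svm the fitted linear maximum-margin classifier.
#' @slot trainingMeta list: per-class training counts, seed, hyperparameters.
#' @export
setClass("BoFModel",
  representation(vocabulary = "list", svm = "ANY", trainingMeta = "list"))

#' HurdleFit: two-part foraging-count model
#'
#' The presence part is a penalized logistic model for P(count > 0); the
#' abundance part a zero-truncated negative binomial for positive counts.
#' Both share the design: site intercepts plus a per-site cyclic smooth of
#' tidal state. Each part stores coefficients, covariance, smoothing
#' parameters, an AR1 residual correlation estimate and its design builder.
#'
#' @slot presence list (coef, cov, rho, lambda, edf, n, terms, ...).
#' @slot abundance list (coef, cov, theta, rho, lambda, edf, n, terms, ...).
#' @slot basis list describing the shared cyclic basis (knots, period).
#' @slot sites character vector of site levels.
#' @slot meta list: convergence info, call details.
#' @export
setClass("HurdleFit",
  representation(presence = "list", abundance = "list", basis = "list",
                 sites = "character", meta = "list"))

#' FlowField: steady unidirectional channel flow with log-law profile
#'
#' Horizontal speed follows the law of the wall,
#' `u(h) = (ustar / kappa) * log(h / z0)` (clipped at >= 0) where `h` is
#' height above the bed, evaluated at `h = z0` for any `h < z0`. Particle
#' code addresses the water column by depth below surface `z` in
#' `[0, depth]`; the conversion is `h = depth - z`.
#'
#' @slot depth water depth, m.
#' @slot ustar bed friction velocity, m/s.
#' @slot z0 roughness length, m.
#' @slot kappa von Karman constant (0.41).
#' @slot Dh horizontal dispersion, m^2/s (after scaling).
#' @slot Dv vertical dispersion, m^2/s.
#' @slot scaling horizontal eddy-viscosity scaling (dimensionless).
#' @export
setClass("FlowField",
  representation(depth = "numeric", ustar = "numeric", z0 = "numeric",
                 kappa = "numeric", Dh = "numeric", Dv = "numeric",
                 scaling = "numeric"),
  validity = function(object) {
    if (object@z0 >= object@depth) return("z0 must be < depth")
    if (object@ustar < 0) return("ustar must be >= 0")
    if (object@Dv < 0 || object@Dh < 0) return("dispersion must be >= 0")
    TRUE
  })

#' ParticleEnsemble: Lagrangian particle states for transit simulation
#'
#' @slot particles data.frame (id, x, z, release_s, status, arrival_s);
#'   status is one of in_transit, arrived, outside.
#' @slot meta list: schedule, target, integration settings.
#' @export
setClass("ParticleEnsemble",
  representation(particles = "data.frame", meta = "list"),
  validity = function(object) {
    p <- object@particles
    if (nrow(p) && any(!p$status %in% c("in_transit", "arrived", "outside")))
      return("invalid particle status")
    if (nrow(p) && any(!is.na(p$arrival_s) & p$arrival_s < p$release_s))
      return("arrival before release")
    TRUE
  })

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FrameSequence: %d frames of %d x %d px, %.3g fps, gsd %.3g m/px (%.1f s)\n",
              d[3], d[1], d[2], object@fps, object@gsd, d[3] / object@fps))
})

setMethod("show", "CountSeries", function(object) {
  d <- object@data
  cat(sprintf("CountSeries: %d observation minutes at %d sites, tidal period %.2f h\n",
              nrow(d), length(unique(d$site)), object@period))
  if (nrow(d)) cat(sprintf("  zero fraction %.2f, max count %d\n",
                           mean(d$count == 0), max(d$count)))
})

setMethod("show", "ADCPTransect", function(object) {
  n <- length(object@ensembles)
  cat(sprintf("ADCPTransect: %d ensembles", n))
  if (n) {
    ys <- vapply(object@ensembles, function(e) e@y, numeric(1))
    cat(sprintf(", y in [%.1f, %.1f] m, %d bins x %d beams",
                min(ys), max(ys), ncol(object@ensembles[[1]]@echoCounts),
                nrow(object@ensembles[[1]]@echoCounts)))
  }
  cat("\n")
})

setMethod("show", "TrackSet", function(object) {
  p <- object@points
  cat(sprintf("TrackSet: %d tracks, %d points, %.3g fps\n",
              length(unique(p$track_id)), nrow(p), object@fps))
})

setMethod("show", "HurdleFit", function(object) {
  cat(sprintf("HurdleFit: %d sites, cyclic tidal smooth (%d knots, period %.2f h)\n",
              length(object@sites), object@basis$nKnots, object@basis$period))
  cat(sprintf("  presence: n = %d, AR1 rho = %.3f\n",
              object@presence$n, object@presence$rho))
  cat(sprintf("  abundance: n = %d positives, theta = %.3g, AR1 rho = %.3f\n",
              object@abundance$n, object@abundance$theta, object@abundance$rho))
})

setMethod("show", "ParticleEnsemble", function(object) {
  p <- object@particles
  cat(sprintf("ParticleEnsemble: %d particles (%d arrived, %d in transit, %d outside)\n",
              nrow(p), sum(p$status == "arrived"), sum(p$status == "in_transit"),
              sum(p$status == "outside")))
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField: depth %.1f m, u* %.3g m/s, z0 %.3g m, Dh %.3g, Dv %.3g m^2/s\n",
              object@depth, object@ustar, object@z0, object@Dh, object@Dv))
})

#' Number of frames in a sequence
#' @param x a [FrameSequence-class]
#' @return integer frame count
#' @export
nFrames <- function(x) dim(x@pixels)[3]

#' Extract one frame as a matrix
#' @param x a [FrameSequence-class]
#' @param i frame index (1-based)
#' @return H x W numeric matrix
#' @export
frameAt <- function(x, i) x@pixels[, , i]

#' Frames-per-second accessor
#' @param x a [FrameSequence-class]
#' @return numeric fps
#' @export
frameRate <- function(x) x@fps

#' Ground-sample distance accessor
#' @param x a [FrameSequence-class]
#' @return metres per pixel
#' @export
groundSampleDistance <- function(x) x@gsd

#' Track points accessor
#' @param x a [TrackSet-class]
#' @return data.frame of track points
#' @export
trackPoints <- function(x) x@points

#' Count data accessor
#' @param x a [CountSeries-class]
#' @return data.frame of observation minutes
#' @export
countData <- function(x) x@data

#' Particle states accessor
#' @param x a [ParticleEnsemble-class]
#' @return data.frame of particle states
#' @export
particleStates <- function(x) x@particles
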