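# ---- file interfaces -------------------------------------------------------

#' Write a frame sequence as numbered PNGs with a JSON sidecar
#'
#' @param frames a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeFrameSequence <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nFrames(frames)
  paths <- file.path(dir, sprintf("frame_%05d.png", seq_len(n)))
  for (i in seq_len(n)) png::writePNG(frameAt(frames, i), paths[i])
  meta <- file.path(dir, "frames.json")
  jsonlite::write_json(list(fps = frames@fps, gsd = frames@gsd, n = n),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}

#' Read a frame sequence written by [writeFrameSequence()]
#'
#' @param dir directory holding `frame_*.png` and `frames.json`.
#' @return a [FrameSequence-class].
#' @export
readFrameSequence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "frames.json"),
                              simplifyVector = TRUE)
  paths <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  stopifnot(length(paths) == meta$n)
  first <- png::readPNG(paths[1])
  arr <- array(0, dim = c(nrow(first), ncol(first), meta$n))
  arr[, , 1] <- first
  for (i in seq_along(paths)[-1]) arr[, , i] <- png::readPNG(paths[i])
  new("FrameSequence", pixels = arr, fps = meta$fps, gsd = meta$gsd)
}

#' Write/read count series as CSV
#'
#' Columns: site, t_min, tide (hours after high water), count, survey_id.
#' @param counts a [CountSeries-class].
#' @param path CSV path.
#' @return `writeCounts` the path invisibly; `readCounts` a
#'   [CountSeries-class].
#' @export
writeCounts <- function(counts, path) {
  write.csv(counts@data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCounts
#' @param period tidal period of the data, hours.
#' @export
readCounts <- function(path, period = 12.4) {
  new("CountSeries", data = read.csv(path), period = period)
}

#' Write an ADCP transect as a long-format CSV
#'
#' One row per (ping, bin, beam): ping, t_s, y_m, bin, beam, echo_counts,
#' u, v, w (instrument-relative), bt_u, bt_v, temperature, salinity.
#'
#' @param transect an [ADCPTransect-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeEnsembles <- function(transect, path) {
  rows <- lapply(seq_along(transect@ensembles), function(i) {
    e <- transect@ensembles[[i]]
    nb <- ncol(e@echoCounts); nbeam <- nrow(e@echoCounts)
    data.frame(ping = i, t_s = e@pingTime, y_m = e@y,
               bin = rep(seq_len(nb), each = nbeam),
               beam = rep(seq_len(nbeam), nb),
               echo_counts = as.vector(e@echoCounts),
               u = rep(e@velocity[, 1], each = nbeam),
               v = rep(e@velocity[, 2], each = nbeam),
               w = rep(e@velocity[, 3], each = nbeam),
               bt_u = e@bottomTrack[1], bt_v = e@bottomTrack[2],
               temperature = e@temperature, salinity = e@salinity)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an ADCP transect written by [writeEnsembles()]
#'
#' @param path CSV path.
#' @param instrument an [InstrumentConfig-class].
#' @return an [ADCPTransect-class].
#' @export
readEnsembles <- function(path, instrument = instrumentConfig()) {
  d <- read.csv(path)
  ens <- lapply(split(d, d$ping), function(g) {
    g <- g[order(g$bin, g$beam), ]
    nb <- max(g$bin); nbeam <- max(g$beam)
    first <- g[g$beam == 1, ]
    new("ADCPEnsemble", pingTime = g$t_s[1], y = g$y_m[1],
        echoCounts = matrix(g$echo_counts, nbeam, nb),
        velocity = cbind(u = first$u, v = first$v, w = first$w),
        bottomTrack = c(g$bt_u[1], g$bt_v[1]),
        temperature = g$temperature[1], salinity = g$salinity[1])
  })
  new("ADCPTransect", ensembles = ens[order(as.integer(names(ens)))],
      instrument = instrument)
}

#' Write tracks as CSV (track_id, frame, t_s, x_m, y_m)
#' @param tracks a [TrackSet-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  write.csv(tracks@points, path, row.names = FALSE)
  invisible(path)
}

# ---- orchestration ---------------------------------------------------------

#' Run pipeline stages end to end
#'
#' Executes the requested stages in dependency order on synthetic inputs —
#' `video` (simulate, detect, classify, track, metrics), `adcp` (simulate,
#' grid, wake extent), `hurdle` (simulate counts, fit, predictions, term
#' tests) and `transit` (flow field, trickle release, summary) — writing
#' versioned outputs and a manifest of md5-hashed files. Per-stage RNG
#' seeds derive from the global seed and the stage name via an md5 hash, so
#' adding or reordering stages cannot silently change another stage's
#' stream.
#'
#' @param config nested list of per-stage configuration, or the path to a
#'   YAML file holding one. Recognised blocks: `video` (arguments of
#'   [sceneConfig()] plus `diffThreshold`), `adcp` ([adcpSimConfig()]
#'   arguments), `hurdle` ([surveyConfig()] arguments), `transit`
#'   (`flow` = [flowFieldConfig()] arguments, `schedule` =
#'   [releaseSchedule()] arguments, `targetX`, `totalTime`).
#' @param stages character subset of `c("video", "adcp", "hurdle",
#'   "transit")`.
#' @param seed global seed.
#' @param outDir output directory.
#' @return the run manifest (also written to `manifest.json`), invisibly.
#' @export
runPipeline <- function(config = list(), stages = c("video", "adcp",
                                                    "hurdle", "transit"),
                        seed = 1L, outDir = tempfile("wakewatch_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  seeds <- list()
  addOut <- function(x) outputs <<- c(outputs, x)

  if ("video" %in% stages) {
    s <- stageSeed(seed, "video")
    seeds$video <- s
    args <- config$video
    diffThr <- if (is.null(args$diffThreshold)) 0.1 else args$diffThreshold
    args$diffThreshold <- NULL
    cfg <- do.call(sceneConfig, c(args, list(seed = s)))
    sim <- generateWakeVideo(cfg)
    det <- detectTargets(sim$frames, diffThreshold = diffThr,
                         birdSizePx = cfg@birdSizePx)
    f <- file.path(outDir, "detections.csv")
    write.csv(det, f, row.names = FALSE)
    addOut(f)
    trk <- compileTracks(det, fps = cfg@fps, scale = cfg@gsd,
                         gateRadius = 4 * cfg@birdSpeed / cfg@fps + 1)
    f <- file.path(outDir, "tracks.csv")
    writeTracks(trk, f)
    addOut(f)
    mets <- trackSetMetrics(filterTracksByDuration(trk, 2))
    f <- file.path(outDir, "track_metrics.csv")
    write.csv(mets, f, row.names = FALSE)
    addOut(f)
  }
  if ("adcp" %in% stages) {
    s <- stageSeed(seed, "adcp")
    seeds$adcp <- s
    cfg <- do.call(adcpSimConfig, c(config$adcp, list(seed = s)))
    sim <- generateADCPTransect(cfg)
    f <- file.path(outDir, "ensembles.csv")
    writeEnsembles(sim$transect, f)
    addOut(f)
    sec <- gridSection(sim$transect)
    ext <- wakeDeficitExtent(sec)
    f <- file.path(outDir, "adcp_summary.json")
    jsonlite::write_json(list(wake_extent_m = ext,
                              true_width_m = sim$trueWake$width),
                         f, auto_unbox = TRUE, digits = NA)
    addOut(f)
  }
  if ("hurdle" %in% stages) {
    s <- stageSeed(seed, "hurdle")
    seeds$hurdle <- s
    cfg <- do.call(surveyConfig, c(config$hurdle, list(seed = s)))
    sim <- generateSurveyCounts(cfg)
    f <- file.path(outDir, "counts.csv")
    writeCounts(sim$counts, f)
    addOut(f)
    fit <- fitHurdle(sim$counts)
    grid <- seq(0, cfg@tidalPeriod - 1e-6, length.out = 50)
    preds <- do.call(rbind, lapply(fit@sites, function(st)
      predictHurdle(fit, st, grid)))
    f <- file.path(outDir, "predictions.csv")
    write.csv(preds, f, row.names = FALSE)
    addOut(f)
    tests <- rbind(
      termFTest(fit, "site", "presence"),
      do.call(rbind, lapply(fit@sites, function(st)
        termFTest(fit, paste0("s(tide):", st), "presence"))),
      termFTest(fit, "site", "abundance"),
      do.call(rbind, lapply(fit@sites, function(st)
        termFTest(fit, paste0("s(tide):", st), "abundance"))))
    f <- file.path(outDir, "term_tests.csv")
    write.csv(tests, f, row.names = FALSE)
    addOut(f)
  }
  if ("transit" %in% stages) {
    s <- stageSeed(seed, "transit")
    seeds$transit <- s
    tc <- config$transit
    flow <- generateFlowField(do.call(flowFieldConfig,
                                      as.list(tc$flow)))
    sched <- do.call(releaseSchedule, as.list(tc$schedule))
    targetX <- if (is.null(tc$targetX)) 2000 else tc$targetX
    totalTime <- if (is.null(tc$totalTime)) 3600 * 4 else tc$totalTime
    ens <- runRelease(sched, flow, targetX, totalTime, seed = s)
    f <- file.path(outDir, "particles.csv")
    write.csv(ens@particles, f, row.names = FALSE)
    addOut(f)
    sm <- transitSummary(ens)
    f <- file.path(outDir, "transit_summary.json")
    jsonlite::write_json(list(fraction_arrived = sm$fractionArrived,
                              median_s = sm$median, mean_s = sm$mean),
                         f, auto_unbox = TRUE, digits = NA)
    addOut(f)
  }
  manifest <- list(stages = stages, seed = seed, stageSeeds = seeds,
                   version = as.character(utils::packageVersion("wakewatch")),
                   outputs = lapply(outputs, function(f)
                     list(file = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
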