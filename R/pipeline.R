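# End-to-end driver: configuration, stage orchestration, run manifest.

.defaultConfig <- function() {
  list(
    seed = 1L,
    simulate = list(shape = c(900L, 44L, 52L), frameRate = 150,
                    noiseSd = 0.2, pixelPitch = 50,
                    components = list()),
    band = list(low = 0.5, high = 4),
    cheby = list(attenuation_db = 40),
    artifact = list(k_sd = 3, guard_s = 0.5),
    flow = list(alpha = 0.5, penalty = "charbonnier", charbonnier_eps = 1e-3,
                max_iters = 300L, tol = 1e-6, n_scales = 3L),
    patterns = list(plane_thresh = 0.85, standing_k = 2, link_tol = 2,
                    ring_agreement = 0.8, d = 5, r = 3),
    stats = list(op_thresh = 0.5, rostral_frac = 0.3, caudal_frac = 0.3,
                 n_perm = 1000L, n_regions = 21L),
    modes = list(k_max = 20L)
  )
}

#' Build a validated pipeline configuration
#'
#' Nested settings for every stage; unknown keys are rejected so typos
#' fail loudly. Every run logs the fully resolved configuration into its
#' manifest.
#'
#' @param ... named overrides, nested lists matching the default structure
#'   (`seed`, `simulate`, `band`, `cheby`, `artifact`, `flow`, `patterns`,
#'   `stats`, `modes`)
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(...) {
  cfg <- .defaultConfig()
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config key '", nm, "'")
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("unknown config key '", nm, ".", bad[1], "'")
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else cfg[[nm]] <- over[[nm]]
  }
  if (cfg$band$high >= cfg$simulate$frameRate / 2)
    stop("config 'band.high' is at or above Nyquist for the simulated rate")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, preprocessing (coarse-grain optional,
#' bandpass, artifact masking, instantaneous phase), PVF estimation,
#' pattern detection and tracking, SVD modes, and the spatial statistics,
#' writing every intermediate artifact plus a machine-readable manifest
#' (inputs, seed, package version, file checksums, stage timings) into
#' `outDir`.
#'
#' @param config a [pipelineConfig()]
#' @param outDir output directory (created if needed)
#' @param movie optional [VoltageMovie] to analyse; when `NULL` a
#'   synthetic movie is generated from `config$simulate`
#' @param regionFixture optional list (`regionMap`, `hierarchy`) for the
#'   regional statistics; when `NULL` a synthetic fixture is generated
#' @param coarseScale optional coarse-graining factor applied before
#'   filtering (e.g. 0.5); `NULL` skips the step
#' @return invisibly, a list with the main stage outputs and the manifest
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, movie = NULL,
                        regionFixture = NULL, coarseScale = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   package = as.character(utils::packageVersion("cortexwave")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stageDir <- function(s) {
    d <- file.path(outDir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }

  t0 <- tic()
  if (is.null(movie)) {
    sim <- config$simulate
    comps <- sim$components
    if (!length(comps))
      comps <- list(waveComponent("plane", wavevector = c(0.15, 0.05),
                                  freq = 2))
    spec <- movieSpec(sim$shape, frameRate = sim$frameRate,
                      components = comps, noiseSd = sim$noiseSd,
                      pixelPitch = sim$pixelPitch, seed = config$seed)
    movie <- generateMovie(spec)
    writeMovieRDS(movie, file.path(stageDir("simulate"), "movie.rds"),
                  spec = spec)
  }
  manifest$stages$simulate <- list(seconds = tic() - t0,
                                   frames = nFrames(movie))

  t0 <- tic()
  if (!is.null(coarseScale)) movie <- coarseGrain(movie, coarseScale)
  filt <- bandpass(movie, band = c(config$band$low, config$band$high),
                   attenuationDb = config$cheby$attenuation_db)
  filt <- maskArtifacts(filt, kSd = config$artifact$k_sd,
                        guardS = config$artifact$guard_s)
  phase <- instantaneousPhase(filt, bandLow = config$band$low)
  saveRDS(phase, file.path(stageDir("preprocess"), "phase.rds"))
  manifest$stages$preprocess <- list(seconds = tic() - t0,
                                     validFrames = sum(validMask(phase)))

  t0 <- tic()
  fs <- config$flow
  settings <- flowSettings(alpha = fs$alpha, penalty = fs$penalty,
                           charbonnierEps = fs$charbonnier_eps,
                           maxIters = fs$max_iters, tol = fs$tol,
                           nScales = fs$n_scales)
  fields <- estimatePVFSeries(phase, settings)
  if (!length(fields)) stop("pvf stage: no valid frame pairs")
  saveRDS(fields, file.path(stageDir("pvf"), "fields.rds"))
  manifest$stages$pvf <- list(seconds = tic() - t0, fields = length(fields))

  t0 <- tic()
  pc <- config$patterns
  summaries <- frameSummaries(fields, planeThresh = pc$plane_thresh,
                              standingK = pc$standing_k)
  pts <- do.call(rbind, lapply(fields, criticalPoints,
                               ringAgreement = pc$ring_agreement))
  tracked <- trackPatterns(pts, linkTol = pc$link_tol)
  filtered <- filterTracks(tracked, d = pc$d, r = pc$r)
  pdir <- stageDir("patterns")
  write.csv(summaries, file.path(pdir, "frame_summaries.csv"),
            row.names = FALSE)
  trackCols <- c("t", "row", "col", "type", "subtype", "tau", "delta",
                 "poincareIndex", "radius", "trackId")
  write.csv(tracked$points[, intersect(trackCols, names(tracked$points))],
            file.path(pdir, "tracks.csv"), row.names = FALSE)
  write.csv(tracked$tracks, file.path(pdir, "track_summary.csv"),
            row.names = FALSE)
  manifest$stages$patterns <- list(seconds = tic() - t0,
                                   points = nrow(tracked$points),
                                   tracks = nrow(tracked$tracks),
                                   filteredTracks = nrow(filtered$tracks))

  t0 <- tic()
  modeset <- svdModes(fields, kMax = min(config$modes$k_max, length(fields)))
  msum <- data.frame(mode = seq_along(singularValues(modeset)),
                     sigma = singularValues(modeset),
                     varianceFraction = varianceFractions(modeset))
  msum$dominant <- vapply(msum$mode, function(m)
    directionSplit(modeset, m)[["dominant"]], numeric(1))
  msum$opposite <- 1 - msum$dominant
  mdir <- stageDir("modes")
  saveRDS(modeset, file.path(mdir, "modes.rds"))
  write.csv(msum, file.path(mdir, "mode_summary.csv"), row.names = FALSE)
  manifest$stages$modes <- list(seconds = tic() - t0,
                                top3Variance = sum(msum$varianceFraction[1:min(3, nrow(msum))]))

  t0 <- tic()
  st <- config$stats
  dstates <- directionStates(summaries, opThresh = st$op_thresh)
  shape <- dim(velocity(fields[[1]]))
  scen <- reversalScenarios(dstates, filtered$points, shape,
                            rostralFrac = st$rostral_frac,
                            caudalFrac = st$caudal_frac)
  nValid <- length(fields)
  emap <- emergenceProbabilityMap(filtered$points, shape, nValid)
  if (is.null(regionFixture))
    regionFixture <- generateRegionFixture(shape, nRegions = st$n_regions,
                                           targetCorr = 0,
                                           seed = config$seed)
  regTab <- regionalAverage(emap, regionFixture$regionMap,
                            hierarchy = regionFixture$hierarchy)
  sdir <- stageDir("stats")
  write.csv(dstates$states, file.path(sdir, "direction_states.csv"),
            row.names = FALSE)
  write.csv(dstates$episodes, file.path(sdir, "episodes.csv"),
            row.names = FALSE)
  write.csv(scen, file.path(sdir, "reversal_scenarios.csv"),
            row.names = FALSE)
  write.csv(regTab, file.path(sdir, "regional_probability.csv"),
            row.names = FALSE)
  corrs <- lapply(c("source", "sink", "saddle"), function(ty) {
    r <- try(hierarchyCorrelation(regTab, ty), silent = TRUE)
    if (inherits(r, "try-error")) list(r = NA_real_, p = NA_real_) else r
  })
  corTab <- data.frame(type = c("source", "sink", "saddle"),
                       r = vapply(corrs, `[[`, numeric(1), "r"),
                       p = vapply(corrs, `[[`, numeric(1), "p"))
  write.csv(corTab, file.path(sdir, "hierarchy_correlation.csv"),
            row.names = FALSE)
  manifest$stages$stats <- list(seconds = tic() - t0,
                                episodes = nrow(dstates$episodes))

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outDir, "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(movie = movie, phase = phase, fields = fields,
                 summaries = summaries, tracked = tracked,
                 filtered = filtered, modes = modeset, states = dstates,
                 scenarios = scen, regional = regTab,
                 correlations = corTab, manifest = manifest))
}
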