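# Downstream inference: direction-state segmentation, reversal-scenario
# counting, emergence-probability maps, regional averaging, and the
# hierarchy correlation with its permutation null.

#' Segment frames into large-scale direction states
#'
#' A frame is `posteroanterior` when the order parameter is at least
#' `opThresh` (default 0.5, the relaxed threshold for relatively coherent
#' large-scale waves) and the mean direction lies strictly inside
#' `(pi/4, 3*pi/4)`; `anteroposterior` for `(5*pi/4, 7*pi/4)`; otherwise
#' `disordered`. Contiguous runs are merged into episodes.
#'
#' @param summaries data.frame from [frameSummaries()] (columns `t`,
#'   `orderParameter`, `direction`)
#' @param opThresh order-parameter threshold for coherent waves
#' @return list with `states` (per-frame data.frame with `state`) and
#'   `episodes` (state, tStart, tEnd, length)
#' @export
directionStates <- function(summaries, opThresh = 0.5) {
  op <- summaries$orderParameter
  th <- summaries$direction
  state <- rep("disordered", nrow(summaries))
  coherent <- !is.na(op) & op >= opThresh
  state[coherent & th > pi / 4 & th < 3 * pi / 4] <- "posteroanterior"
  state[coherent & th > 5 * pi / 4 & th < 7 * pi / 4] <- "anteroposterior"
  states <- data.frame(t = summaries$t, state = state,
                       orderParameter = op, direction = th,
                       stringsAsFactors = FALSE)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  episodes <- data.frame(state = r$values,
                         tStart = summaries$t[starts],
                         tEnd = summaries$t[ends],
                         length = r$lengths, stringsAsFactors = FALSE)
  list(states = states, episodes = episodes)
}

# frames of the last quarter of an episode (floor-rounded, >= 1 frame)
lastQuarter <- function(tStart, tEnd) {
  n <- tEnd - tStart + 1
  q <- max(1, floor(n / 4))
  (tEnd - q + 1):tEnd
}
firstQuarter <- function(tStart, tEnd) {
  n <- tEnd - tStart + 1
  q <- max(1, floor(n / 4))
  tStart:(tStart + q - 1)
}

#' Count source/sink occurrences around direction reversals
#'
#' For every (coherent wave, disordered interval, coherent wave) episode
#' triple, counts the source and sink tracks present in the rostral and
#' caudal boxes during the last quarter of the disordered interval or the
#' first quarter of the following wave. Triples are grouped by the
#' direction of the following wave: scenario `a-a/p-a` (next wave
#' anteroposterior) versus `p-p/a-p` (next wave posteroanterior). Counts
#' are normalised by the number of following waves of each direction and,
#' optionally in either order, by the overall source/sink totals (sources
#' are typically detected more often than sinks). Raw counts are always
#' emitted alongside.
#'
#' @param states result of [directionStates()]
#' @param points filtered, tracked point table (columns `t`, `row`,
#'   `col`, `type`, `trackId`)
#' @param shape `(H, W)` of the field
#' @param rostralFrac,caudalFrac fraction of rows forming the rostral
#'   (top) and caudal (bottom) boxes
#' @param normOrder `"waves_first"` (normalise by wave counts, then by
#'   source/sink totals) or `"patterns_first"`
#' @return data.frame with one row per (scenario, box, type) cell:
#'   raw count, nTriples, normalised value
#' @export
reversalScenarios <- function(states, points, shape, rostralFrac = 0.3,
                              caudalFrac = 0.3,
                              normOrder = c("waves_first", "patterns_first")) {
  normOrder <- match.arg(normOrder)
  ep <- states$episodes
  coh <- c("posteroanterior", "anteroposterior")
  triples <- list()
  for (i in seq_len(max(0, nrow(ep) - 2))) {
    if (ep$state[i] %in% coh && ep$state[i + 1] == "disordered" &&
        ep$state[i + 2] %in% coh)
      triples[[length(triples) + 1]] <- ep[i:(i + 2), ]
  }
  cells <- expand.grid(scenario = c("a-a/p-a", "p-p/a-p"),
                       box = c("rostral", "caudal"),
                       type = c("source", "sink"),
                       stringsAsFactors = FALSE)
  cells$count <- 0
  cells$nTriples <- 0
  if (!length(triples)) {
    warning("no coherent-disordered-coherent episode triples found")
    cells$normalized <- 0
    return(cells)
  }
  H <- shape[1]
  rostralRows <- c(1, ceiling(rostralFrac * H))
  caudalRows <- c(floor((1 - caudalFrac) * H) + 1, H)
  inBox <- function(p, box) {
    rng <- if (box == "rostral") rostralRows else caudalRows
    p$row >= rng[1] & p$row <= rng[2]
  }
  nextDir <- vapply(triples, function(tr) tr$state[3], character(1))
  scen <- ifelse(nextDir == "anteroposterior", "a-a/p-a", "p-p/a-p")
  for (k in seq_along(triples)) {
    tr <- triples[[k]]
    win <- c(lastQuarter(tr$tStart[2], tr$tEnd[2]),
             firstQuarter(tr$tStart[3], tr$tEnd[3]))
    pw <- points[points$t %in% win, , drop = FALSE]
    for (j in seq_len(nrow(cells))) {
      if (cells$scenario[j] != scen[k]) next
      sel <- pw$type == cells$type[j] & inBox(pw, cells$box[j])
      # a track counts once per triple regardless of how long it lingers
      cells$count[j] <- cells$count[j] + length(unique(pw$trackId[sel]))
    }
  }
  for (s in unique(cells$scenario))
    cells$nTriples[cells$scenario == s] <- sum(scen == s)
  totType <- c(source = sum(cells$count[cells$type == "source"]),
               sink = sum(cells$count[cells$type == "sink"]))
  byWaves <- ifelse(cells$nTriples > 0, cells$count / cells$nTriples, 0)
  if (normOrder == "waves_first") {
    tt <- vapply(split(byWaves, cells$type), sum, numeric(1))
    cells$normalized <- ifelse(tt[cells$type] > 0,
                               byWaves / tt[cells$type], 0)
  } else {
    byType <- ifelse(totType[cells$type] > 0,
                     cells$count / totType[cells$type], 0)
    cells$normalized <- ifelse(cells$nTriples > 0,
                               byType / cells$nTriples, 0)
  }
  cells
}

#' Per-pixel emergence-probability map of local wave patterns
#'
#' For each pixel and pattern type, the probability of pattern emergence
#' is the cumulative time a (filtered) track of that type occupies the
#' pixel (locations rounded to the nearest pixel) divided by the number
#' of artifact-valid frames.
#'
#' @param points filtered point table (`t`, `row`, `col`, `type`)
#' @param shape `(H, W)`
#' @param totalValidFrames denominator (> 0)
#' @return named list of H x W probability maps, one per type present in
#'   `c("source", "sink", "saddle")`
#' @export
emergenceProbabilityMap <- function(points, shape, totalValidFrames) {
  if (totalValidFrames <= 0) stop("'totalValidFrames' must be > 0")
  H <- shape[1]; W <- shape[2]
  maps <- list()
  for (ty in c("source", "sink", "saddle")) {
    m <- matrix(0, H, W)
    p <- points[points$type == ty, , drop = FALSE]
    if (nrow(p)) {
      ri <- pmin(pmax(round(p$row), 1L), H)
      ci <- pmin(pmax(round(p$col), 1L), W)
      for (i in seq_along(ri)) m[ri[i], ci[i]] <- m[ri[i], ci[i]] + 1
    }
    maps[[ty]] <- m / totalValidFrames
  }
  maps
}

#' Average a probability map over regions
#'
#' Means over member pixels per region per pattern type. Hemisphere
#' pooling falls out of the labeling: paired regions sharing one label are
#' pooled automatically.
#'
#' @param maps named list of H x W maps (e.g. from
#'   [emergenceProbabilityMap()]) or one matrix
#' @param regionMap H x W integer label matrix
#' @param hierarchy optional data.frame (`region`, `hierarchyIndex`) to
#'   join
#' @return data.frame: `region`, `pixels`, one probability column per
#'   type, and `hierarchyIndex` if supplied
#' @export
regionalAverage <- function(maps, regionMap, hierarchy = NULL) {
  if (is.matrix(maps)) maps <- list(probability = maps)
  regs <- sort(unique(as.vector(regionMap)))
  regs <- regs[regs > 0]
  fac <- factor(as.vector(regionMap), levels = regs)
  out <- data.frame(region = regs,
                    pixels = as.integer(table(fac)))
  for (nm in names(maps)) {
    if (!identical(dim(maps[[nm]]), dim(regionMap)))
      stop("map '", nm, "' does not match the region map dimensions")
    sums <- rowsum(as.vector(maps[[nm]]), fac)
    out[[nm]] <- as.numeric(sums) / out$pixels
  }
  if (!is.null(hierarchy))
    out <- merge(out, hierarchy, by = "region", sort = TRUE)
  out
}

#' Pearson correlation of regional probability with the hierarchy index
#'
#' @param table data.frame from [regionalAverage()] with a
#'   `hierarchyIndex` column
#' @param type which probability column to correlate
#' @return list with `r` and two-sided `p` (t-distribution, n - 2 df)
#' @export
hierarchyCorrelation <- function(table, type = "source") {
  if (!type %in% names(table)) stop("no column '", type, "' in table")
  if (!"hierarchyIndex" %in% names(table))
    stop("table carries no 'hierarchyIndex' column")
  x <- table[[type]]; h <- table$hierarchyIndex
  ok <- is.finite(x) & is.finite(h)
  if (sum(ok) < 4) stop("need at least 4 regions with finite values")
  if (sd(x[ok]) == 0 || sd(h[ok]) == 0)
    stop("correlation undefined: zero variance in ",
         if (sd(x[ok]) == 0) "probabilities" else "hierarchy index")
  ct <- cor.test(x[ok], h[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Permutation null for the hierarchy correlation
#'
#' Randomly permutes pixel locations of the probability map `nPerm` times;
#' each permuted map is regionally averaged and correlated with the
#' hierarchy index, giving the null distribution of `r` under no spatial
#' association. Returns the null draws, the observed `r`, its rank within
#' the null, and central empirical bands.
#'
#' @param map H x W probability map
#' @param regionMap H x W integer labels
#' @param hierarchy data.frame (`region`, `hierarchyIndex`)
#' @param nPerm number of permutations (default 1000)
#' @param seed integer RNG seed
#' @return list: `null` (numeric vector), `observed`, `rank` (fraction of
#'   null draws below the observed r), `band95`, `band99`
#' @export
permutationNull <- function(map, regionMap, hierarchy, nPerm = 1000L,
                            seed = 1L) {
  if (nPerm < 100) warning("nPerm < 100 gives a wide, unstable null band")
  obs <- hierarchyCorrelation(regionalAverage(map, regionMap, hierarchy),
                              type = "probability")
  vecMap <- as.vector(map)
  regs <- sort(unique(as.vector(regionMap)))
  regs <- regs[regs > 0]
  fac <- factor(as.vector(regionMap), levels = regs)
  h <- hierarchy$hierarchyIndex[match(regs, hierarchy$region)]
  counts <- as.integer(table(fac))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    perm <- vecMap[sample.int(length(vecMap))]
    means <- as.numeric(rowsum(perm, fac)) / counts
    if (sd(means) == 0) return(NA_real_)
    cor(means, h)
  }, numeric(1))
  null <- null[is.finite(null)]
  list(null = null, observed = obs$r,
       rank = mean(null < obs$r),
       band95 = unname(quantile(null, c(0.025, 0.975))),
       band99 = unname(quantile(null, c(0.005, 0.995))))
}
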