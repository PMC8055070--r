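# Temporal linking of critical points into tracks, (d, r) filtering, and
# the derived census statistics.

#' Link classified critical points into tracks
#'
#' Greedy nearest-neighbor linking of same-type points across consecutive
#' frames within `linkTol` pixels; ties are broken by smallest distance,
#' then lowest row, then lowest column. Unmatched points open or close
#' tracks. A track's duration `d` is the number of time steps the same
#' location is occupied by the same singularity; `minRadius` is the
#' smallest pattern radius along the track.
#'
#' @param points data.frame of classified points across frames (columns
#'   `t`, `row`, `col`, `type`, and optionally `radius`, `poincareIndex`),
#'   e.g. rows of [criticalPoints()] over a field sequence
#' @param linkTol maximum link distance in pixels
#' @return list with `points` (input plus `trackId`) and `tracks`
#'   (one row per track: `trackId`, `type`, `d`, `minRadius`,
#'   `centroidRow`, `centroidCol`, `tStart`, `tEnd`)
#' @export
trackPatterns <- function(points, linkTol = 2) {
  if (!nrow(points)) {
    return(list(points = cbind(points, trackId = integer(0)),
                tracks = data.frame(trackId = integer(0), type = character(0),
                                    d = integer(0), minRadius = numeric(0),
                                    centroidRow = numeric(0),
                                    centroidCol = numeric(0),
                                    tStart = integer(0), tEnd = integer(0))))
  }
  points <- points[order(points$t, points$row, points$col), , drop = FALSE]
  points$trackId <- NA_integer_
  nextId <- 1L
  # active tracks: id, type, last position, last frame
  act <- data.frame(id = integer(0), type = character(0), row = numeric(0),
                    col = numeric(0), t = integer(0),
                    stringsAsFactors = FALSE)
  for (t in sort(unique(points$t))) {
    idx <- which(points$t == t)
    live <- act[act$t == t - 1L, , drop = FALSE]
    taken <- rep(FALSE, nrow(live))
    assigned <- rep(FALSE, length(idx))
    if (nrow(live)) {
      # all candidate links within tolerance, ordered for determinism
      cand <- expand.grid(p = seq_along(idx), a = seq_len(nrow(live)))
      cand$dist <- sqrt((points$row[idx[cand$p]] - live$row[cand$a])^2 +
                        (points$col[idx[cand$p]] - live$col[cand$a])^2)
      cand <- cand[cand$dist <= linkTol &
                     points$type[idx[cand$p]] == live$type[cand$a], ,
                   drop = FALSE]
      cand <- cand[order(cand$dist, points$row[idx[cand$p]],
                         points$col[idx[cand$p]]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        p <- cand$p[k]; a <- cand$a[k]
        if (assigned[p] || taken[a]) next
        points$trackId[idx[p]] <- live$id[a]
        assigned[p] <- TRUE; taken[a] <- TRUE
      }
    }
    for (p in which(!assigned)) {
      points$trackId[idx[p]] <- nextId
      nextId <- nextId + 1L
    }
    act <- data.frame(id = points$trackId[idx], type = points$type[idx],
                      row = points$row[idx], col = points$col[idx],
                      t = t, stringsAsFactors = FALSE)
  }
  sp <- split(seq_len(nrow(points)), points$trackId)
  tracks <- do.call(rbind, lapply(sp, function(ii) {
    data.frame(trackId = points$trackId[ii[1]], type = points$type[ii[1]],
               d = length(ii),
               minRadius = if ("radius" %in% names(points))
                 min(points$radius[ii]) else NA_real_,
               centroidRow = mean(points$row[ii]),
               centroidCol = mean(points$col[ii]),
               tStart = min(points$t[ii]), tEnd = max(points$t[ii]),
               stringsAsFactors = FALSE)
  }))
  rownames(tracks) <- NULL
  list(points = points, tracks = tracks)
}

#' Filter tracks by the (d, r) detection threshold
#'
#' @param tracked result of [trackPatterns()]
#' @param d minimum duration in frames
#' @param r minimum pattern radius in pixels
#' @return the tracked list restricted to surviving tracks
#' @export
filterTracks <- function(tracked, d = 5, r = 3) {
  keep <- tracked$tracks$d >= d & tracked$tracks$minRadius >= r
  ids <- tracked$tracks$trackId[keep]
  list(points = tracked$points[tracked$points$trackId %in% ids, , drop = FALSE],
       tracks = tracked$tracks[keep, , drop = FALSE])
}

#' Detection-probability surface over (d, r) thresholds
#'
#' Probability at threshold `(d, r)` is the number of tracks surviving
#' `(d, r)` divided by the number surviving `(1, 1)`; by construction the
#' value at `(1, 1)` is 1 and the surface is non-increasing along both
#' axes.
#'
#' @param tracks track table from [trackPatterns()]
#' @param dRange,rRange threshold grids (start at 1)
#' @return matrix of probabilities, rows indexed by `d`, columns by `r`
#' @export
detectionProbabilitySurface <- function(tracks, dRange = 1:10, rRange = 1:6) {
  n11 <- sum(tracks$d >= 1 & tracks$minRadius >= 1)
  if (n11 == 0) stop("no tracks survive threshold (1, 1)")
  out <- outer(dRange, rRange, Vectorize(function(d, r)
    sum(tracks$d >= d & tracks$minRadius >= r) / n11))
  dimnames(out) <- list(d = dRange, r = rRange)
  out
}

.coexistCombos <- c("source", "sink", "saddle", "source+sink",
                    "source+saddle", "sink+saddle", "source+sink+saddle")

#' Census of coexisting local wave patterns
#'
#' Labels every analysed frame by the combination of pattern types present
#' (the seven combinations of source, sink and saddle, or `none`) and
#' histograms the combinations.
#'
#' @param points filtered point table (with `t`, `type`)
#' @param frames integer vector of all analysed frame indices
#' @return list with `perFrame` (frame, combination, nPatterns) and
#'   `histogram` (combination, count, probability over frames with any
#'   pattern)
#' @export
coexistenceCensus <- function(points, frames) {
  combo <- vapply(frames, function(t) {
    ty <- sort(unique(points$type[points$t == t]))
    ord <- intersect(c("source", "sink", "saddle"), ty)
    if (!length(ord)) "none" else paste(ord, collapse = "+")
  }, character(1))
  nPat <- vapply(frames, function(t) sum(points$t == t), integer(1))
  perFrame <- data.frame(t = frames, combination = combo, nPatterns = nPat,
                         stringsAsFactors = FALSE)
  counts <- vapply(.coexistCombos, function(cb) sum(combo == cb), integer(1))
  nAny <- sum(combo != "none")
  hist <- data.frame(combination = .coexistCombos, count = as.integer(counts),
                     probability = if (nAny > 0) counts / nAny else
                       rep(0, length(counts)),
                     stringsAsFactors = FALSE)
  rownames(hist) <- NULL
  list(perFrame = perFrame, histogram = hist)
}

#' Total Poincare index change between successive frames
#'
#' The total index of a frame is the sum of indices of its classified
#' points (+1 source/sink, -1 saddle). Pairwise creation or annihilation
#' of a source/sink with a saddle leaves the total unchanged
#' (Poincare-Hopf); nonzero deltas indicate patterns crossing the field
#' boundary.
#'
#' @param points point table (with `t`, `poincareIndex`)
#' @param frames integer vector of analysed frame indices (ordered)
#' @return list with `series` (t, totalIndex, delta to next frame) and
#'   `distribution` (delta, probability)
#' @export
indexChangeSeries <- function(points, frames) {
  total <- vapply(frames, function(t)
    sum(points$poincareIndex[points$t == t]), numeric(1))
  delta <- diff(total)
  series <- data.frame(t = frames,
                       totalIndex = total,
                       delta = c(delta, NA_real_))
  tab <- table(factor(delta))
  distribution <- data.frame(delta = as.numeric(names(tab)),
                             probability = as.numeric(tab) / length(delta))
  list(series = series, distribution = distribution)
}
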