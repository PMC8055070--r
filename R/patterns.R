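# Frame-level wave-pattern classification: order parameter, plane and
# standing wave criteria, and the window-size sweep.

#' Order parameter of a phase velocity field
#'
#' `vbar = |mean(v)| / mean(|v|)` over reliable pixels: 1 when all
#' velocity vectors are parallel, near 0 for incoherent directions (for N
#' iid uniform directions the expectation is ~ sqrt(pi)/(2 sqrt(N))).
#'
#' @param field a [PhaseVelocityField] (or complex matrix)
#' @return scalar in `[0, 1]`
#' @export
orderParameter <- function(field) {
  v <- if (is(field, "PhaseVelocityField"))
    velocity(field)[reliability(field)] else field
  v0 <- mean(Mod(v))
  if (!length(v) || v0 == 0)
    stop("mean speed is zero: order parameter undefined (standing wave)")
  Mod(mean(v)) / v0
}

#' Mean propagation direction of a field
#'
#' Angle of the mean velocity vector, measured counterclockwise from +x
#' (lateral right) with anterior taken as the negative-row direction, in
#' `[0, 2*pi)`. Posteroanterior propagation falls in `(pi/4, 3*pi/4)`,
#' anteroposterior in `(5*pi/4, 7*pi/4)`.
#'
#' @param field a [PhaseVelocityField] (or complex matrix)
#' @return angle in radians
#' @export
meanDirection <- function(field) {
  v <- if (is(field, "PhaseVelocityField"))
    velocity(field)[reliability(field)] else field
  mv <- mean(v)
  th <- atan2(-Im(mv), Re(mv))   # anterior = -row
  (th + 2 * pi) %% (2 * pi)
}

#' Classify one frame as standing, plane, or other
#'
#' The standing-wave criterion is checked first: a frame is standing when
#' its mean speed falls `standingK` standard deviations below the mean of
#' the speed history across the analysed period (effective synchrony,
#' negligible propagation). Only if not standing is the plane-wave
#' criterion applied: order parameter at or above `planeThresh` (default
#' 0.85). Everything else is `other`.
#'
#' @param field a [PhaseVelocityField]
#' @param planeThresh order-parameter threshold for plane waves
#' @param standingK standing-wave criterion in standard deviations
#' @param speedHistory numeric vector of mean speeds over the analysed
#'   period (required)
#' @return one-row data.frame: `t`, `orderParameter`, `meanSpeed`,
#'   `direction`, `label`
#' @export
classifyFrame <- function(field, planeThresh = 0.85, standingK = 2,
                          speedHistory) {
  if (missing(speedHistory) || length(speedHistory) < 2L)
    stop("'speedHistory' across the analysed period is required")
  v <- velocity(field)[reliability(field)]
  v0 <- mean(Mod(v))
  standing <- v0 < mean(speedHistory) - standingK * sd(speedHistory)
  if (standing) {
    op <- if (v0 > 0) Mod(mean(v)) / v0 else NA_real_
    label <- "standing"
  } else {
    op <- orderParameter(field)
    label <- if (op >= planeThresh) "plane" else "other"
  }
  data.frame(t = frameIndex(field), orderParameter = op, meanSpeed = v0,
             direction = meanDirection(field), label = label,
             stringsAsFactors = FALSE)
}

#' Frame summaries for a sequence of fields
#'
#' Builds the speed history from the whole sequence, then applies
#' [classifyFrame()] to every field.
#'
#' @param fields list of [PhaseVelocityField]
#' @inheritParams classifyFrame
#' @return data.frame, one row per field
#' @export
frameSummaries <- function(fields, planeThresh = 0.85, standingK = 2) {
  if (!length(fields)) stop("empty field sequence")
  speeds <- vapply(fields, function(f)
    mean(Mod(velocity(f)[reliability(f)])), numeric(1))
  do.call(rbind, lapply(fields, classifyFrame, planeThresh = planeThresh,
                        standingK = standingK, speedHistory = speeds))
}

# split 1:n into k nearly equal contiguous chunks
chunkIndices <- function(n, k) {
  edges <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (edges[i] + 1):edges[i + 1])
}

#' Plane/standing probabilities versus analysis-window size
#'
#' Divides the field of view into 1, 2 (left/right), 4 (2 x 2) or 16
#' (4 x 4) windows, classifies every window of every frame with its own
#' speed history, and tabulates the probability of plane and standing
#' labels per window size. Plane-wave probability rises as windows
#' shrink, since locally most non-stationary patterns look planar.
#'
#' @param fields list of [PhaseVelocityField]
#' @param partitions window counts, subset of `c(1, 2, 4, 16)`
#' @inheritParams classifyFrame
#' @return data.frame: `nWindows`, `windowFraction`, `pPlane`, `pStanding`
#' @export
windowSweep <- function(fields, partitions = c(1, 2, 4, 16),
                        planeThresh = 0.85, standingK = 2) {
  if (!length(partitions)) stop("empty partition specification")
  if (!all(partitions %in% c(1, 2, 4, 16)))
    stop("supported partitions are 1, 2, 4 and 16 windows")
  if (!length(fields)) stop("empty field sequence")
  d <- dim(velocity(fields[[1]]))
  layout <- list(`1` = c(1, 1), `2` = c(1, 2), `4` = c(2, 2), `16` = c(4, 4))
  out <- lapply(partitions, function(np) {
    lay <- layout[[as.character(np)]]
    rowChunks <- chunkIndices(d[1], lay[1])
    colChunks <- chunkIndices(d[2], lay[2])
    labels <- character(0)
    for (ri in rowChunks) for (ci in colChunks) {
      vs <- lapply(fields, function(f) velocity(f)[ri, ci, drop = FALSE])
      rels <- lapply(fields, function(f) reliability(f)[ri, ci, drop = FALSE])
      speeds <- mapply(function(v, r) mean(Mod(v[r])), vs, rels)
      thr <- mean(speeds) - standingK * sd(speeds)
      for (i in seq_along(vs)) {
        vv <- vs[[i]][rels[[i]]]
        v0 <- mean(Mod(vv))
        labels <- c(labels, if (v0 < thr) "standing"
                    else if (v0 > 0 && Mod(mean(vv)) / v0 >= planeThresh) "plane"
                    else "other")
      }
    }
    data.frame(nWindows = np, windowFraction = 1 / np,
               pPlane = mean(labels == "plane"),
               pStanding = mean(labels == "standing"))
  })
  do.call(rbind, out)
}
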