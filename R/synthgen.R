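#' Specify one wave component of a synthetic movie
#'
#' Kinematic wave templates used by [generateMovie()]: traveling plane
#' waves, standing waves, radially propagating sources/sinks, in/out
#' spirals, and saddles. A traveling component contributes
#' `amplitude * cos(phi(r, c) - 2*pi*freq*t/frameRate + phaseOffset)` with
#' spatial phase `phi` determined by the kind:
#' plane `phi = k . x`; source/sink `phi = +/- k_r * ||x - center||`;
#' spirals add the polar angle around the center to the radial term. A
#' standing component is `amplitude * cos(k . x) * cos(2*pi*freq*t/fs +
#' phaseOffset)`. A `saddle` component is realised implicitly as two
#' same-sign radial (source) components straddling `center`, whose
#' interaction region contains a saddle of the phase flow; an exact linear
#' saddle field for oracle work is available from [generateLinearField()].
#'
#' @param kind one of `"plane"`, `"standing"`, `"source"`, `"sink"`,
#'   `"spiral_in"`, `"spiral_out"`, `"saddle"`
#' @param center `(row, col)` grid coordinates (radial kinds and saddle)
#' @param wavevector `(k_row, k_col)` in radians/pixel (plane and standing)
#' @param radialWavenumber radians/pixel (radial kinds)
#' @param freq temporal frequency in Hz
#' @param amplitude peak amplitude, arbitrary voltage units (> 0)
#' @param phaseOffset radians
#' @param saddleSeparation pixel distance between the two implicit radial
#'   components of a `saddle`
#' @return a `WaveComponent` list usable in [movieSpec()]
#' @export
waveComponent <- function(kind = c("plane", "standing", "source", "sink",
                                   "spiral_in", "spiral_out", "saddle"),
                          center = NULL, wavevector = NULL,
                          radialWavenumber = NULL, freq = 2,
                          amplitude = 1, phaseOffset = 0,
                          saddleSeparation = NULL) {
  kind <- match.arg(kind)
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  if (kind %in% c("plane", "standing") && is.null(wavevector))
    stop("'wavevector' is required for kind '", kind, "'")
  if (kind %in% c("source", "sink", "spiral_in", "spiral_out", "saddle")) {
    if (is.null(radialWavenumber))
      stop("'radialWavenumber' is required for kind '", kind, "'")
    if (is.null(center))
      stop("'center' is required for kind '", kind, "'")
  }
  structure(list(kind = kind, center = center, wavevector = wavevector,
                 radialWavenumber = radialWavenumber, freq = freq,
                 amplitude = amplitude, phaseOffset = phaseOffset,
                 saddleSeparation = saddleSeparation),
            class = "WaveComponent")
}

#' Specify a synthetic voltage movie
#'
#' @param shape integer `(T, H, W)`; `T >= 2`, `H, W >= 8`
#' @param frameRate acquisition rate in Hz
#' @param components list of [waveComponent()] specs
#' @param noiseSd standard deviation of additive white Gaussian noise
#' @param pixelPitch micrometres/pixel (metadata)
#' @param seed integer; identical seed gives a bit-identical movie
#' @return a `MovieSpec` list for [generateMovie()]
#' @export
movieSpec <- function(shape, frameRate = 150, components = list(),
                      noiseSd = 0.2, pixelPitch = 50, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || shape[1] < 2L || shape[2] < 8L || shape[3] < 8L)
    stop("'shape' must be (T, H, W) with T >= 2 and H, W >= 8")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (frameRate <= 0) stop("'frameRate' must be > 0")
  nyq <- frameRate / 2
  for (cmp in components) {
    if (!inherits(cmp, "WaveComponent")) stop("components must be waveComponent() specs")
    if (cmp$freq >= nyq)
      stop("component frequency ", cmp$freq, " Hz is at or above Nyquist")
  }
  structure(list(shape = shape, frameRate = frameRate,
                 components = components, noiseSd = noiseSd,
                 pixelPitch = pixelPitch, seed = as.integer(seed)),
            class = "MovieSpec")
}

# spatial phase field of one traveling component on an H x W grid
componentPhaseField <- function(cmp, H, W) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  switch(cmp$kind,
    plane = cmp$wavevector[1] * (rows - 1) + cmp$wavevector[2] * (cols - 1),
    source = cmp$radialWavenumber *
      sqrt((rows - cmp$center[1])^2 + (cols - cmp$center[2])^2),
    sink = -cmp$radialWavenumber *
      sqrt((rows - cmp$center[1])^2 + (cols - cmp$center[2])^2),
    spiral_out = cmp$radialWavenumber *
      sqrt((rows - cmp$center[1])^2 + (cols - cmp$center[2])^2) +
      atan2(-(rows - cmp$center[1]), cols - cmp$center[2]),
    spiral_in = -cmp$radialWavenumber *
      sqrt((rows - cmp$center[1])^2 + (cols - cmp$center[2])^2) +
      atan2(-(rows - cmp$center[1]), cols - cmp$center[2]),
    stop("no phase field for kind '", cmp$kind, "'"))
}

#' Generate a synthetic voltage movie
#'
#' Sums the wave components of a [movieSpec()] frame by frame and adds
#' white Gaussian noise. Generation is a pure function of the spec
#' (including its seed).
#'
#' @param spec a `MovieSpec`
#' @return a [VoltageMovie]
#' @examples
#' sp <- movieSpec(c(30, 16, 16), frameRate = 150, noiseSd = 0,
#'                 components = list(waveComponent("plane",
#'                   wavevector = c(0, 0.2), freq = 2)))
#' generateMovie(sp)
#' @export
generateMovie <- function(spec) {
  stopifnot(inherits(spec, "MovieSpec"))
  Tn <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  t0 <- seq_len(Tn) - 1
  dat <- array(0, dim = c(Tn, H, W))
  comps <- list()
  for (cmp in spec$components) {
    if (cmp$kind == "saddle") {
      sep <- if (is.null(cmp$saddleSeparation)) max(8, round(W / 3)) else
        cmp$saddleSeparation
      for (s in c(-1, 1))
        comps[[length(comps) + 1]] <- waveComponent("source",
          center = cmp$center + c(0, s * sep / 2),
          radialWavenumber = cmp$radialWavenumber, freq = cmp$freq,
          amplitude = cmp$amplitude, phaseOffset = cmp$phaseOffset)
    } else comps[[length(comps) + 1]] <- cmp
  }
  for (cmp in comps) {
    wFrame <- 2 * pi * cmp$freq / spec$frameRate   # radians/frame
    if (cmp$kind == "standing") {
      rows <- matrix(seq_len(H), H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      spat <- cmp$amplitude * cos(cmp$wavevector[1] * (rows - 1) +
                                  cmp$wavevector[2] * (cols - 1))
      tc <- cos(wFrame * t0 + cmp$phaseOffset)
      for (t in seq_len(Tn)) dat[t, , ] <- dat[t, , ] + spat * tc[t]
    } else {
      phi <- componentPhaseField(cmp, H, W)
      for (t in seq_len(Tn))
        dat[t, , ] <- dat[t, , ] +
          cmp$amplitude * cos(phi - wFrame * t0[t] + cmp$phaseOffset)
    }
  }
  if (spec$noiseSd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    dat <- dat + array(rnorm(length(dat), sd = spec$noiseSd), dim = dim(dat))
  }
  VoltageMovie(dat, frameRate = spec$frameRate, pixelPitch = spec$pixelPitch)
}

# save/restore the global RNG state so generators are pure in their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate an exact linear vector field
#'
#' Returns the analytic field `v(x) = A (x - center)` as a
#' [PhaseVelocityField], with the displacement expressed in `(x, y)` =
#' `(col, row)` order so that `A` is exactly the Jacobian the classifier
#' estimates. Used as the oracle input for critical-point classification
#' and Poincare-index computations.
#'
#' @param A non-singular 2 x 2 real matrix
#' @param center `(row, col)` of the critical point
#' @param shape `(H, W)` grid size
#' @return a [PhaseVelocityField] (exact, no noise)
#' @export
generateLinearField <- function(A, center, shape) {
  A <- matrix(A, 2, 2)
  if (abs(det(A)) < .Machine$double.eps * 100)
    stop("'A' is singular: degenerate critical point")
  H <- shape[1]; W <- shape[2]
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- cols - center[2]
  dy <- rows - center[1]
  u <- A[1, 1] * dx + A[1, 2] * dy
  w <- A[2, 1] * dx + A[2, 2] * dy
  PhaseVelocityField(u + 1i * w)
}

#' Temporal phase-randomisation surrogate
#'
#' Per pixel independently: Fourier transform the time series, multiply
#' every positive-frequency coefficient by a random unit-modulus factor
#' (Hermitian symmetry enforced; DC untouched; for even T the Nyquist bin
#' is kept real by a random sign), and invert. The per-pixel power
#' spectrum is preserved to numerical tolerance while all temporal phase
#' structure is destroyed.
#'
#' @param movie a [VoltageMovie] with at least 4 frames
#' @param seed integer RNG seed
#' @return a [VoltageMovie] surrogate
#' @export
shuffleTemporal <- function(movie, seed = 1L) {
  stopifnot(is(movie, "VoltageMovie"))
  Tn <- nFrames(movie)
  if (Tn < 4L) stop("temporal shuffling needs at least 4 frames")
  d <- frameDims(movie)
  X <- movieToMatrix(movieData(movie))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  F <- mvfft(X)
  P <- ncol(X)
  if (Tn %% 2 == 0) {
    npos <- Tn / 2 - 1
    if (npos > 0) {
      ph <- matrix(exp(2i * pi * runif(npos * P)), npos, P)
      F[2:(Tn / 2), ] <- F[2:(Tn / 2), , drop = FALSE] * ph
      F[Tn:(Tn / 2 + 2), ] <- Conj(F[2:(Tn / 2), , drop = FALSE])
    }
    sgn <- matrix(sample(c(-1, 1), P, replace = TRUE), 1, P)
    F[Tn / 2 + 1, ] <- F[Tn / 2 + 1, ] * sgn
  } else {
    npos <- (Tn - 1) / 2
    ph <- matrix(exp(2i * pi * runif(npos * P)), npos, P)
    F[2:(npos + 1), ] <- F[2:(npos + 1), , drop = FALSE] * ph
    F[Tn:(npos + 2), ] <- Conj(F[2:(npos + 1), , drop = FALSE])
  }
  Y <- Re(mvfft(F, inverse = TRUE)) / Tn
  VoltageMovie(matrixToMovie(Y, d[1], d[2]), frameRate = frameRate(movie),
               pixelPitch = pixelPitch(movie), validMask = validMask(movie))
}

#' Spatial pixel-permutation surrogate
#'
#' Applies one random permutation of pixel locations identically to every
#' frame: each pixel keeps its own full time series but loses its spatial
#' neighborhood, destroying spatial phase gradients while preserving all
#' temporal statistics.
#'
#' @param movie a [VoltageMovie]
#' @param seed integer RNG seed
#' @return a [VoltageMovie] surrogate
#' @export
shuffleSpatial <- function(movie, seed = 1L) {
  stopifnot(is(movie, "VoltageMovie"))
  d <- frameDims(movie)
  X <- movieToMatrix(movieData(movie))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(ncol(X))
  VoltageMovie(matrixToMovie(X[, perm, drop = FALSE], d[1], d[2]),
               frameRate = frameRate(movie), pixelPitch = pixelPitch(movie),
               validMask = validMask(movie))
}

#' Synthetic region map, hierarchy table and probability map
#'
#' Builds a fixture for the hierarchy-correlation analysis: contiguous
#' rectangular region labels tiling the grid, a per-region hierarchy index,
#' and a per-pixel probability map whose regional averages have an exact
#' (construction-enforced) Pearson correlation with the hierarchy index
#' equal to `targetCorr`. Within-region pixel noise is centred per region
#' so regional means are unchanged.
#'
#' @param shape `(H, W)` grid size
#' @param nRegions number of regions (>= 4)
#' @param targetCorr target Pearson correlation in `[-1, 1]`
#' @param seed integer RNG seed
#' @param withinSd standard deviation of within-region pixel variation
#' @return list with `regionMap` (H x W integer labels), `hierarchy`
#'   (data.frame: region, hierarchyIndex), `probabilityMap` (H x W)
#' @export
generateRegionFixture <- function(shape, nRegions = 21L, targetCorr = 0,
                                  seed = 1L, withinSd = 0.002) {
  H <- shape[1]; W <- shape[2]
  nRegions <- as.integer(nRegions)
  if (nRegions < 4L) stop("'nRegions' must be >= 4")
  if (abs(targetCorr) > 1) stop("'targetCorr' must be within [-1, 1]")
  if (nRegions > H * W / 4) stop("too many regions for this grid")

  # tile the grid: nb row-bands, regions split band-wise along columns
  nb <- max(1L, floor(sqrt(nRegions)))
  base <- nRegions %/% nb
  extra <- nRegions %% nb
  perBand <- rep(base, nb)
  if (extra > 0) perBand[seq_len(extra)] <- perBand[seq_len(extra)] + 1L
  rowEdges <- round(seq(0, H, length.out = nb + 1))
  regionMap <- matrix(0L, H, W)
  lab <- 0L
  for (b in seq_len(nb)) {
    rws <- (rowEdges[b] + 1):rowEdges[b + 1]
    colEdges <- round(seq(0, W, length.out = perBand[b] + 1))
    for (k in seq_len(perBand[b])) {
      lab <- lab + 1L
      regionMap[rws, (colEdges[k] + 1):colEdges[k + 1]] <- lab
    }
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- runif(nRegions)
  # regional means with exact correlation: project noise orthogonal to h
  zh <- as.numeric(scale(h))
  e <- rnorm(nRegions)
  e <- e - mean(e)
  e <- e - sum(e * zh) / sum(zh * zh) * zh
  if (sum(e^2) < .Machine$double.eps)
    stop("degenerate residual; cannot hit target correlation with so few regions")
  ze <- e / sqrt(sum(e^2) / (nRegions - 1))
  z <- targetCorr * zh + sqrt(1 - targetCorr^2) * ze
  # affine map into a positive probability range (correlation invariant)
  m <- 0.05 * (1 + 0.8 * z / max(abs(z), 1e-12))
  probabilityMap <- matrix(m[regionMap], H, W)
  if (withinSd > 0) {
    noise <- matrix(rnorm(H * W, sd = withinSd), H, W)
    # centre the noise within each region so regional means are exact
    noise <- noise - ave(as.vector(noise), as.vector(regionMap))
    probabilityMap <- pmax(probabilityMap + matrix(noise, H, W), 0)
  }
  got <- cor(rowsum(as.vector(probabilityMap), as.vector(regionMap))[, 1] /
               tabulate(regionMap, nRegions), h)
  if (abs(got - targetCorr) > 0.02)
    stop(sprintf("constructed correlation %.3f misses target %.3f", got,
                 targetCorr))
  list(regionMap = regionMap,
       hierarchy = data.frame(region = seq_len(nRegions), hierarchyIndex = h),
       probabilityMap = probabilityMap)
}
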