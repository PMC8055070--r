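#' VoltageMovie: a scalar-valued imaging movie
#'
#' Container for a T x H x W stack of population-voltage values (one scalar
#' per pixel per frame) with acquisition metadata. Row 1 is anterior
#' (rostral); columns increase laterally to the right. The per-frame
#' `validMask` marks frames usable for analysis (artifact masking flips
#' entries to `FALSE` without altering data).
#'
#' @slot data numeric array, dim T x H x W
#' @slot frameRate acquisition rate in Hz
#' @slot pixelPitch pixel size in micrometres (metadata only)
#' @slot validMask logical vector of length T
#'
#' @param data,frameRate,pixelPitch,validMask slot values; `validMask`
#'   defaults to all-`TRUE`
#' @param x a `VoltageMovie`
#' @export
setClass("VoltageMovie",
  representation(data = "array", frameRate = "numeric",
                 pixelPitch = "numeric", validMask = "logical"))

setValidity("VoltageMovie", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3-d array (frames x rows x cols)")
  if (d[1] < 2L) return("movie must have at least 2 frames")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("'frameRate' must be a single positive number")
  if (length(object@validMask) != d[1])
    return("'validMask' length must equal the number of frames")
  if (any(object@validMask) &&
      !all(is.finite(object@data[object@validMask, , , drop = FALSE])))
    return("non-finite values on frames marked valid")
  TRUE
})

#' @rdname VoltageMovie-class
#' @export
VoltageMovie <- function(data, frameRate, pixelPitch = NA_real_,
                         validMask = rep(TRUE, dim(data)[1])) {
  new("VoltageMovie", data = data, frameRate = frameRate,
      pixelPitch = as.numeric(pixelPitch), validMask = validMask)
}

#' PhaseMovie: instantaneous phase and envelope of a band-limited movie
#'
#' Per-pixel analytic-signal decomposition of a band-limited
#' [VoltageMovie]: `phase` in (-pi, pi] and the non-negative envelope
#' `amplitude`. `reliable` flags pixels/frames where the phase is
#' trustworthy (away from analytic-signal end transients and with envelope
#' well above zero).
#'
#' @slot phase numeric array T x H x W, radians in (-pi, pi]
#' @slot amplitude numeric array T x H x W, envelope (>= 0)
#' @slot frameRate Hz
#' @slot validMask logical length T (inherited from the movie)
#' @slot reliable logical array T x H x W
#'
#' @param phase,amplitude,frameRate,validMask,reliable slot values
#' @param x a `PhaseMovie`
#' @export
setClass("PhaseMovie",
  representation(phase = "array", amplitude = "array", frameRate = "numeric",
                 validMask = "logical", reliable = "array"))

setValidity("PhaseMovie", function(object) {
  d <- dim(object@phase)
  if (length(d) != 3L) return("'phase' must be a 3-d array")
  if (!identical(dim(object@amplitude), d))
    return("'amplitude' dimensions must match 'phase'")
  if (!identical(dim(object@reliable), d))
    return("'reliable' dimensions must match 'phase'")
  ph <- object@phase[object@reliable]
  if (length(ph) && (any(ph > pi + 1e-9) || any(ph <= -pi - 1e-9)))
    return("phase must lie in (-pi, pi]")
  amp <- object@amplitude[object@reliable]
  if (length(amp) && any(amp < 0)) return("amplitude must be >= 0")
  if (length(object@validMask) != d[1])
    return("'validMask' length must equal the number of frames")
  TRUE
})

#' @rdname PhaseMovie-class
#' @export
PhaseMovie <- function(phase, amplitude, frameRate,
                       validMask = rep(TRUE, dim(phase)[1]),
                       reliable = array(TRUE, dim(phase))) {
  new("PhaseMovie", phase = phase, amplitude = amplitude,
      frameRate = frameRate, validMask = validMask, reliable = reliable)
}

#' PhaseVelocityField: per-pixel wave propagation velocity for one frame
#'
#' The phase velocity field (PVF) of one frame pair, stored as a complex
#' H x W matrix `v = u + i*w` with `u` the column (lateral) velocity and
#' `w` the row velocity, in pixels/frame. Vectors point in the direction of
#' wave propagation. `reliability` marks pixels whose phase was reliable in
#' both frames; `converged` records whether the variational solver reached
#' its tolerance.
#'
#' @slot v complex H x W matrix, pixels/frame
#' @slot t index of the earlier of the two frames used
#' @slot reliability logical H x W
#' @slot converged logical flag from the solver
#' @slot iterations solver iteration count
#' @slot energy final value of the variational energy
#'
#' @param v,t,reliability,converged,iterations,energy slot values
#' @param x a `PhaseVelocityField`
#' @export
setClass("PhaseVelocityField",
  representation(v = "matrix", t = "integer", reliability = "matrix",
                 converged = "logical", iterations = "integer",
                 energy = "numeric"))

setValidity("PhaseVelocityField", function(object) {
  if (!is.complex(object@v)) return("'v' must be a complex matrix")
  if (!identical(dim(object@reliability), dim(object@v)))
    return("'reliability' dimensions must match 'v'")
  if (any(object@reliability & !is.finite(Re(object@v))))
    return("non-finite velocity on reliable pixels")
  TRUE
})

#' @rdname PhaseVelocityField-class
#' @export
PhaseVelocityField <- function(v, t = 1L,
                               reliability = matrix(TRUE, nrow(v), ncol(v)),
                               converged = TRUE, iterations = 0L,
                               energy = NA_real_) {
  if (!is.complex(v)) storage.mode(v) <- "complex"
  new("PhaseVelocityField", v = v, t = as.integer(t),
      reliability = reliability, converged = converged,
      iterations = as.integer(iterations), energy = energy)
}

#' SVDModeSet: principal spatial modes of a PVF sequence
#'
#' Result of the singular value decomposition of the stacked
#' velocity-field matrix (frames x 2HW, real parts then imaginary parts).
#' Modes are unit-norm in the flattened real embedding and ordered by
#' decreasing singular value.
#'
#' @slot modes complex array H x W x K of mode fields
#' @slot sigma singular values, descending
#' @slot varianceFractions sigma_k^2 / sum(sigma^2)
#' @slot projections frames x K real weight matrix (M = w R)
#' @slot frameIndex indices of the frames that entered the decomposition
#'
#' @param x an `SVDModeSet`
#' @export
setClass("SVDModeSet",
  representation(modes = "array", sigma = "numeric",
                 varianceFractions = "numeric", projections = "matrix",
                 frameIndex = "integer"))

setValidity("SVDModeSet", function(object) {
  k <- dim(object@modes)[3]
  if (length(object@sigma) != k || length(object@varianceFractions) != k)
    return("'sigma' and 'varianceFractions' must have one entry per mode")
  if (is.unsorted(rev(object@sigma))) return("singular values must descend")
  if (any(object@sigma < 0)) return("singular values must be >= 0")
  TRUE
})

#' FlowSettings: parameters of the variational optical-flow solver
#'
#' @param alpha weight of the spatial smoothness term (> 0)
#' @param penalty data-term penalty, `"charbonnier"` (robust, default) or
#'   `"quadratic"`
#' @param charbonnierEps Charbonnier epsilon (radians)
#' @param maxIters maximum fixed-point sweeps
#' @param tol relative energy-change convergence tolerance
#' @param nScales coarse-to-fine pyramid levels (1 = single scale)
#' @return a `FlowSettings` object
#' @export
flowSettings <- function(alpha = 0.5, penalty = c("charbonnier", "quadratic"),
                         charbonnierEps = 1e-3, maxIters = 300L,
                         tol = 1e-6, nScales = 3L) {
  penalty <- match.arg(penalty)
  stopifnot(alpha > 0, tol > 0, maxIters >= 1, charbonnierEps > 0,
            nScales >= 1)
  structure(list(alpha = alpha, penalty = penalty,
                 charbonnierEps = charbonnierEps,
                 maxIters = as.integer(maxIters), tol = tol,
                 nScales = as.integer(nScales)),
            class = "FlowSettings")
}

## ---- accessors ------------------------------------------------------------

#' @rdname VoltageMovie-class
#' @export
setMethod("movieData", "VoltageMovie", function(x) x@data)
#' @rdname VoltageMovie-class
#' @export
setMethod("frameRate", "VoltageMovie", function(x) x@frameRate)
#' @rdname VoltageMovie-class
#' @export
setMethod("frameRate", "PhaseMovie", function(x) x@frameRate)
#' @rdname VoltageMovie-class
#' @export
setMethod("pixelPitch", "VoltageMovie", function(x) x@pixelPitch)
#' @rdname VoltageMovie-class
#' @export
setMethod("validMask", "VoltageMovie", function(x) x@validMask)
#' @rdname VoltageMovie-class
#' @export
setMethod("validMask", "PhaseMovie", function(x) x@validMask)
#' @rdname VoltageMovie-class
#' @export
setMethod("nFrames", "VoltageMovie", function(x) dim(x@data)[1])
#' @rdname VoltageMovie-class
#' @export
setMethod("nFrames", "PhaseMovie", function(x) dim(x@phase)[1])
#' @rdname VoltageMovie-class
#' @export
setMethod("frameDims", "VoltageMovie", function(x) dim(x@data)[2:3])
#' @rdname VoltageMovie-class
#' @export
setMethod("frameDims", "PhaseMovie", function(x) dim(x@phase)[2:3])
#' @rdname PhaseMovie-class
#' @export
setMethod("phaseData", "PhaseMovie", function(x) x@phase)
#' @rdname PhaseMovie-class
#' @export
setMethod("amplitudeData", "PhaseMovie", function(x) x@amplitude)
#' @rdname PhaseMovie-class
#' @export
setMethod("reliability", "PhaseMovie", function(x) x@reliable)
#' @rdname PhaseVelocityField-class
#' @export
setMethod("velocity", "PhaseVelocityField", function(x) x@v)
#' @rdname PhaseVelocityField-class
#' @export
setMethod("frameIndex", "PhaseVelocityField", function(x) x@t)
#' @rdname PhaseVelocityField-class
#' @export
setMethod("reliability", "PhaseVelocityField", function(x) x@reliability)
#' @rdname SVDModeSet-class
#' @export
setMethod("modeFields", "SVDModeSet", function(x) x@modes)
#' @rdname SVDModeSet-class
#' @export
setMethod("singularValues", "SVDModeSet", function(x) x@sigma)
#' @rdname SVDModeSet-class
#' @export
setMethod("varianceFractions", "SVDModeSet", function(x) x@varianceFractions)
#' @rdname SVDModeSet-class
#' @export
setMethod("projections", "SVDModeSet", function(x) x@projections)

## ---- show methods ---------------------------------------------------------

setMethod("show", "VoltageMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "VoltageMovie: %d frames of %d x %d @ %g Hz (%d valid frames)\n",
    d[1], d[2], d[3], object@frameRate, sum(object@validMask)))
})

setMethod("show", "PhaseMovie", function(object) {
  d <- dim(object@phase)
  cat(sprintf(
    "PhaseMovie: %d frames of %d x %d @ %g Hz (%.1f%% reliable pixels)\n",
    d[1], d[2], d[3], object@frameRate, 100 * mean(object@reliable)))
})

setMethod("show", "PhaseVelocityField", function(object) {
  d <- dim(object@v)
  sp <- Mod(object@v[object@reliability])
  cat(sprintf(
    "PhaseVelocityField: %d x %d at frame %d; mean speed %.3g px/frame%s\n",
    d[1], d[2], object@t, if (length(sp)) mean(sp) else NA_real_,
    if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SVDModeSet", function(object) {
  k <- dim(object@modes)[3]
  cat(sprintf(
    "SVDModeSet: %d modes of %d x %d over %d frames; top-3 variance %.1f%%\n",
    k, dim(object@modes)[1], dim(object@modes)[2], nrow(object@projections),
    100 * sum(object@varianceFractions[seq_len(min(3, k))])))
})
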