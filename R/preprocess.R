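#' Spatial coarse-graining by bicubic interpolation
#'
#' Resamples every frame at the given scale with cubic convolution (Keys
#' kernel, weighted average of the nearest 4 x 4 neighborhood), the
#' standard noise-reduction step before phase-velocity estimation. An
#' 88 x 104 frame at scale 0.5 becomes 44 x 52. Frame count, frame rate
#' and valid mask are unchanged; pixel pitch is divided by the scale.
#'
#' @param movie a [VoltageMovie]
#' @param scale resampling factor in (0, 1)
#' @return a [VoltageMovie] with smaller frames
#' @export
coarseGrain <- function(movie, scale = 0.5) {
  stopifnot(is(movie, "VoltageMovie"))
  if (scale <= 0 || scale >= 1) stop("'scale' must be in (0, 1)")
  d <- frameDims(movie)
  Hn <- max(1L, round(d[1] * scale)); Wn <- max(1L, round(d[2] * scale))
  if (Hn < 4L || Wn < 4L)
    stop("'scale' = ", scale, " would leave fewer than 4 pixels per side")
  Wr <- cubicWeights(d[1], scale)
  Wc <- cubicWeights(d[2], scale)
  dat <- movieData(movie)
  out <- array(0, dim = c(nFrames(movie), Hn, Wn))
  for (t in seq_len(nFrames(movie)))
    out[t, , ] <- resizeFrame(dat[t, , ], scale, Wr, Wc)
  VoltageMovie(out, frameRate = frameRate(movie),
               pixelPitch = pixelPitch(movie) / scale,
               validMask = validMask(movie))
}

# minimal analog Chebyshev-II order selection for a bandpass design:
# prewarp edges, map through the lowpass prototype, apply the standard
# inverse-Chebyshev order formula.
cheby2BandpassOrder <- function(passHz, stopHz, fs, Rp = 1, Rs = 40) {
  warp <- function(f) tan(pi * f / fs)
  wp <- warp(passHz); ws <- warp(stopHz)
  bw <- wp[2] - wp[1]; w0sq <- wp[1] * wp[2]
  Omega <- function(w) abs((w^2 - w0sq) / (w * bw))
  OmegaS <- min(Omega(ws[1]), Omega(ws[2]))
  num <- acosh(sqrt((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1)))
  max(1L, as.integer(ceiling(num / acosh(OmegaS))))
}

#' Zero-phase temporal bandpass filtering
#'
#' Per-pixel zero-phase (forward-backward) Chebyshev type II bandpass
#' filtering, the narrowband step that isolates the delta-band (default
#' 0.5-4 Hz) oscillation before phase extraction. The filter order is
#' selected by the standard inverse-Chebyshev order rule for the
#' requested stopband attenuation at the given stopband edges. The
#' forward-backward pass (squared-magnitude response, zero group delay by
#' construction) is applied in the frequency domain on
#' reflection-padded traces, which makes the operation exactly symmetric
#' under time reversal and numerically stable for narrow bands.
#'
#' @param movie a [VoltageMovie]
#' @param band `(low, high)` passband edges in Hz
#' @param stopband `(low, high)` stopband edges in Hz (defaults to
#'   `band[1]/2` and `2*band[2]`)
#' @param attenuationDb stopband attenuation of the design, dB
#' @return a band-limited [VoltageMovie]
#' @export
bandpass <- function(movie, band = c(0.5, 4), stopband = NULL,
                     attenuationDb = 40) {
  stopifnot(is(movie, "VoltageMovie"))
  fs <- frameRate(movie)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("'band' must satisfy 0 < low < high < frameRate/2")
  if (is.null(stopband)) stopband <- c(band[1] / 2, min(2 * band[2], fs / 2 * 0.98))
  n <- cheby2BandpassOrder(band, stopband, fs, Rs = attenuationDb)
  flt <- signal::cheby2(n, attenuationDb, stopband * 2 / fs, type = "pass")
  d <- frameDims(movie)
  Tn <- nFrames(movie)
  X <- movieToMatrix(movieData(movie))
  # reflect-pad each trace (same length both sides), apply |H(w)|^2 on
  # the FFT grid, crop back
  npad <- min(Tn - 1L, as.integer(ceiling(2 * fs / band[1])))
  pre <- if (npad > 0) X[(npad + 1):2, , drop = FALSE] else NULL
  post <- if (npad > 0) X[(Tn - 1):(Tn - npad), , drop = FALSE] else NULL
  Xp <- rbind(pre, X, post)
  Np <- nrow(Xp)
  wGrid <- 2 * pi * (seq_len(Np) - 1) / Np           # radians/sample
  ew <- exp(-1i * outer(wGrid, seq(0, length(flt$b) - 1)))
  ea <- exp(-1i * outer(wGrid, seq(0, length(flt$a) - 1)))
  H <- as.vector(ew %*% flt$b) / as.vector(ea %*% flt$a)
  gain <- Mod(H)^2                                   # forward + backward
  Y <- Re(mvfft(mvfft(Xp) * gain, inverse = TRUE)) / Np
  Y <- Y[npad + seq_len(Tn), , drop = FALSE]
  VoltageMovie(matrixToMovie(Y, d[1], d[2]), frameRate = fs,
               pixelPitch = pixelPitch(movie), validMask = validMask(movie))
}

#' Flag movement-artifact periods
#'
#' Marks as invalid the frames whose spatially averaged (band-limited)
#' signal deviates from its temporal mean by more than `kSd` standard
#' deviations, plus a guard margin on either side to cover filter ringing.
#' Data values are never altered; only `validMask` changes.
#'
#' @param movie a band-limited [VoltageMovie]
#' @param kSd threshold in standard deviations of the spatial-mean trace
#' @param guardS guard margin in seconds around each flagged sample
#' @return the movie with an updated `validMask`
#' @export
maskArtifacts <- function(movie, kSd = 3, guardS = 0.5) {
  stopifnot(is(movie, "VoltageMovie"))
  m <- apply(movieData(movie), 1, mean)
  dev <- abs(m - mean(m))
  flag <- dev > kSd * sd(m)
  if (kSd <= 0) flag <- rep(TRUE, length(m))
  guard <- ceiling(guardS * frameRate(movie))
  if (any(flag) && guard > 0) {
    idx <- which(flag)
    for (i in idx)
      flag[max(1, i - guard):min(length(flag), i + guard)] <- TRUE
  }
  mask <- validMask(movie) & !flag
  if (!any(mask))
    stop("all frames flagged as artifacts: recording unusable at kSd = ", kSd)
  VoltageMovie(movieData(movie), frameRate = frameRate(movie),
               pixelPitch = pixelPitch(movie), validMask = mask)
}

#' Instantaneous phase and envelope via the analytic signal
#'
#' Computes the per-pixel analytic signal (Hilbert transform) of a
#' band-limited movie: phase is the argument, amplitude the modulus.
#' Reliability flags exclude (i) the first and last `1/bandLow` seconds
#' (analytic-signal end transients) and (ii) pixels whose envelope falls
#' below `1e-6` times the median envelope (phase undefined near zero
#' amplitude).
#'
#' @param movie a band-limited [VoltageMovie]
#' @param bandLow low passband edge in Hz used for the edge-transient
#'   margin
#' @param edgeSeconds override for the edge margin in seconds (defaults to
#'   `1/bandLow`)
#' @return a [PhaseMovie]
#' @export
instantaneousPhase <- function(movie, bandLow = 0.5, edgeSeconds = NULL) {
  stopifnot(is(movie, "VoltageMovie"))
  dat <- movieData(movie)
  if (!all(is.finite(dat))) stop("movie contains non-finite values")
  d <- frameDims(movie)
  Tn <- nFrames(movie)
  Z <- analyticSignal(movieToMatrix(dat))
  phase <- matrixToMovie(Arg(Z), d[1], d[2])
  amp <- matrixToMovie(Mod(Z), d[1], d[2])
  rel <- array(TRUE, dim = c(Tn, d[1], d[2]))
  edge <- if (is.null(edgeSeconds)) 1 / bandLow else edgeSeconds
  nEdge <- min(floor(edge * frameRate(movie)), floor((Tn - 1) / 2))
  if (nEdge > 0) {
    rel[seq_len(nEdge), , ] <- FALSE
    rel[(Tn - nEdge + 1):Tn, , ] <- FALSE
  }
  medAmp <- median(amp)
  rel[amp < 1e-6 * medAmp] <- FALSE
  PhaseMovie(phase, amp, frameRate = frameRate(movie),
             validMask = validMask(movie), reliable = rel)
}
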