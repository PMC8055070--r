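# Variational estimation of phase velocity fields.
#
# The data term enforces phase constancy between consecutive frames,
# dphi_t + u * dphi/dx + w * dphi/dy = 0, with all phase differences
# computed circularly (via arguments of phasor products) so the estimate
# is invariant to phase wrapping. The smoothness term penalises spatial
# gradients of both velocity components. The discrete Euler-Lagrange
# equations are solved by red-black Gauss-Seidel sweeps with an exact
# 2 x 2 block solve per pixel; the robust (Charbonnier) data penalty is
# handled by lagged half-quadratic reweighting, which keeps the energy
# non-increasing.

# zero-padded one-pixel shift (out-of-grid contributions are zero)
shiftZero <- function(M, dr = 0L, dc = 0L) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
  ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
  out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

# circular spatial gradient of a phasor field: central differences in the
# interior, one-sided at the borders (replicate-equivalent)
phasorGradient <- function(z) {
  H <- nrow(z); W <- ncol(z)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3)
    gx[, 2:(W - 1)] <- Arg(z[, 3:W, drop = FALSE] *
                           Conj(z[, 1:(W - 2), drop = FALSE])) / 2
  if (W >= 2) {
    gx[, 1] <- Arg(z[, 2] * Conj(z[, 1]))
    gx[, W] <- Arg(z[, W] * Conj(z[, W - 1]))
  }
  if (H >= 3)
    gy[2:(H - 1), ] <- Arg(z[3:H, , drop = FALSE] *
                           Conj(z[1:(H - 2), , drop = FALSE])) / 2
  if (H >= 2) {
    gy[1, ] <- Arg(z[2, ] * Conj(z[1, ]))
    gy[H, ] <- Arg(z[H, ] * Conj(z[H - 1, ]))
  }
  list(gx = gx, gy = gy)
}

# variational energy of a candidate flow
flowEnergy <- function(u, w, phit, gx, gy, wd, settings) {
  r <- phit + u * gx + w * gy
  data <- if (settings$penalty == "quadratic") sum(wd * r^2) else
    sum(wd * sqrt(r^2 + settings$charbonnierEps^2))
  H <- nrow(u); W <- ncol(u)
  du2 <- 0
  if (W >= 2) du2 <- du2 + sum((u[, -1] - u[, -W])^2) + sum((w[, -1] - w[, -W])^2)
  if (H >= 2) du2 <- du2 + sum((u[-1, ] - u[-H, ])^2) + sum((w[-1, ] - w[-H, ])^2)
  data + settings$alpha * du2
}

# one Gauss-Seidel half-sweep over the pixels selected by `mask`
gsHalfSweep <- function(u, w, mask, phit, gx, gy, dataW, alpha, deg) {
  Su <- shiftZero(u, -1L, 0L) + shiftZero(u, 1L, 0L) +
        shiftZero(u, 0L, -1L) + shiftZero(u, 0L, 1L)
  Sw <- shiftZero(w, -1L, 0L) + shiftZero(w, 1L, 0L) +
        shiftZero(w, 0L, -1L) + shiftZero(w, 0L, 1L)
  a11 <- dataW * gx^2 + alpha * deg
  a12 <- dataW * gx * gy
  a22 <- dataW * gy^2 + alpha * deg
  b1 <- -dataW * gx * phit + alpha * Su
  b2 <- -dataW * gy * phit + alpha * Sw
  det <- a11 * a22 - a12^2
  un <- (a22 * b1 - a12 * b2) / det
  wn <- (a11 * b2 - a12 * b1) / det
  u[mask] <- un[mask]
  w[mask] <- wn[mask]
  list(u = u, w = w)
}

# single-scale fixed-point solve of the Euler-Lagrange system
solveFlow <- function(phit, gx, gy, wd, settings, u0 = NULL, w0 = NULL) {
  H <- nrow(phit); W <- ncol(phit)
  u <- if (is.null(u0)) matrix(0, H, W) else u0
  w <- if (is.null(w0)) matrix(0, H, W) else w0
  deg <- matrix(4, H, W) -
    (row(phit) == 1) - (row(phit) == H) - (col(phit) == 1) - (col(phit) == W)
  parity <- (row(phit) + col(phit)) %% 2 == 0
  eps2 <- settings$charbonnierEps^2
  energies <- numeric(0)
  E <- flowEnergy(u, w, phit, gx, gy, wd, settings)
  converged <- FALSE
  iters <- 0L
  for (k in seq_len(settings$maxIters)) {
    dataW <- if (settings$penalty == "quadratic") wd else {
      r <- phit + u * gx + w * gy
      wd * 0.5 / sqrt(r^2 + eps2)       # half-quadratic majorizer weight
    }
    s <- gsHalfSweep(u, w, parity, phit, gx, gy, dataW, settings$alpha, deg)
    s <- gsHalfSweep(s$u, s$w, !parity, phit, gx, gy, dataW, settings$alpha, deg)
    maxUpd <- max(abs(s$u - u), abs(s$w - w))
    u <- s$u; w <- s$w
    Enew <- flowEnergy(u, w, phit, gx, gy, wd, settings)
    energies <- c(energies, Enew)
    iters <- k
    if (abs(E - Enew) <= settings$tol * max(abs(E), .Machine$double.eps) &&
        maxUpd <= sqrt(settings$tol) * (1 + max(abs(u), abs(w)))) {
      converged <- TRUE
      E <- Enew
      break
    }
    E <- Enew
  }
  list(u = u, w = w, converged = converged, iterations = iters,
       energy = E, energies = energies)
}

# resize helper producing an explicit output length
cubicWeightsTo <- function(n, nOut) {
  scale <- nOut / n
  W <- matrix(0, nOut, n)
  for (i in seq_len(nOut)) {
    x <- (i - 0.5) / scale + 0.5
    base <- floor(x)
    taps <- (base - 1):(base + 2)
    wts <- cubicKernel(x - taps)
    taps <- pmin(pmax(taps, 1L), n)
    for (j in seq_along(taps)) W[i, taps[j]] <- W[i, taps[j]] + wts[j]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

resizeTo <- function(M, Hn, Wn) {
  cubicWeightsTo(nrow(M), Hn) %*% M %*% t(cubicWeightsTo(ncol(M), Wn))
}

# coarse-to-fine solve on phasor pyramids; the energy is convex, so the
# pyramid only provides a good initialisation for the fine scale
flowPyramid <- function(z1, z2, wd, settings, level) {
  H <- nrow(z1); W <- ncol(z1)
  u0 <- w0 <- NULL
  if (level > 1 && min(H, W) >= 16) {
    Hc <- floor(H / 2); Wc <- floor(W / 2)
    normz <- function(z) {
      zr <- resizeTo(Re(z), Hc, Wc) + 1i * resizeTo(Im(z), Hc, Wc)
      m <- Mod(zr)
      zr[m < 1e-12] <- 1
      zr / Mod(zr)
    }
    wdc <- (resizeTo(wd, Hc, Wc) > 0.5) * 1
    coarse <- flowPyramid(normz(z1), normz(z2), wdc, settings, level - 1L)
    u0 <- resizeTo(coarse$u, H, W) * (W / Wc)
    w0 <- resizeTo(coarse$w, H, W) * (H / Hc)
  }
  phit <- Arg(z2 * Conj(z1))
  g1 <- phasorGradient(z1); g2 <- phasorGradient(z2)
  gx <- (g1$gx + g2$gx) / 2
  gy <- (g1$gy + g2$gy) / 2
  solveFlow(phit, gx, gy, wd, settings, u0, w0)
}

#' Estimate the phase velocity field for one frame pair
#'
#' Minimises the variational energy
#' `E(v) = sum_pixels rho(dphi_t + u dphi/dx + w dphi/dy)
#'        + alpha (||grad u||^2 + ||grad w||^2)`
#' over the field `v = u + i w` (pixels/frame), where all phase
#' differences are circular (computed through unit phasors) and `rho` is
#' the quadratic or Charbonnier penalty of the [flowSettings()]. Pixels
#' unreliable in either frame are excluded from the data term but smoothed
#' over. The returned vectors point in the direction of wave propagation.
#'
#' @param phase a [PhaseMovie]
#' @param t frame index; frames `t` and `t+1` must be valid
#' @param settings a [flowSettings()] object
#' @return a [PhaseVelocityField] aligned to frame `t`
#' @export
estimatePVF <- function(phase, t, settings = flowSettings()) {
  stopifnot(is(phase, "PhaseMovie"))
  Tn <- nFrames(phase)
  t <- as.integer(t)
  if (t < 1L || t + 1L > Tn) stop("frame pair (", t, ", ", t + 1, ") out of range")
  vm <- validMask(phase)
  if (!vm[t] || !vm[t + 1L]) stop("frames ", t, " and ", t + 1,
                                  " must both be valid")
  ph <- phaseData(phase)
  z1 <- exp(1i * ph[t, , ])
  z2 <- exp(1i * ph[t + 1L, , ])
  rel <- reliability(phase)[t, , ] & reliability(phase)[t + 1L, , ]
  if (!any(rel)) stop("no reliable pixels at frame ", t)
  wd <- rel * 1
  sol <- flowPyramid(z1, z2, wd, settings, settings$nScales)
  if (!sol$converged)
    warning("flow solver did not converge in ", settings$maxIters,
            " iterations at frame ", t)
  PhaseVelocityField(sol$u + 1i * sol$w, t = t, reliability = rel,
                     converged = sol$converged,
                     iterations = sol$iterations, energy = sol$energy)
}

#' Estimate phase velocity fields for every valid frame pair
#'
#' @param phase a [PhaseMovie]
#' @param settings a [flowSettings()]
#' @param frames optional subset of frame indices (earlier frame of each
#'   pair); defaults to all pairs with both frames valid
#' @return a list of [PhaseVelocityField] objects
#' @export
estimatePVFSeries <- function(phase, settings = flowSettings(),
                              frames = NULL) {
  vm <- validMask(phase)
  Tn <- nFrames(phase)
  if (is.null(frames)) {
    frames <- which(vm[-Tn] & vm[-1])
    # skip frames with no reliable pixels (e.g. analytic-signal edges)
    rel <- reliability(phase)
    anyRel <- vapply(seq_len(Tn), function(t) any(rel[t, , ]), logical(1))
    frames <- frames[anyRel[frames] & anyRel[frames + 1L]]
  }
  lapply(frames, function(t) estimatePVF(phase, t, settings))
}

#' Spatially averaged gradient magnitude of a PVF
#'
#' The coherence statistic separating structured waves from surrogate
#' data: the per-pixel velocity gradient stacks the x- and y-derivatives
#' (central differences) of both components into a 2 x 2 matrix whose
#' Frobenius norm is averaged over reliable pixels. Organised waves give
#' small values; shuffled data give large ones.
#'
#' @param field a [PhaseVelocityField]
#' @return the mean gradient magnitude (scalar)
#' @export
pvfGradient <- function(field) {
  stopifnot(is(field, "PhaseVelocityField"))
  v <- velocity(field)
  rel <- reliability(field)
  if (!any(rel)) stop("no reliable pixels in field")
  gu <- gradientXY(Re(v))
  gw <- gradientXY(Im(v))
  g <- sqrt(gu$dx^2 + gu$dy^2 + gw$dx^2 + gw$dy^2)
  mean(g[rel])
}

#' Gradient-of-PVF time series
#'
#' Maps [estimatePVF()] + [pvfGradient()] over all valid frame pairs,
#' skipping masked frames.
#'
#' @param phase a [PhaseMovie]
#' @param settings a [flowSettings()]
#' @return data.frame with columns `t` and `gradient`
#' @export
gradientSeries <- function(phase, settings = flowSettings()) {
  fields <- estimatePVFSeries(phase, settings)
  if (!length(fields))
    return(data.frame(t = integer(0), gradient = numeric(0)))
  data.frame(t = vapply(fields, frameIndex, integer(1)),
             gradient = vapply(fields, pvfGradient, numeric(1)))
}
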