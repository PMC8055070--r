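test_that("plane-wave flow matches the analytic minimal-norm solution", {
  k <- c(0, 0.2); freq <- 2; fs <- 150
  pm <- planePhaseMovie(Tn = 20, H = 24, W = 24, k = k, freq = freq, fs = fs)
  f <- estimatePVF(pm, 8, flowSettings())
  v <- velocity(f)[5:20, 5:20]
  wf <- 2 * pi * freq / fs
  vExp <- wf * complex(real = k[2], imaginary = k[1]) / sum(k^2)
  dirErr <- abs(atan2(sin(Arg(v) - Arg(vExp)), cos(Arg(v) - Arg(vExp))))
  expect_lt(max(dirErr) * 180 / pi, 5)
  expect_lt(max(abs(Mod(v) - Mod(vExp)) / Mod(vExp)), 0.10)
  expect_true(f@converged)
  # sign convention: v points along propagation (+x here)
  expect_true(all(Re(v) > 0))
})

test_that("static phase gives zero flow and radial waves point outward", {
  ph <- array(0, c(4, 16, 16))
  for (t in 1:4) ph[t, , ] <- outer((1:16) * 0.2, (1:16) * 0.1, "+")
  ph <- (ph + pi) %% (2 * pi) - pi
  pm <- PhaseMovie(ph, array(1, dim(ph)), 150)
  f <- estimatePVF(pm, 2, flowSettings(penalty = "quadratic", nScales = 1))
  expect_lt(max(Mod(velocity(f))), 1e-6)

  pmr <- radialPhaseMovie(Tn = 10, H = 30, W = 30, center = c(15, 15),
                          kr = 0.35, freq = 2, fs = 150)
  fr <- estimatePVF(pmr, 5, flowSettings())
  v <- velocity(fr)
  rr <- matrix(1:30, 30, 30); cc <- t(rr)
  d <- sqrt((rr - 15)^2 + (cc - 15)^2)
  vrad <- Re(v) * (cc - 15) / d + Im(v) * (rr - 15) / d
  sel <- d >= 3 & d <= 10
  expect_gte(mean(vrad[sel] > 0), 0.95)
})

test_that("fixed-point solution matches a dense Euler-Lagrange solve", {
  set.seed(4)
  ph <- array(0, c(2, 8, 8))
  ph[1, , ] <- matrix(runif(64, -1, 1), 8, 8)
  ph[2, , ] <- ph[1, , ] + matrix(runif(64, -0.3, 0.3), 8, 8)
  pm <- PhaseMovie(ph, array(1, dim(ph)), 150)
  st <- flowSettings(alpha = 0.5, penalty = "quadratic", nScales = 1,
                     maxIters = 100000, tol = 1e-20)
  f <- estimatePVF(pm, 1, st)
  z1 <- exp(1i * ph[1, , ]); z2 <- exp(1i * ph[2, , ])
  g1 <- cortexwave:::phasorGradient(z1)
  g2 <- cortexwave:::phasorGradient(z2)
  oracle <- denseFlowSolve(Arg(z2 * Conj(z1)), (g1$gx + g2$gx) / 2,
                           (g1$gy + g2$gy) / 2, matrix(1, 8, 8), 0.5)
  expect_lt(max(abs(Re(velocity(f)) - oracle$u)), 1e-8)
  expect_lt(max(abs(Im(velocity(f)) - oracle$w)), 1e-8)
})

test_that("flow is invariant to phase wrapping and equivariant to rotation", {
  pm <- planePhaseMovie(Tn = 6, H = 9, W = 9, k = c(0.15, 0.1), freq = 2,
                        fs = 150)
  st <- flowSettings(penalty = "quadratic", nScales = 1, tol = 1e-13,
                     maxIters = 20000)
  f0 <- velocity(estimatePVF(pm, 3, st))
  # add 2*pi to one pixel of both frames: the solver sees the phase only
  # through unit phasors, so the field is unchanged
  ph <- phaseData(pm)
  z1 <- exp(1i * ph[3, , ]); z2 <- exp(1i * ph[4, , ])
  z1w <- z1; z2w <- z2
  z1w[5, 5] <- exp(1i * (ph[3, 5, 5] + 2 * pi))
  z2w[5, 5] <- exp(1i * (ph[4, 5, 5] + 2 * pi))
  wd <- matrix(1, 9, 9)
  s0 <- cortexwave:::flowPyramid(z1, z2, wd, st, 1L)
  s1 <- cortexwave:::flowPyramid(z1w, z2w, wd, st, 1L)
  expect_lt(max(abs(s1$u - s0$u)) + max(abs(s1$w - s0$w)), 1e-9)
  expect_lt(max(abs(s0$u - Re(f0))) + max(abs(s0$w - Im(f0))), 1e-12)
  # rotate input frames by 90 degrees: field rotates with them
  rot <- function(M) t(M)[, nrow(M):1, drop = FALSE]   # (r,c) -> (c, H+1-r)
  phR <- array(0, dim(phaseData(pm)))
  for (t in 1:6) phR[t, , ] <- rot(phaseData(pm)[t, , ])
  fR <- velocity(estimatePVF(PhaseMovie(phR, array(1, dim(phR)), 150), 3, st))
  # under (r', c') = (c, H+1-r): u' = -w, w' = u
  expected <- rot(-Im(f0)) + 1i * rot(Re(f0))
  expect_lt(max(Mod(fR - expected)[2:8, 2:8]), 1e-6)
})

test_that("the variational energy is non-increasing across iterations", {
  set.seed(9)
  phit <- matrix(runif(144, -1, 1), 12, 12)
  gx <- matrix(runif(144, -0.5, 0.5), 12, 12)
  gy <- matrix(runif(144, -0.5, 0.5), 12, 12)
  wd <- matrix(1, 12, 12)
  for (pen in c("quadratic", "charbonnier")) {
    st <- flowSettings(penalty = pen, nScales = 1, maxIters = 150)
    sol <- cortexwave:::solveFlow(phit, gx, gy, wd, st)
    expect_true(all(diff(sol$energies) <= 1e-10 * max(sol$energies)))
  }
})

test_that("pvf gradient statistic matches closed forms", {
  # spatially uniform field -> 0
  u <- PhaseVelocityField(matrix(2 + 1i, 10, 10))
  expect_equal(pvfGradient(u), 0)
  # v = (x, 0): per-pixel gradient norm 1 everywhere under central diffs
  H <- 20; W <- 20
  lin <- PhaseVelocityField(matrix(rep(1:W, each = H), H, W) + 0i)
  expect_equal(pvfGradient(lin), 1, tolerance = 1e-12)
  expect_error(pvfGradient(PhaseVelocityField(matrix(0i, 4, 4),
               reliability = matrix(FALSE, 4, 4))), "reliable")
})

test_that("gradient series separates structured from shuffled movies", {
  # 2 Hz wave sampled at 20 Hz: several full cycles in 40 frames, so the
  # analytic-signal phase is well defined
  sp <- movieSpec(c(40, 20, 20), frameRate = 20, noiseSd = 0,
                  components = list(waveComponent("plane",
                    wavevector = c(0, 0.3), freq = 2)))
  m <- generateMovie(sp)
  phS <- instantaneousPhase(m, edgeSeconds = 0)
  phN <- instantaneousPhase(shuffleSpatial(m, 5), edgeSeconds = 0)
  st <- flowSettings(maxIters = 100)
  gS <- gradientSeries(phS, st)
  # surrogate data have no coherent flow; capped iterations are expected
  gN <- suppressWarnings(gradientSeries(phN, st))
  expect_lt(max(gS$gradient), 0.05)            # smooth plane-wave flow
  expect_gt(median(gN$gradient) / median(gS$gradient), 5)
  # masked frames are skipped; empty valid set gives an empty series
  pmEmpty <- PhaseMovie(array(0, c(4, 8, 8)), array(1, c(4, 8, 8)), 150,
                        validMask = rep(FALSE, 4))
  expect_equal(nrow(gradientSeries(pmEmpty)), 0)
})
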