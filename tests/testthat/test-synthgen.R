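test_that("generated movies follow the component formulas", {
  # plane wave, no noise: value at phase-field zero, t = 0, is the amplitude
  sp <- movieSpec(c(10, 12, 12), frameRate = 150, noiseSd = 0,
                  components = list(waveComponent("plane",
                    wavevector = c(0, 0.25), freq = 2, amplitude = 1.7)))
  m <- generateMovie(sp)
  expect_equal(movieData(m)[1, 1, 1], 1.7)   # col 1 => phase field 0, t = 0
  # standing wave: nodes where cos(k.x) = 0 stay zero for all t
  kc <- pi / 6                               # node at col 4 (x = 3)
  sp2 <- movieSpec(c(30, 12, 12), frameRate = 150, noiseSd = 0,
                   components = list(waveComponent("standing",
                     wavevector = c(0, kc), freq = 2)))
  m2 <- generateMovie(sp2)
  expect_lt(max(abs(movieData(m2)[, , 4])), 1e-12)
  # determinism: identical seed => bit-identical movie
  spn <- movieSpec(c(8, 8, 8), noiseSd = 0.3, seed = 42L)
  expect_identical(movieData(generateMovie(spn)), movieData(generateMovie(spn)))
  # invalid specs rejected with the offending field named
  expect_error(movieSpec(c(1, 8, 8)), "shape")
  expect_error(movieSpec(c(10, 8, 8), noiseSd = -1), "noiseSd")
  expect_error(waveComponent("plane", wavevector = c(0, 0.1), amplitude = 0),
               "amplitude")
})

test_that("source movie yields an outward-pointing PVF near the center", {
  pm <- radialPhaseMovie(Tn = 20, H = 32, W = 32, center = c(16, 16),
                         kr = 0.3, freq = 2, fs = 150)
  f <- estimatePVF(pm, 10, flowSettings())
  v <- velocity(f)
  rr <- matrix(1:32, 32, 32); cc <- t(rr)
  d <- sqrt((rr - 16)^2 + (cc - 16)^2)
  sel <- abs(d - 5) < 0.6                    # ring at radius ~5
  ang <- atan2(Im(v), Re(v))
  angRad <- atan2(rr - 16, cc - 16)          # analytic outward direction
  err <- abs(atan2(sin(ang - angRad), cos(ang - angRad)))
  expect_lt(max(err[sel]) * 180 / pi, 10)
})

test_that("temporal shuffling preserves per-pixel power spectra", {
  sp <- movieSpec(c(64, 8, 8), frameRate = 150, noiseSd = 0,
                  components = list(waveComponent("plane",
                    wavevector = c(0, 0.3), freq = 2)))
  m <- generateMovie(sp)
  st <- shuffleTemporal(m, seed = 7)
  A <- abs(mvfft(matrix(movieData(m), 64)))
  B <- abs(mvfft(matrix(movieData(st), 64)))
  expect_lt(max(abs(A - B) / (A + 1e-12)), 1e-9)
  expect_true(all(abs(Im(movieData(st))) == 0))
  # constant movie has only a DC component: unchanged
  cm <- VoltageMovie(array(2.5, c(16, 8, 8)), 150)
  expect_equal(movieData(shuffleTemporal(cm, 1)), movieData(cm),
               tolerance = 1e-12)
  # odd frame count exercises the odd-T Hermitian branch
  modd <- VoltageMovie(array(rnorm(15 * 64), c(15, 8, 8)), 150)
  sodd <- shuffleTemporal(modd, 3)
  Ao <- abs(mvfft(matrix(movieData(modd), 15)))
  Bo <- abs(mvfft(matrix(movieData(sodd), 15)))
  expect_lt(max(abs(Ao - Bo) / (Ao + 1e-12)), 1e-9)
})

test_that("spatial shuffling permutes pixels identically on every frame", {
  sp <- movieSpec(c(12, 8, 8), frameRate = 150, noiseSd = 0.2, seed = 5L)
  m <- generateMovie(sp)
  s1 <- shuffleSpatial(m, seed = 11)
  s2 <- shuffleSpatial(m, seed = 11)
  expect_identical(movieData(s1), movieData(s2))
  # frame-wise multiset equality (each pixel keeps its own time series)
  for (t in c(1, 7)) {
    expect_equal(sort(as.vector(movieData(s1)[t, , ])),
                 sort(as.vector(movieData(m)[t, , ])))
  }
  # a spatially uniform movie is unchanged
  u <- VoltageMovie(array(rep(rnorm(12), 64), c(12, 8, 8)), 150)
  expect_equal(movieData(shuffleSpatial(u, 3)), movieData(u))
})

test_that("spatial shuffling destroys plane-wave order", {
  # order parameter of the shuffled movie's PVF drops below the
  # plane-wave threshold in >= 95% of Monte-Carlo seeds
  pmStruct <- planePhaseMovie(Tn = 8, H = 16, W = 16, k = c(0, 0.35),
                              freq = 2, fs = 150)
  sp <- movieSpec(c(40, 16, 16), frameRate = 20, noiseSd = 0,
                  components = list(waveComponent("plane",
                    wavevector = c(0, 0.35), freq = 2)))
  m <- generateMovie(sp)
  drops <- vapply(1:20, function(s) {
    sh <- shuffleSpatial(m, seed = s)
    ph <- instantaneousPhase(sh, edgeSeconds = 0)
    orderParameter(suppressWarnings(
      estimatePVF(ph, 20, flowSettings(maxIters = 80))))
  }, numeric(1))
  expect_gte(mean(drops < 0.85), 0.95)
  # while the structured movie is squarely a plane wave
  expect_gt(orderParameter(estimatePVF(pmStruct, 4, flowSettings())), 0.99)
})

test_that("region fixtures hit the target correlation and shape", {
  fx <- generateRegionFixture(c(44, 52), nRegions = 21, targetCorr = -0.76,
                              seed = 3)
  expect_equal(nrow(fx$hierarchy), 21)
  expect_equal(sort(unique(as.vector(fx$regionMap))), 1:21)
  ra <- regionalAverage(fx$probabilityMap, fx$regionMap, fx$hierarchy)
  expect_equal(cor(ra$probability, ra$hierarchyIndex), -0.76,
               tolerance = 0.02)
  expect_true(all(fx$probabilityMap >= 0))
  expect_error(generateRegionFixture(c(20, 20), nRegions = 3,
                                     targetCorr = 0), "nRegions")
  expect_error(generateRegionFixture(c(20, 20), nRegions = 5,
                                     targetCorr = 1.2), "targetCorr")
})

test_that("linear-field generator rejects singular Jacobians", {
  expect_error(generateLinearField(matrix(c(1, 2, 2, 4), 2), c(5, 5), c(10, 10)),
               "singular")
})
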