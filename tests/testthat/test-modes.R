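test_that("flattening follows the real-then-imaginary row-major layout", {
  v <- matrix(complex(real = 1:6, imaginary = 7:12), 2, 3)
  x <- flattenPVF(v)
  expect_equal(length(x), 12)
  expect_equal(x[1:3], c(1, 3, 5))     # first row of the real part
  expect_equal(x[7:9], c(7, 9, 11))    # first row of the imaginary part
  expect_equal(unflattenPVF(x, 2, 3), v)
  # the documented full-frame size
  expect_equal(length(flattenPVF(matrix(0i, 44, 52))), 4576)
  expect_equal(flattenPVF(matrix(0i, 4, 4)), rep(0, 32))
  expect_error(unflattenPVF(x, 3, 3), "does not match")
})

test_that("svd bookkeeping: rank-1, rank-2, reconstruction, Parseval", {
  H <- 8; W <- 8
  f1 <- matrix(complex(real = 1, imaginary = 0.5), H, W)
  set.seed(2)
  tc <- rnorm(50) + 2
  rank1 <- lapply(seq_along(tc), function(t)
    PhaseVelocityField(tc[t] * f1, t = t))
  ms1 <- suppressWarnings(svdModes(rank1, kMax = 3))  # rank 1 < kMax
  expect_equal(varianceFractions(ms1)[1], 1, tolerance = 1e-12)
  # orthogonal planted fields in equal mixture: ~0.5 each at T = 400
  f2 <- matrix(0i, H, W); f2[, 1:4] <- 1i; f2[, 5:8] <- -1i
  f1o <- matrix(1 + 0i, H, W)
  set.seed(5)
  a <- as.numeric(scale(rnorm(200))) + 0.3   # equal-energy weight draws
  b <- as.numeric(scale(rnorm(200))) + 0.3
  mix <- lapply(1:400, function(t)
    PhaseVelocityField(if (t %% 2) a[(t + 1) / 2] * f1o else b[t / 2] * f2,
                       t = t))
  ms2 <- suppressWarnings(svdModes(mix, kMax = 4))
  expect_equal(varianceFractions(ms2)[1], 0.5, tolerance = 0.02)
  expect_equal(varianceFractions(ms2)[2], 0.5, tolerance = 0.02)
  expect_equal(sum(varianceFractions(ms2)), 1, tolerance = 1e-9)
  # modes orthonormal in the flattened embedding
  V <- vapply(1:4, function(j) flattenPVF(modeFields(ms2)[, , j]),
              numeric(2 * H * W))
  expect_lt(max(abs(crossprod(V) - diag(4))), 1e-8)
  # full-mode reconstruction reproduces every input vector
  wmat <- t(vapply(mix, flattenPVF, numeric(2 * H * W)))
  msF <- suppressWarnings(svdModes(mix, kMax = length(mix)))
  VF <- vapply(seq_along(singularValues(msF)), function(j)
    flattenPVF(modeFields(msF)[, , j]), numeric(2 * H * W))
  expect_lt(max(abs(projections(msF) %*% t(VF) - wmat)), 1e-8)
  # energy bookkeeping (Parseval)
  expect_equal(sum(projections(msF)^2), sum(wmat^2), tolerance = 1e-8)
  # per-frame projection shares sum to 1
  expect_equal(rowSums(projectionVariance(msF)), rep(1, 400))
})

test_that("svd matches a brute-force covariance eigendecomposition", {
  H <- 6; W <- 6
  set.seed(8)
  fields <- lapply(1:20, function(t)
    PhaseVelocityField(matrix(complex(real = rnorm(H * W),
                                      imaginary = rnorm(H * W)), H, W), t = t))
  wmat <- t(vapply(fields, flattenPVF, numeric(2 * H * W)))
  ev <- eigen(crossprod(wmat), symmetric = TRUE)
  ms <- svdModes(fields, kMax = 10)
  expect_equal(singularValues(ms)^2, ev$values[1:10], tolerance = 1e-8)
  for (j in 1:5) {
    m <- flattenPVF(modeFields(ms)[, , j])
    expect_equal(abs(sum(m * ev$vectors[, j])), 1, tolerance = 1e-8)
  }
})

test_that("mode alignment recovers permutations and planted dictionaries", {
  H <- 6; W <- 6
  set.seed(13)
  base <- lapply(1:30, function(t)
    PhaseVelocityField(matrix(complex(real = rnorm(H * W),
                                      imaginary = rnorm(H * W)), H, W), t = t))
  ms <- svdModes(base, kMax = 5)
  # aligned to itself: identity permutation, correlations 1
  self <- alignModes(ms, ms, 5)
  expect_equal(self$permutation, 1:5)
  expect_equal(abs(self$correlations), rep(1, 5), tolerance = 1e-10)
  # swap modes 1 and 2 in the candidate: permutation (2, 1, 3, ...)
  swapped <- ms
  swapped@modes[, , 1] <- modeFields(ms)[, , 2]
  swapped@modes[, , 2] <- modeFields(ms)[, , 1]
  sw <- alignModes(swapped, ms, 5)
  expect_equal(sw$permutation[1:2], c(2L, 1L))
  expect_equal(sw$permutation[3:5], 3:5)
  expect_error(alignModes(ms, ms, 50), "exceeds")
})

test_that("direction split reflects the sign mixture of the time course", {
  H <- 6; W <- 6
  f <- matrix(1 + 0i, H, W)
  # constant-sign time course: (1, 0)
  pos <- lapply(1:40, function(t) PhaseVelocityField((1 + 0.1 * t %% 3) * f,
                                                     t = t))
  expect_equal(as.vector(directionSplit(svdModes(pos, 1), 1)), c(1, 0))
  # symmetric alternation: (0.5, 0.5)
  alt <- lapply(1:40, function(t)
    PhaseVelocityField((if (t %% 2) 1 else -1) * f, t = t))
  expect_equal(as.vector(directionSplit(svdModes(alt, 1), 1)), c(0.5, 0.5))
  # planted 70/30 split in squared-projection weight
  set.seed(21)
  signs <- rep(c(1, -1), times = c(280, 120))
  wts <- sample(signs)
  mix <- lapply(seq_along(wts), function(t)
    PhaseVelocityField(wts[t] * f, t = t))
  ds <- directionSplit(svdModes(mix, 1), 1)
  expect_equal(unname(ds["dominant"]), 0.7, tolerance = 0.05)
})
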