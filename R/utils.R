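# Internal numeric helpers shared across the pipeline.

# wrap angles to (-pi, pi]
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# circular difference arg(e^{i(a - b)}), wrap-safe
circDiff <- function(a, b) Arg(exp(1i * (a - b)))

# analytic signal of each column of a real T x P matrix (FFT method).
analyticSignal <- function(X) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  F <- mvfft(X)
  h <- numeric(Tn)
  if (Tn %% 2 == 0) {
    h[1] <- 1; h[Tn / 2 + 1] <- 1
    if (Tn > 2) h[2:(Tn / 2)] <- 2
  } else {
    h[1] <- 1
    if (Tn > 1) h[2:((Tn + 1) / 2)] <- 2
  }
  mvfft(F * h, inverse = TRUE) / Tn
}

# Keys cubic convolution kernel, a = -0.5 (the classic bicubic weight over
# the nearest 4x4 neighborhood)
cubicKernel <- function(s) {
  s <- abs(s)
  a <- -0.5
  w <- numeric(length(s))
  i1 <- s <= 1
  i2 <- s > 1 & s < 2
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

# 1-d cubic resampling matrix mapping n input samples to nOut output
# samples at the given scale; replicate boundary handling.
cubicWeights <- function(n, scale) {
  nOut <- max(1L, round(n * scale))
  W <- matrix(0, nOut, n)
  for (i in seq_len(nOut)) {
    x <- (i - 0.5) / scale + 0.5      # continuous input coordinate
    base <- floor(x)
    taps <- (base - 1):(base + 2)
    wts <- cubicKernel(x - taps)
    taps <- pmin(pmax(taps, 1L), n)   # replicate edges
    for (j in seq_along(taps)) W[i, taps[j]] <- W[i, taps[j]] + wts[j]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

# separable bicubic resize of a single frame
resizeFrame <- function(mat, scale, Wr = NULL, Wc = NULL) {
  if (is.null(Wr)) Wr <- cubicWeights(nrow(mat), scale)
  if (is.null(Wc)) Wc <- cubicWeights(ncol(mat), scale)
  Wr %*% mat %*% t(Wc)
}

# shift a matrix by one pixel with replicate padding; dr/dc in {-1,0,1}
shiftPad <- function(M, dr = 0L, dc = 0L) {
  H <- nrow(M); W <- ncol(M)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  M[ri, ci, drop = FALSE]
}

# MATLAB-style gradient: central differences interior, one-sided at edges.
# Returns list(dx, dy): dx along columns (x), dy along rows (y).
gradientXY <- function(M) {
  H <- nrow(M); W <- ncol(M)
  dx <- matrix(0, H, W); dy <- matrix(0, H, W)
  if (W >= 2) {
    dx[, 2:(W - 1)] <- (M[, 3:W, drop = FALSE] - M[, 1:(W - 2), drop = FALSE]) / 2
    dx[, 1] <- M[, 2] - M[, 1]
    dx[, W] <- M[, W] - M[, W - 1]
  }
  if (H >= 2) {
    dy[2:(H - 1), ] <- (M[3:H, , drop = FALSE] - M[1:(H - 2), , drop = FALSE]) / 2
    dy[1, ] <- M[2, ] - M[1, ]
    dy[H, ] <- M[H, ] - M[H - 1, ]
  }
  list(dx = dx, dy = dy)
}

# movie array helpers: frames are the first margin
movieToMatrix <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1])      # T x (H*W), column-major pixel order
}

matrixToMovie <- function(M, H, W) {
  array(M, dim = c(nrow(M), H, W))
}
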