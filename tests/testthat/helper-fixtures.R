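# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# Analytic phase movie of a plane wave phi = k . x - w t (exact, no
# filtering needed). k = (k_row, k_col) rad/px, freq in Hz.
planePhaseMovie <- function(Tn = 40, H = 24, W = 24, k = c(0, 0.2),
                            freq = 2, fs = 150) {
  wf <- 2 * pi * freq / fs
  ph <- array(0, c(Tn, H, W))
  spat <- outer((seq_len(H) - 1) * k[1], (seq_len(W) - 1) * k[2], "+")
  for (t in seq_len(Tn)) ph[t, , ] <- spat - wf * (t - 1)
  ph <- (ph + pi) %% (2 * pi) - pi
  PhaseMovie(ph, array(1, dim(ph)), fs)
}

# Analytic phase movie of an outward radial wave centred at `center`.
radialPhaseMovie <- function(Tn = 40, H = 32, W = 32, center = c(16, 16),
                             kr = 0.3, freq = 2, fs = 150, sign = 1) {
  wf <- 2 * pi * freq / fs
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  spat <- sign * kr * sqrt((rr - center[1])^2 + (cc - center[2])^2)
  ph <- array(0, c(Tn, H, W))
  for (t in seq_len(Tn)) ph[t, , ] <- spat - wf * (t - 1)
  ph <- (ph + pi) %% (2 * pi) - pi
  PhaseMovie(ph, array(1, dim(ph)), fs)
}

# Composite analytic vector field from a complex polynomial: one factor
# (zeta - z) per index +1 zero, conj(zeta - z) per index -1 zero.
# zeta = col + 1i * row. Returns a PhaseVelocityField.
compositeField <- function(H, W, plusZeros = list(), minusZeros = list()) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  zeta <- cc + 1i * rr
  f <- matrix(1 + 0i, H, W)
  for (z in plusZeros) f <- f * (zeta - (z[2] + 1i * z[1]))
  for (z in minusZeros) f <- f * Conj(zeta - (z[2] + 1i * z[1]))
  PhaseVelocityField(f)
}

# Independent dense solve of the quadratic-penalty Euler-Lagrange system
# on a small grid; the oracle for the fixed-point solver. Unknowns are
# (u, w) stacked pixel-wise (column-major).
denseFlowSolve <- function(phit, gx, gy, wd, alpha) {
  H <- nrow(phit); W <- ncol(phit); N <- H * W
  idx <- function(r, c) (c - 1) * H + r
  A <- matrix(0, 2 * N, 2 * N)
  b <- numeric(2 * N)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    p <- idx(r, c)
    g <- c(gx[r, c], gy[r, c])
    A[p, p] <- A[p, p] + wd[r, c] * g[1]^2
    A[p, N + p] <- A[p, N + p] + wd[r, c] * g[1] * g[2]
    A[N + p, p] <- A[N + p, p] + wd[r, c] * g[1] * g[2]
    A[N + p, N + p] <- A[N + p, N + p] + wd[r, c] * g[2]^2
    b[p] <- b[p] - wd[r, c] * g[1] * phit[r, c]
    b[N + p] <- b[N + p] - wd[r, c] * g[2] * phit[r, c]
    for (nb in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (nb[1] < 1 || nb[1] > H || nb[2] < 1 || nb[2] > W) next
      q <- idx(nb[1], nb[2])
      A[p, p] <- A[p, p] + alpha
      A[p, q] <- A[p, q] - alpha
      A[N + p, N + p] <- A[N + p, N + p] + alpha
      A[N + p, N + q] <- A[N + p, N + q] - alpha
    }
  }
  z <- solve(A, b)
  list(u = matrix(z[1:N], H, W), w = matrix(z[N + 1:N], H, W))
}

# expected type from direct eigen-analysis of a 2x2 Jacobian
eigenType <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  if (is.complex(ev) && any(abs(Im(ev)) > 1e-12)) {
    list(type = if (Re(ev[1]) > 0) "source" else "sink", subtype = "focus")
  } else {
    ev <- Re(ev)
    if (prod(ev) < 0) list(type = "saddle", subtype = "none")
    else list(type = if (sum(ev) > 0) "source" else "sink",
              subtype = "node")
  }
}
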