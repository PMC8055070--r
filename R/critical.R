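# Critical points of phase velocity fields: subpixel detection by
# bilinear nullcline intersection, Jacobian classification (source, sink,
# saddle; node vs focus), Poincare index, and pattern radius.

# bilinear coefficients of a 2x2 cell with corner (r, c):
# f(x, y) = a + b x + c y + d x y on local coords (x, y) in [0, 1]^2,
# x along columns, y along rows
bilinearCoeffs <- function(M, r, c) {
  a <- M[r, c]
  list(a = a,
       b = M[r, c + 1] - a,
       c = M[r + 1, c] - a,
       d = M[r + 1, c + 1] - M[r, c + 1] - M[r + 1, c] + a)
}

# RMS magnitude of the field's spatial gradient, the scale for the
# degeneracy epsilon
fieldGradientScale <- function(v) {
  gu <- gradientXY(Re(v)); gw <- gradientXY(Im(v))
  sqrt(mean(gu$dx^2 + gu$dy^2 + gw$dx^2 + gw$dy^2))
}

#' Locate critical points by bilinear nullcline intersection
#'
#' For every 2 x 2 pixel cell, the bilinear interpolants of both velocity
#' components are tested for a common zero (the intersection of the u- and
#' w-nullclines); intersections are returned at subpixel precision.
#' Multiple intersections per cell are possible (the elimination is
#' quadratic). Since a bilinear function on a cell is a convex combination
#' of its corners, only cells whose corners straddle zero in both
#' components can contain a critical point.
#'
#' @param field a [PhaseVelocityField] (or complex matrix)
#' @return data.frame with subpixel `row`, `col` (possibly empty)
#' @export
findCriticalPoints <- function(field) {
  v <- if (is(field, "PhaseVelocityField")) velocity(field) else field
  U <- Re(v); W <- Im(v)
  H <- nrow(U); Wd <- ncol(U)
  if (H < 2 || Wd < 2) return(data.frame(row = numeric(0), col = numeric(0)))
  # candidate cells: corner signs straddle zero in both components
  cz <- function(M) {
    m00 <- M[-H, -Wd]; m01 <- M[-H, -1]; m10 <- M[-1, -Wd]; m11 <- M[-1, -1]
    lo <- pmin(m00, m01, m10, m11); hi <- pmax(m00, m01, m10, m11)
    lo <= 0 & hi >= 0
  }
  cand <- which(cz(U) & cz(W), arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(row = numeric(0), col = numeric(0)))
  tol <- 1e-9
  rows <- numeric(0); cols <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    cu <- bilinearCoeffs(U, r, c)
    cw <- bilinearCoeffs(W, r, c)
    # eliminate x: (a2 + c2 y)(b1 + d1 y) = (a1 + c1 y)(b2 + d2 y)
    A <- cw$c * cu$d - cu$c * cw$d
    B <- cw$a * cu$d + cu$b * cw$c - cu$a * cw$d - cu$c * cw$b
    C <- cw$a * cu$b - cu$a * cw$b
    ys <- if (abs(A) < tol * max(1, abs(B), abs(C))) {
      if (abs(B) > tol * max(1, abs(C))) -C / B else numeric(0)
    } else {
      disc <- B^2 - 4 * A * C
      if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
    for (y in ys) {
      if (!is.finite(y) || y < -tol || y > 1 + tol) next
      den1 <- cu$b + cu$d * y
      den2 <- cw$b + cw$d * y
      x <- if (abs(den1) >= abs(den2)) {
        if (abs(den1) < 1e-12) next else -(cu$a + cu$c * y) / den1
      } else -(cw$a + cw$c * y) / den2
      if (!is.finite(x) || x < -tol || x > 1 + tol) next
      # verify both interpolants vanish
      uval <- cu$a + cu$b * x + cu$c * y + cu$d * x * y
      wval <- cw$a + cw$b * x + cw$c * y + cw$d * x * y
      scale <- max(abs(c(cu$a, cu$b, cu$c, cu$d, cw$a, cw$b, cw$c, cw$d)), 1e-12)
      if (abs(uval) > 1e-6 * scale || abs(wval) > 1e-6 * scale) next
      rows <- c(rows, r + min(max(y, 0), 1))
      cols <- c(cols, c + min(max(x, 0), 1))
    }
  }
  if (!length(rows)) return(data.frame(row = numeric(0), col = numeric(0)))
  pts <- data.frame(row = rows, col = cols)
  # points on shared cell edges appear twice: deduplicate
  pts[!duplicated(round(pts * 1e6)), , drop = FALSE]
}

#' Classify a critical point from the local Jacobian
#'
#' Estimates the Jacobian `J = [[du/dx, du/dy], [dw/dx, dw/dy]]` from the
#' bilinear cell containing the point and classifies it from trace
#' `tau` and determinant `Delta`: saddle when `Delta < 0` (Poincare index
#' -1); otherwise source when `tau > 0` and sink when `tau < 0` (index
#' +1), with subtype `node` for real eigenvalues and `focus` (spiral) for
#' a complex-conjugate pair. Points with both `|tau|` and `|Delta|` below
#' a scale-free degeneracy epsilon are reported as `degenerate`.
#'
#' @param field a [PhaseVelocityField] (or complex matrix)
#' @param location numeric `(row, col)`, subpixel
#' @return one-row data.frame: `row`, `col`, `tau`, `delta`, `lambda1`,
#'   `lambda2` (complex), `type`, `subtype`, `poincareIndex`, Jacobian
#'   entries `j11`, `j12`, `j21`, `j22`
#' @export
classifyCriticalPoint <- function(field, location) {
  v <- if (is(field, "PhaseVelocityField")) velocity(field) else field
  U <- Re(v); W <- Im(v)
  H <- nrow(U); Wd <- ncol(U)
  r0 <- min(max(floor(location[1]), 1L), H - 1L)
  c0 <- min(max(floor(location[2]), 1L), Wd - 1L)
  y <- location[1] - r0
  x <- location[2] - c0
  cu <- bilinearCoeffs(U, r0, c0)
  cw <- bilinearCoeffs(W, r0, c0)
  J <- matrix(c(cu$b + cu$d * y, cw$b + cw$d * y,    # d/dx column
                cu$c + cu$d * x, cw$c + cw$d * x),   # d/dy column
              2, 2)
  tau <- J[1, 1] + J[2, 2]
  delta <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- as.complex(tau^2 - 4 * delta)
  lambda <- (tau + c(1, -1) * sqrt(disc)) / 2
  eps <- 1e-9 * max(fieldGradientScale(v), .Machine$double.eps)
  if (abs(tau) < eps && abs(delta) < eps^2) {
    type <- "degenerate"; subtype <- "none"; index <- NA_integer_
  } else if (delta < 0) {
    type <- "saddle"; subtype <- "none"; index <- -1L
  } else {
    type <- if (tau > 0) "source" else "sink"
    subtype <- if (Re(disc) < 0) "focus" else "node"
    index <- 1L
  }
  data.frame(row = location[1], col = location[2], tau = tau, delta = delta,
             lambda1 = lambda[1], lambda2 = lambda[2], type = type,
             subtype = subtype, poincareIndex = index,
             j11 = J[1, 1], j12 = J[1, 2], j21 = J[2, 1], j22 = J[2, 2],
             stringsAsFactors = FALSE)
}

#' Ordered square contour of pixels around a center
#'
#' Pixels of the square of half-width `halfWidth` around
#' `(round(row), round(col))`, ordered so a field `v(x) = x - x0` winds
#' once positively (index +1).
#'
#' @param center numeric `(row, col)`
#' @param halfWidth half-width of the square in pixels
#' @return integer matrix with columns `row`, `col`
#' @export
squareLoop <- function(center, halfWidth) {
  r0 <- round(center[1]); c0 <- round(center[2]); h <- halfWidth
  top <- cbind(r0 - h, (c0 - h):(c0 + h))
  right <- cbind((r0 - h + 1):(r0 + h), c0 + h)
  bottom <- cbind(r0 + h, (c0 + h - 1):(c0 - h))
  left <- cbind((r0 + h - 1):(r0 - h + 1), c0 - h)
  loop <- rbind(top, right, bottom, left)
  colnames(loop) <- c("row", "col")
  loop
}

#' Poincare index of a closed contour
#'
#' Winding number of the velocity-vector angle along the loop: the sum of
#' wrap-corrected angle increments divided by `2*pi`, rounded to the
#' nearest integer. +1 around a source or sink, -1 around a saddle, and
#' additive over the enclosed critical points.
#'
#' @param field a [PhaseVelocityField] (or complex matrix)
#' @param loop integer matrix of `(row, col)` pixels forming a closed
#'   contour (e.g. from [squareLoop()]); must avoid zeros of the field
#' @return integer winding number
#' @export
poincareIndex <- function(field, loop) {
  v <- if (is(field, "PhaseVelocityField")) velocity(field) else field
  H <- nrow(v); Wd <- ncol(v)
  if (any(loop[, 1] < 1 | loop[, 1] > H | loop[, 2] < 1 | loop[, 2] > Wd))
    stop("loop leaves the field")
  vals <- v[cbind(loop[, 1], loop[, 2])]
  eps <- 1e-9 * max(mean(Mod(v)), .Machine$double.eps)
  if (any(Mod(vals) < eps))
    stop("loop crosses a near-zero pixel: winding number undefined")
  ang <- Arg(vals)
  inc <- wrapAngle(diff(c(ang, ang[1])))
  as.integer(round(sum(inc) / (2 * pi)))
}

#' Pattern radius of a classified critical point
#'
#' The largest integer `R` such that every pixel ring at Chebyshev
#' distance `1..R` from the singularity has at least `ringAgreement`
#' (default 80%) of its pixels matching the type's directional signature:
#' positive radial velocity component for a source, negative for a sink,
#' and for a saddle the quadrant sign pattern predicted by the Jacobian's
#' quadratic form `rhat' J rhat`. `R` is limited by the distance to the
#' field boundary; 0 means the signature fails already at the first ring.
#'
#' @param field a [PhaseVelocityField] (or complex matrix)
#' @param point one-row data.frame from [classifyCriticalPoint()]
#' @param ringAgreement required fraction of signature-consistent pixels
#' @return integer radius in pixels
#' @export
patternRadius <- function(field, point, ringAgreement = 0.8) {
  v <- if (is(field, "PhaseVelocityField")) velocity(field) else field
  H <- nrow(v); Wd <- ncol(v)
  r0 <- round(point$row); c0 <- round(point$col)
  J <- matrix(c(point$j11, point$j21, point$j12, point$j22), 2, 2)
  scale <- max(fieldGradientScale(v), .Machine$double.eps)
  R <- 0L
  repeat {
    Rtry <- R + 1L
    if (r0 - Rtry < 1 || r0 + Rtry > H || c0 - Rtry < 1 || c0 + Rtry > Wd)
      break
    ring <- squareLoop(c(r0, c0), Rtry)
    dx <- ring[, 2] - point$col      # x = col
    dy <- ring[, 1] - point$row      # y = row
    nrm <- sqrt(dx^2 + dy^2)
    dxn <- dx / nrm; dyn <- dy / nrm
    vals <- v[cbind(ring[, 1], ring[, 2])]
    vr <- Re(vals) * dxn + Im(vals) * dyn
    ok <- switch(point$type,
      source = vr > 0,
      sink = vr < 0,
      saddle = {
        q <- J[1, 1] * dxn^2 + (J[1, 2] + J[2, 1]) * dxn * dyn +
          J[2, 2] * dyn^2
        keep <- abs(q) > 1e-9 * scale
        if (!any(keep)) break
        (sign(vr) == sign(q))[keep]
      },
      stop("cannot measure a radius for type '", point$type, "'"))
    if (mean(ok) < ringAgreement) break
    R <- Rtry
  }
  R
}

#' Detect and classify all critical points of one field
#'
#' Convenience wrapper: [findCriticalPoints()], then
#' [classifyCriticalPoint()] and [patternRadius()] for each, dropping
#' degenerate points.
#'
#' @param field a [PhaseVelocityField]
#' @param ringAgreement passed to [patternRadius()]
#' @return data.frame of classified points with `t` and `radius` columns
#' @export
criticalPoints <- function(field, ringAgreement = 0.8) {
  locs <- findCriticalPoints(field)
  t0 <- if (is(field, "PhaseVelocityField")) frameIndex(field) else NA_integer_
  if (!nrow(locs))
    return(data.frame(t = integer(0), row = numeric(0), col = numeric(0),
                      tau = numeric(0), delta = numeric(0),
                      type = character(0), subtype = character(0),
                      poincareIndex = integer(0), radius = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(locs)), function(i)
    classifyCriticalPoint(field, c(locs$row[i], locs$col[i]))))
  out <- out[out$type != "degenerate", , drop = FALSE]
  if (!nrow(out)) {
    out$radius <- integer(0)
  } else {
    out$radius <- vapply(seq_len(nrow(out)), function(i)
      patternRadius(field, out[i, , drop = FALSE], ringAgreement), integer(1))
  }
  cbind(t = t0, out)
}
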