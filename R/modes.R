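# Singular value decomposition of PVF sequences into principal spatial
# modes, mode alignment across datasets, and direction-proportion
# bookkeeping.

#' Flatten a velocity field into the real embedding
#'
#' Row-major flatten of the real part (length `H*W`) followed by the
#' imaginary part (length `H*W`), total `2*H*W`. A 44 x 52 field flattens
#' to length 4576. The inverse is [unflattenPVF()].
#'
#' @param field a [PhaseVelocityField] or complex matrix
#' @return numeric vector of length `2*H*W`
#' @export
flattenPVF <- function(field) {
  v <- if (is(field, "PhaseVelocityField")) velocity(field) else field
  c(as.vector(t(Re(v))), as.vector(t(Im(v))))
}

#' @rdname flattenPVF
#' @param x flattened vector of length `2*H*W`
#' @param H,W field dimensions
#' @export
unflattenPVF <- function(x, H, W) {
  if (length(x) != 2 * H * W)
    stop("flattened length ", length(x), " does not match ", H, " x ", W)
  re <- matrix(x[seq_len(H * W)], H, W, byrow = TRUE)
  im <- matrix(x[H * W + seq_len(H * W)], H, W, byrow = TRUE)
  re + 1i * im
}

#' Principal spatial modes of a PVF sequence
#'
#' Stacks the flattened fields into the `L x 2HW` matrix `w`, takes the
#' thin SVD `w = T S R*`, and returns the top `kMax` spatial modes
#' (columns of `R` reshaped back to fields), singular values, variance
#' fractions `sigma_k^2 / sum(sigma^2)` (denominator over all singular
#' values), and the projection weights `M = w R`. Each mode's sign is
#' fixed so its largest-magnitude entry is positive (projections flipped
#' accordingly), making output deterministic across runs.
#'
#' @param fields list of [PhaseVelocityField] (consistent shape); frames
#'   failing artifact masking should already be excluded
#' @param kMax number of modes to keep
#' @return an [SVDModeSet]
#' @export
svdModes <- function(fields, kMax = 20L) {
  if (length(fields) < 2L) stop("need at least 2 fields")
  d <- dim(velocity(fields[[1]]))
  H <- d[1]; W <- d[2]
  wmat <- t(vapply(fields, flattenPVF, numeric(2 * H * W)))
  sv <- svd(wmat)
  rank <- sum(sv$d > sv$d[1] * max(dim(wmat)) * .Machine$double.eps)
  k <- min(kMax, length(sv$d))
  if (kMax > rank)
    warning("kMax = ", kMax, " exceeds numerical rank ", rank,
            "; trailing modes are noise-level")
  Vk <- sv$v[, seq_len(k), drop = FALSE]
  M <- wmat %*% Vk
  for (j in seq_len(k)) {
    i <- which.max(abs(Vk[, j]))
    if (Vk[i, j] < 0) {
      Vk[, j] <- -Vk[, j]
      M[, j] <- -M[, j]
    }
  }
  modes <- array(0i, dim = c(H, W, k))
  for (j in seq_len(k)) modes[, , j] <- unflattenPVF(Vk[, j], H, W)
  tIdx <- vapply(fields, frameIndex, integer(1))
  new("SVDModeSet", modes = modes, sigma = sv$d[seq_len(k)],
      varianceFractions = sv$d[seq_len(k)]^2 / sum(sv$d^2),
      projections = M, frameIndex = tIdx)
}

#' Per-frame projection variance shares
#'
#' For frame `n`, the share of mode `m` is `M[n,m]^2 / sum_i M[n,i]^2`.
#'
#' @param modeset an [SVDModeSet]
#' @return frames x modes matrix of shares (rows sum to 1)
#' @export
projectionVariance <- function(modeset) {
  M2 <- projections(modeset)^2
  M2 / rowSums(M2)
}

#' Align one mode set to a reference
#'
#' Greedy one-to-one matching of candidate modes to reference modes
#' maximising the absolute Pearson correlation of the flattened mode
#' vectors, used to compare principal modes across animals or trials.
#'
#' @param candidate,reference [SVDModeSet] objects of the same field shape
#' @param k number of top modes to align
#' @return list with `permutation` (candidate index matched to each
#'   reference rank), `correlations` (signed, per reference rank) and
#'   `absCorrelations`
#' @export
alignModes <- function(candidate, reference, k) {
  kc <- dim(modeFields(candidate))[3]
  kr <- dim(modeFields(reference))[3]
  if (k > kc || k > kr) stop("k = ", k, " exceeds available modes")
  fc <- vapply(seq_len(k), function(j) flattenPVF(modeFields(candidate)[, , j]),
               numeric(2 * prod(dim(modeFields(candidate))[1:2])))
  fr <- vapply(seq_len(k), function(j) flattenPVF(modeFields(reference)[, , j]),
               numeric(2 * prod(dim(modeFields(reference))[1:2])))
  cc <- cor(fr, fc)          # k_ref x k_cand
  perm <- integer(k)
  corrs <- numeric(k)
  absc <- abs(cc)
  for (step in seq_len(k)) {
    i <- which(absc == max(absc), arr.ind = TRUE)[1, ]
    perm[i[1]] <- i[2]
    corrs[i[1]] <- cc[i[1], i[2]]
    absc[i[1], ] <- -Inf
    absc[, i[2]] <- -Inf
  }
  list(permutation = perm, correlations = corrs,
       absCorrelations = abs(corrs))
}

#' Dominant/opposite direction proportions of a mode
#'
#' Each spatial mode represents a pattern in a dominant direction and the
#' same pattern reversed for all pixels (opposite sign of the projection
#' weight). The proportions are the squared-projection-weighted fractions
#' of frames with positive vs negative weight, labeled so
#' `dominant >= opposite`.
#'
#' @param modeset an [SVDModeSet]
#' @param modeIndex which mode
#' @return named vector `c(dominant, opposite)` plus attribute
#'   `dominantSign`
#' @export
directionSplit <- function(modeset, modeIndex) {
  m <- projections(modeset)[, modeIndex]
  w <- m^2
  if (sum(w) == 0) stop("mode ", modeIndex, " has zero projection energy")
  pPos <- sum(w[m > 0]) / sum(w)
  dominantSign <- if (pPos >= 0.5) 1 else -1
  out <- c(dominant = max(pPos, 1 - pPos), opposite = min(pPos, 1 - pPos))
  attr(out, "dominantSign") <- dominantSign
  out
}
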