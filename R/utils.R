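## Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded pipeline stages never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has.old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has.old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has.old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing kept below 2^31 so every stage and subject
#' draws from its own stream derived from one master seed.
#'
#' @param seed master integer seed.
#' @param ... further integer offsets (stage index, subject index, ...).
#' @return a positive integer seed.
#' @keywords internal
deriveSeed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed) %% m
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) * 7919 + 1) %% m
  }
  as.integer(s)
}

## z-score a vector; constant input returns all zeros rather than NaN.
zscoreVec <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm full width at half maximum (any length unit).
#' @return standard deviation in the same unit.
#' @keywords internal
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## 1-D truncated, row-renormalised Gaussian convolution matrix.
## sigma in voxel units; truncation radius 3 sd. sigma 0 -> identity.
gaussKernelMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-d^2 / (2 * sigma^2))
  w[abs(d) > ceiling(3 * sigma)] <- 0
  sweep(w, 1, rowSums(w), "/")
}

## Multiply axis `axis` of a 3- or 4-D array by matrix K (separable smoothing).
axisMatMult <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  pd <- dim(a)
  a <- K %*% matrix(a, nrow = pd[1])
  dim(a) <- pd
  aperm(a, order(perm))
}

## Separable Gaussian smoothing of the spatial axes of a 3- or 4-D array.
## sigmaVox: per-axis sd in voxel units (length 3).
smoothSeparable <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0) {
      arr <- axisMatMult(arr, gaussKernelMatrix(d[ax], sigmaVox[ax]), ax)
    }
  }
  arr
}

#' Spectral radius of a square matrix
#' @param M square numeric matrix.
#' @return largest eigenvalue modulus.
#' @keywords internal
spectralRadius <- function(M) {
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Companion matrix of a VAR(p) coefficient array
#'
#' @param A K x K x p array; `A[i, j, l]` is the effect of series j at lag l
#'   on series i.
#' @return the (K p) x (K p) companion matrix whose spectral radius decides
#'   stationarity.
#' @keywords internal
companionMatrix <- function(A) {
  K <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, K * p, K * p)
  for (l in seq_len(p)) C[1:K, ((l - 1) * K + 1):(l * K)] <- A[, , l]
  if (p > 1) C[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
  C
}

## Sample skewness (biased, fine for a sign convention).
sampleSkewness <- function(v) {
  v <- v - mean(v)
  s2 <- mean(v^2)
  if (s2 == 0) return(0)
  mean(v^3) / s2^1.5
}

## Sample excess kurtosis.
sampleKurtosis <- function(v) {
  v <- v - mean(v)
  s2 <- mean(v^2)
  if (s2 == 0) return(0)
  mean(v^4) / s2^2 - 3
}
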