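## Single-subject spatial ICA: PCA reduction of the time dimension followed
## by fixed-point negentropy maximization at each of a range of model orders.

#' Enumerate ICA model orders
#'
#' Arithmetic sequence of component counts. The full-scale default 20 to 130
#' in steps of 10 yields 12 model orders; desk-scale analyses typically use
#' 10 to 40.
#'
#' @param lower first order (default 20).
#' @param upper inclusive upper bound (default 130).
#' @param step increment (default 10).
#' @return integer vector of model orders.
#' @examples
#' enumerateModelOrders()          # 12 orders
#' enumerateModelOrders(10, 40)    # desk scale
#' @export
enumerateModelOrders <- function(lower = 20L, upper = 130L, step = 10L) {
  if (lower > upper) stop("lower must be <= upper")
  if (step <= 0) stop("step must be positive")
  as.integer(seq(lower, upper, by = step))
}

#' PCA reduction of a time-by-voxel data matrix
#'
#' Reduces a T x M matrix (time points x voxels) to its top-N whitened
#' principal-component projections: an N x M matrix whose rows have identity
#' covariance over voxels. The discarded variance equals the sum of the
#' discarded eigenvalues of the T x T voxel-averaged covariance.
#'
#' @param X T x M numeric matrix, voxels as columns; each voxel's time
#'   series is mean-centred internally.
#' @param N number of components to keep; must satisfy N < T.
#' @return list with `Y` (N x M whitened matrix), `basis` (T x N
#'   eigenvector matrix), `eigenvalues` (all T), `voxelMeans`,
#'   `explainedVariance`.
#' @export
reducePCA <- function(X, N) {
  Tn <- nrow(X); M <- ncol(X)
  if (N >= Tn)
    stop(sprintf("requested N = %d components but only T = %d time points; need N < T",
                 N, Tn))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- tcrossprod(Xc) / M
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  E <- eg$vectors[, seq_len(N), drop = FALSE]
  Y <- diag(1 / sqrt(vals[seq_len(N)]), N) %*% crossprod(E, Xc)
  list(Y = Y, basis = E, eigenvalues = vals, voxelMeans = mu,
       explainedVariance = sum(vals[seq_len(N)]) / sum(vals))
}

## Symmetric fixed-point ICA with the log-cosh contrast on whitened rows.
## Returns the orthonormal unmixing matrix, per-component convergence flags,
## and the iteration count. When not a single component stabilises (high
## model orders can leave a near-Gaussian noise subspace with no fixed
## point), the iteration is restarted from fresh seeded initialisations
## before giving up.
fastICACore <- function(Y, seed, maxIter = 500L, tol = 1e-4, restarts = 2L) {
  N <- nrow(Y); M <- ncol(Y)
  onePass <- function(s) {
    W <- withSeed(s, qr.Q(qr(matrix(stats::rnorm(N * N), N, N))))
    iter <- 0L
    best <- list(W = W, converged = rep(FALSE, N), score = -Inf)
    allPrev <- FALSE
    repeat {
      iter <- iter + 1L
      S <- W %*% Y
      G <- tanh(S)
      W1 <- tcrossprod(G, Y) / M - diag(rowMeans(1 - G^2), N) %*% W
      sv <- svd(W1)
      W1 <- tcrossprod(sv$u, sv$v)
      delta <- abs(abs(rowSums(W1 * W)) - 1)
      convPer <- delta < tol
      ## keep the most stable iterate seen: a rotating near-Gaussian noise
      ## subspace can keep perturbing the final iteration without the
      ## informative components being any less converged
      score <- sum(convPer) - mean(pmin(delta, 1))
      if (score > best$score)
        best <- list(W = W1, converged = convPer, score = score)
      W <- W1
      ## stop only after two consecutive fully-converged iterations, so a
      ## transient dip while passing a saddle does not end the search
      if ((all(convPer) && allPrev) || iter >= maxIter) break
      allPrev <- all(convPer)
    }
    list(W = best$W, converged = best$converged, iterations = iter)
  }
  fit <- onePass(seed)
  tries <- 0L
  while (!any(fit$converged) && tries < restarts) {
    tries <- tries + 1L
    fit <- onePass(deriveSeed(seed, 29L, tries))
  }
  if (!any(fit$converged))
    stop(sprintf("spatial ICA failed to converge for any component (cap %d iterations, tolerance %g)",
                 maxIter, tol))
  fit
}

#' Extract spatial independent components from a PCA reduction
#'
#' Fixed-point maximization of non-Gaussianity (log-cosh contrast, symmetric
#' orthogonalization) on the whitened rows, so the unmixing matrix is
#' orthonormal in whitened space. Each spatial map is z-scored over voxels,
#' and its sign is fixed so that the map skewness is nonnegative (map and
#' time course flip together). Components are ordered by decreasing map
#' kurtosis. Deterministic given the seed.
#'
#' @param reduced output of [reducePCA()].
#' @param seed integer seed for the unmixing initialization.
#' @param subjectId subject identifier stored in the result.
#' @param maxIter fixed-point iteration cap (default 500).
#' @param tol convergence tolerance on the unmixing rows (default 1e-4).
#' @return an [ICSet-class] with `modelOrder` = nrow(reduced$Y) components.
#' @export
extractSpatialICs <- function(reduced, seed, subjectId = "subject",
                              maxIter = 500L, tol = 1e-4) {
  Y <- reduced$Y
  N <- nrow(Y)
  fit <- fastICACore(Y, seed, maxIter, tol)
  S <- fit$W %*% Y
  ## time course of each map: back-projected mixing column
  Tc <- reduced$basis %*% diag(sqrt(reduced$eigenvalues[seq_len(N)]), N) %*%
    t(fit$W)
  for (i in seq_len(N)) {
    if (sampleSkewness(S[i, ]) < 0) {
      S[i, ] <- -S[i, ]
      Tc[, i] <- -Tc[, i]
    }
    S[i, ] <- zscoreVec(S[i, ])
  }
  ord <- order(apply(S, 1, sampleKurtosis), decreasing = TRUE)
  new("ICSet", subjectId = subjectId, modelOrder = as.integer(N),
      maps = S[ord, , drop = FALSE], timecourses = Tc[, ord, drop = FALSE],
      converged = fit$converged[ord],
      pcaExplainedVariance = reduced$explainedVariance)
}

#' Run spatial ICA for one subject at several model orders
#'
#' @param series a preprocessed [SubjectSeries-class].
#' @param orders integer vector of model orders (see
#'   [enumerateModelOrders()]).
#' @param seed integer seed; each order draws from a derived stream.
#' @param maxIter,tol passed to [extractSpatialICs()].
#' @return named list of [ICSet-class], one per order.
#' @export
runSubjectICA <- function(series, orders, seed, maxIter = 500L, tol = 1e-4) {
  X <- boldMatrix(series)
  out <- lapply(orders, function(N) {
    red <- reducePCA(X, N)
    extractSpatialICs(red, seed = deriveSeed(seed, 13L, N),
                      subjectId = series@subjectId,
                      maxIter = maxIter, tol = tol)
  })
  names(out) <- as.character(orders)
  out
}
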