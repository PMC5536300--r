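## Voxelwise second-level inference on per-subject representative z-maps:
## OLS group contrast covarying age and sex, Monte-Carlo cluster-extent
## correction, severity correlation, and age-by-diagnosis interaction.

#' Build a second-level design matrix from subject covariates
#'
#' Group contrast covarying age and sex, optionally with an age-by-group
#' interaction. The group column codes patient = 1, control = 0, so positive
#' contrast t means patient > control.
#'
#' @param covariates data.frame with columns `group` ("patient"/"control"),
#'   `age`, `sex`.
#' @param interaction include an age-by-group interaction column?
#' @return list with `X` (design matrix: intercept, group, age, sexM, and
#'   optionally group:age) and `contrast` (unit vector on the group column,
#'   or on the interaction column when `interaction = TRUE`).
#' @export
makeGroupDesign <- function(covariates, interaction = FALSE) {
  grp <- as.numeric(covariates$group == "patient")
  X <- cbind(intercept = 1, group = grp,
             age = as.numeric(covariates$age),
             sexM = as.numeric(covariates$sex == "M"))
  target <- "group"
  if (interaction) {
    X <- cbind(X, `group:age` = grp * as.numeric(covariates$age))
    target <- "group:age"
  }
  contrast <- as.numeric(colnames(X) == target)
  list(X = X, contrast = contrast)
}

#' Voxelwise OLS group inference on subject maps
#'
#' Ordinary least squares per voxel; the contrast t statistic is
#' \eqn{t = c'b / sqrt(c'(X'X)^{-1}c \hat\sigma^2)} with
#' df = n - ncol(X). With design (intercept, group) and no covariates this
#' equals the pooled two-sample t exactly.
#'
#' @param maps n x M matrix, one subject map per row.
#' @param design n x p design matrix (full column rank).
#' @param contrast numeric contrast vector of length p.
#' @return object of class `GroupDiffMap`: list with `tMap` (length M),
#'   `beta` (p x M), `residuals` (n x M), `df`, `design`, `contrast`.
#' @export
fitVoxelwiseGLM <- function(maps, design, contrast) {
  n <- nrow(maps); p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match the number of maps")
  qrX <- qr(design)
  if (qrX$rank < p) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(contrast) != p) stop("contrast length must equal ncol(design)")
  XtXinv <- solve(crossprod(design))
  beta <- XtXinv %*% crossprod(design, maps)
  res <- maps - design %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  cv <- as.numeric(t(contrast) %*% XtXinv %*% contrast)
  est <- as.numeric(t(contrast) %*% beta)
  se <- sqrt(cv * sigma2)
  t <- ifelse(se > 0, est / se, 0)
  structure(list(tMap = t, beta = beta, residuals = res, df = df,
                 design = design, contrast = contrast),
            class = "GroupDiffMap")
}

#' @export
print.GroupDiffMap <- function(x, ...) {
  cat(sprintf("GroupDiffMap: %d voxels, df = %d, |t| range [%.2f, %.2f]\n",
              length(x$tMap), x$df, min(abs(x$tMap)), max(abs(x$tMap))))
  invisible(x)
}

#' Estimate the spatial smoothness of residual maps
#'
#' Fits a Gaussian autocorrelation per axis from the lag-1 spatial
#' correlation of the residuals (rho = exp(-d^2 / (4 sigma^2))) and returns
#' the geometric mean FWHM across axes in mm.
#'
#' @param residuals n x M matrix of residual maps over mask voxels.
#' @param mask 3-D logical array.
#' @param voxelSizeMm numeric(3).
#' @return estimated isotropic FWHM in mm (0 when residuals are spatially
#'   uncorrelated).
#' @export
estimateSmoothnessFwhm <- function(residuals, mask, voxelSizeMm) {
  dims <- dim(mask)
  maskIdx <- which(mask)
  full <- array(NA_real_, dims)
  fw <- numeric(3)
  rhoAxis <- numeric(3)
  for (ax in 1:3) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(residuals))) {
      full[maskIdx] <- residuals[i, ]
      a <- full
      idx1 <- seq_len(dims[ax] - 1)
      take <- function(arr, ix) {
        switch(ax,
               arr[ix, , , drop = FALSE],
               arr[, ix, , drop = FALSE],
               arr[, , ix, drop = FALSE])
      }
      x <- as.vector(take(a, idx1))
      y <- as.vector(take(a, idx1 + 1))
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok] - mean(x[ok]); y <- y[ok] - mean(y[ok])
      num <- num + sum(x * y)
      den <- den + sqrt(sum(x^2) * sum(y^2))
    }
    rho <- if (den > 0) num / den else 0
    rhoAxis[ax] <- rho
    fw[ax] <- if (rho <= 0) 0 else
      2 * sqrt(2 * log(2)) * voxelSizeMm[ax] / (2 * sqrt(-log(rho)))
  }
  if (any(fw == 0)) return(0)
  exp(mean(log(fw)))
}

## 26-connectivity connected components of a 3-D logical array.
## Returns a list of integer vectors of linear (array) indices.
connectedComponents26 <- function(binArr) {
  lin <- which(binArr)
  if (!length(lin)) return(list())
  if (length(lin) == 1) return(list(lin))
  dims <- dim(binArr)
  coords <- arrayInd(lin, dims)
  id <- seq_along(lin)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nbLin <- (nb[ok, 3] - 1) * dims[1] * dims[2] +
      (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    hit <- match(nbLin, lin)
    src <- id[ok][!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src))
      edges[[length(edges) + 1]] <- cbind(src, dst)
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- id
  }
  unname(lapply(split(lin, memb), as.integer))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates smooth Gaussian null maps on the mask (white noise convolved to
#' `smoothnessFwhmMm`, then z-scored over mask voxels), thresholds at the
#' two-sided `voxelP`, records each iteration's maximum cluster extent
#' (26-connectivity, positive and negative excursions separately), and
#' returns the smallest extent k whose exceedance probability
#' P(max extent >= k) is at most `fwer`, at least 1.
#'
#' @param mask 3-D logical array.
#' @param voxelSizeMm numeric(3).
#' @param smoothnessFwhmMm smoothness of the null fields, mm (0 = white).
#' @param voxelP two-sided voxelwise p threshold (default 0.01).
#' @param fwer target familywise error rate (default 0.05).
#' @param nIter Monte-Carlo iterations (>= 1000 for reported thresholds).
#' @param seed integer seed.
#' @return integer extent threshold (voxels).
#' @export
monteCarloExtentThreshold <- function(mask, voxelSizeMm, smoothnessFwhmMm,
                                      voxelP = 0.01, fwer = 0.05,
                                      nIter = 1000L, seed = 1L) {
  dims <- dim(mask)
  sigmaVox <- fwhmToSigma(smoothnessFwhmMm) / voxelSizeMm
  if (any(2 * ceiling(3 * sigmaVox) + 1 > 2 * dims))
    stop(sprintf("smoothness %.1f mm is incompatible with the %s grid (kernel wider than mask)",
                 smoothnessFwhmMm, paste(dims, collapse = "x")))
  zthr <- stats::qnorm(1 - voxelP / 2)
  maskIdx <- which(mask)
  maxExt <- withSeed(seed, {
    vapply(seq_len(nIter), function(it) {
      noise <- array(stats::rnorm(prod(dims)), dims)
      if (smoothnessFwhmMm > 0) noise <- smoothSeparable(noise, sigmaVox)
      z <- rep(NA_real_, prod(dims))
      z[maskIdx] <- zscoreVec(noise[maskIdx])
      z <- array(z, dims)
      ext <- 0L
      for (s in c(1, -1)) {
        supra <- !is.na(z) & (s * z > zthr)
        cc <- connectedComponents26(supra)
        if (length(cc))
          ext <- max(ext, max(lengths(cc)))
      }
      as.integer(ext)
    }, integer(1))
  })
  ## smallest extent k with P(max extent >= k) <= fwer: a surviving cluster
  ## needs extent >= k, so thresholding at the (1 - fwer) quantile itself
  ## would overshoot the nominal rate by the probability mass at that
  ## value. The decision uses the one-sided 95% upper confidence bound of
  ## the exceedance probability, so Monte-Carlo error cannot tip the
  ## threshold into an anticonservative choice.
  k <- 1L
  repeat {
    p <- mean(maxExt >= k)
    ub <- p + 1.645 * sqrt(p * (1 - p) / nIter)
    if (ub <= fwer || k > max(maxExt)) break
    k <- k + 1L
  }
  max(1L, k)
}

#' Cluster a t map at a voxel threshold and extent floor
#'
#' Voxels with two-sided p < `voxelP` (Student t with `df`) are grouped by
#' 26-connectivity, positive and negative t separately; clusters with at
#' least `extentThreshold` voxels survive, sorted by decreasing |peak t|.
#'
#' @param tMap numeric vector of t statistics over mask voxels.
#' @param mask 3-D logical array (sum(mask) = length(tMap)).
#' @param df error degrees of freedom.
#' @param voxelP two-sided voxel threshold (default 0.01).
#' @param extentThreshold minimum cluster size in voxels (default 20).
#' @return list with `table` (data.frame: clusterId, sign, peakX, peakY,
#'   peakZ, peakT, extent) and `voxels` (list of mask-voxel index vectors,
#'   same order as the table rows).
#' @export
thresholdClusters <- function(tMap, mask, df, voxelP = 0.01,
                              extentThreshold = 20L) {
  if (df <= 0) stop("df must be positive")
  dims <- dim(mask)
  maskIdx <- which(mask)
  stopifnot(length(tMap) == length(maskIdx))
  tthr <- stats::qt(1 - voxelP / 2, df)
  full <- rep(NA_real_, prod(dims))
  full[maskIdx] <- tMap
  full <- array(full, dims)
  rows <- list(); vox <- list()
  for (s in c(1, -1)) {
    supra <- !is.na(full) & (s * full > tthr)
    for (cc in connectedComponents26(supra)) {
      if (length(cc) < extentThreshold) next
      vals <- full[cc]
      pk <- cc[which.max(abs(vals))]
      pco <- arrayInd(pk, dims)
      rows[[length(rows) + 1]] <- data.frame(
        sign = if (s > 0) "positive" else "negative",
        peakX = pco[1], peakY = pco[2], peakZ = pco[3],
        peakT = vals[which.max(abs(vals))], extent = length(cc))
      vox[[length(vox) + 1]] <- match(cc, maskIdx)
    }
  }
  if (!length(rows))
    return(list(table = data.frame(clusterId = integer(), sign = character(),
                                   peakX = integer(), peakY = integer(),
                                   peakZ = integer(), peakT = numeric(),
                                   extent = integer()),
                voxels = list()))
  tab <- do.call(rbind, rows)
  ord <- order(-abs(tab$peakT))
  tab <- tab[ord, , drop = FALSE]
  vox <- vox[ord]
  tab <- cbind(clusterId = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  list(table = tab, voxels = vox)
}

#' Pearson correlation of per-subject connectivity with symptom severity
#'
#' @param z per-subject scalar connectivity (e.g. mean representative z over
#'   a cluster's surviving voxels).
#' @param severity standardized severity scores, same length.
#' @return list with `r`, `p` (two-sided t approximation), `n`.
#' @export
severityCorrelation <- function(z, severity) {
  ok <- !is.na(z) & !is.na(severity)
  z <- z[ok]; severity <- severity[ok]
  if (length(z) < 3) stop("need at least 3 paired observations")
  if (stats::sd(z) == 0 || stats::sd(severity) == 0)
    stop("zero variance in the inputs")
  ct <- stats::cor.test(z, severity, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(z))
}
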