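test_that("voxelwise GLM group contrast equals the pooled two-sample t", {
  set.seed(31)
  n <- 40; M <- 50
  maps <- rbind(matrix(rnorm(20 * M, mean = 1), 20),
                matrix(rnorm(20 * M, mean = 0), 20))
  grp <- rep(c(1, 0), each = 20)
  X <- cbind(intercept = 1, group = grp)
  fit <- fitVoxelwiseGLM(maps, X, c(0, 1))
  ## textbook pooled-t oracle
  tOracle <- vapply(seq_len(M), function(v) {
    a <- maps[grp == 1, v]; b <- maps[grp == 0, v]
    sp <- sqrt(((19) * var(a) + (19) * var(b)) / 38)
    (mean(a) - mean(b)) / (sp * sqrt(1 / 20 + 1 / 20))
  }, numeric(1))
  expect_equal(fit$tMap, tOracle, tolerance = 1e-10)
  expect_equal(fit$df, 38)
  ## duplicated group column is rejected naming the collinearity
  X2 <- cbind(X, group2 = grp)
  expect_error(fitVoxelwiseGLM(maps, X2, c(0, 1, 0)), "collinear")
})

test_that("null contrasts stay bounded and covariates barely move planted t", {
  set.seed(32)
  for (s in 1:5) {
    maps <- matrix(rnorm(30 * 200), 30)
    X <- cbind(1, rep(c(1, 0), each = 15))
    fit <- fitVoxelwiseGLM(maps, X, c(0, 1))
    expect_lt(max(abs(fit$tMap)), 6)
  }
  ## covariate invariance: age uncorrelated with group
  set.seed(33)
  n <- 40
  grp <- rep(c(1, 0), each = 20)
  eff <- matrix(rnorm(n * 100), n)
  eff[, 1:20] <- eff[, 1:20] + grp * 1.5
  age <- rnorm(n)
  f0 <- fitVoxelwiseGLM(eff, cbind(1, grp), c(0, 1))
  f1 <- fitVoxelwiseGLM(eff, cbind(1, grp, age), c(0, 1, 0))
  rel <- abs(f1$tMap[1:20] - f0$tMap[1:20]) / abs(f0$tMap[1:20])
  expect_lt(median(rel), 0.05)
})

test_that("monte-carlo extent threshold behaves across smoothness levels", {
  mask <- array(TRUE, c(10L, 10L, 8L))
  vox <- c(3.75, 3.75, 3.5)
  ## independent voxels: small extents, reproducible given the seed
  e0 <- monteCarloExtentThreshold(mask, vox, 0, nIter = 1000L, seed = 5L)
  expect_lte(e0, 3)
  expect_identical(e0, monteCarloExtentThreshold(mask, vox, 0,
                                                 nIter = 1000L, seed = 5L))
  ## monotone trend with smoothness (majority over seeds)
  wins <- 0
  for (s in 1:5) {
    es <- vapply(c(0, 6, 12), function(fw)
      monteCarloExtentThreshold(mask, vox, fw, nIter = 200L, seed = 50 + s),
      integer(1))
    if (es[1] <= es[2] && es[2] <= es[3]) wins <- wins + 1
  }
  expect_gte(wins, 3)
  ## degenerate FWER keeps the minimum extent of 1
  expect_equal(monteCarloExtentThreshold(mask, vox, 0, fwer = 1,
                                         nIter = 100L, seed = 1L), 1L)
  expect_error(monteCarloExtentThreshold(mask, vox, 500, nIter = 100L,
                                         seed = 1L), "incompatible")
})

test_that("cluster thresholding applies extent and connectivity rules", {
  mask <- array(TRUE, c(10L, 10L, 8L))
  tMap <- rep(0, sum(mask))
  expect_equal(nrow(thresholdClusters(tMap, mask, 90)$table), 0)
  ## a contiguous 25-voxel block of t = 5 survives extent 20, not 26
  arr <- array(0, dim(mask))
  arr[3:7, 3:7, 4] <- 5
  tBlock <- arr[mask]
  r20 <- thresholdClusters(tBlock, mask, 90, 0.01, 20L)
  expect_equal(nrow(r20$table), 1)
  expect_equal(r20$table$extent, 25)
  expect_identical(r20$table$sign, "positive")
  expect_equal(nrow(thresholdClusters(tBlock, mask, 90, 0.01, 26L)$table), 0)
  ## negative blocks are clustered separately and sorted by |peak t|
  arr[3:7, 3:7, 7] <- -8
  rBoth <- thresholdClusters(arr[mask], mask, 90, 0.01, 20L)
  expect_equal(nrow(rBoth$table), 2)
  expect_identical(rBoth$table$sign[1], "negative")
})

test_that("smoothness estimation tracks the applied kernel", {
  mask <- array(TRUE, c(14L, 14L, 10L))
  vox <- c(4, 4, 4)
  sig <- icahpm:::fwhmToSigma(8) / vox
  set.seed(35)
  res <- t(vapply(1:15, function(i) {
    a <- icahpm:::smoothSeparable(array(rnorm(prod(dim(mask))), dim(mask)), sig)
    as.vector(a)[as.vector(mask)]
  }, numeric(sum(mask))))
  fw <- estimateSmoothnessFwhm(res, mask, vox)
  expect_equal(fw, 8, tolerance = 0.2 * 8)
  ## white residuals: no measurable smoothness
  resW <- matrix(rnorm(15 * sum(mask)), 15)
  expect_lt(estimateSmoothnessFwhm(resW, mask, vox), 4)
})

test_that("severity correlation follows the Pearson contract", {
  z <- 1:10
  expect_equal(severityCorrelation(z, 2 * z + 3)$r, 1)
  expect_equal(severityCorrelation(z, -z)$r, -1)
  expect_error(severityCorrelation(rep(1, 5), rnorm(5)), "variance")
  expect_error(severityCorrelation(1:2, 1:2), "3")
})

test_that("planted amplitude effects surface with the published direction pattern", {
  fix <- toyRunFixture()
  maskIdx <- which(fix$mask)
  dice <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))
  signs <- character(0)
  for (i in seq_along(fix$clusters)) {
    src <- fix$assign[i]
    tab <- fix$groupStats[[i]]$clusters$table
    if (!nrow(tab)) next
    sup <- which(fix$truth$canonicalMaps[src, maskIdx] > 0.5)
    for (r in seq_len(nrow(tab))) {
      d <- dice(fix$groupStats[[i]]$clusters$voxels[[r]], sup)
      if (d > 0.3) signs[as.character(src)] <- tab$sign[r]
    }
  }
  ## amplitude-reduced sources 1 and 3: negative surviving clusters over
  ## the planted support
  expect_identical(signs[["1"]], "negative")
  expect_identical(signs[["3"]], "negative")
  ## amplitude-increased source 2: a positive suprathreshold excursion over
  ## the planted support and a positive pooled effect. (Survival of the
  ## full extent-corrected cluster has only partial power for the
  ## amplitude-raised source at this sample size; see the methods
  ## vignette.)
  i2 <- which(fix$assign == 2)
  gs2 <- fix$groupStats[[i2]]
  sup2 <- which(fix$truth$canonicalMaps[2, maskIdx] > 0.5)
  exc <- thresholdClusters(gs2$fit$tMap, fix$mask, gs2$fit$df, 0.01, 5L)
  dpos <- vapply(seq_len(nrow(exc$table)), function(r)
    if (exc$table$sign[r] == "positive") dice(exc$voxels[[r]], sup2) else 0,
    numeric(1))
  expect_true(any(dpos > 0.3))
  reps2 <- clusterRepresentatives(fix$clusters[[i2]])
  cv2 <- fix$covar[match(rownames(reps2), fix$covar$subject), ]
  zdiff <- mean(rowMeans(reps2[cv2$group == "patient", sup2, drop = FALSE])) -
    mean(rowMeans(reps2[cv2$group == "control", sup2, drop = FALSE]))
  expect_gt(zdiff, 0)
  ## the unmodified source 4 shows no surviving cluster at all
  i4 <- which(fix$assign == 4)
  expect_equal(nrow(fix$groupStats[[i4]]$clusters$table), 0)
})

test_that("severity correlates negatively with connectivity in the patient group", {
  fix <- toyRunFixture()
  i1 <- which(fix$assign == 1)[1]
  reps <- clusterRepresentatives(fix$clusters[[i1]])
  cv <- fix$covar[match(rownames(reps), fix$covar$subject), ]
  sup <- which(fix$truth$canonicalMaps[1, which(fix$mask)] > 0.5)
  zs <- rowMeans(reps[, sup, drop = FALSE])
  pat <- cv$group == "patient" & !is.na(cv$severity)
  r <- severityCorrelation(zs[pat], cv$severity[pat])$r
  expect_lt(r, 0)
})
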