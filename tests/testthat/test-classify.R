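test_that("feature building maps clusters and edges to named columns", {
  reps <- matrix(rnorm(4 * 30), 4,
                 dimnames = list(paste0("s", 1:4), NULL))
  cl <- new("ReproducibleCluster", clusterId = "c1",
            members = data.frame(subject = paste0("s", 1:4), order = 8,
                                 component = 1L),
            alpha = 0.9, tMap = numeric(30), degenerateT = FALSE,
            representatives = reps)
  gtab <- data.frame(subject = rep(paste0("s", 1:4), 2),
                     source = rep(c("c1", "c1"), each = 4),
                     target = rep(c("c2", "c2"), each = 4),
                     mediator = rep(c(NA, "c3"), each = 4),
                     p = 1, gci = abs(rnorm(8)))
  grp <- stats::setNames(rep(c("patient", "control"), 2), paste0("s", 1:4))
  fm <- buildFeatures(list(c1 = cl), list(c1 = 1:5), gtab,
                      paste0("s", 1:4), grp)
  expect_s3_class(fm, "FeatureMatrix")
  expect_identical(fm$featureNames,
                   c("z:c1", "gci:c1->c2", "gci:c1->c2|c3"))
  expect_equal(fm$features[, "z:c1"],
               stats::setNames(rowMeans(reps[, 1:5]), paste0("s", 1:4)))
  ## constant feature dropped with a warning
  gtab2 <- gtab[1:4, ]; gtab2$gci <- 1
  expect_warning(fm2 <- buildFeatures(list(c1 = cl), list(c1 = 1:5), gtab2,
                                      paste0("s", 1:4), grp), "constant")
  expect_identical(fm2$featureNames, "z:c1")
})

test_that("separable classes are perfectly classified, permuted labels are not", {
  d <- sepData()
  rep <- svmCrossval(d$X, d$y, scheme = "loo")
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 1.0)
  repK <- svmCrossval(d$X, d$y, scheme = "kfold", seed = 2L)
  expect_equal(repK$accuracy, 1.0)
  ## permutation null: mean LOO accuracy near chance
  set.seed(52)
  acc <- vapply(1:60, function(i)
    svmCrossval(d$X, sample(as.character(d$y)), scheme = "loo")$accuracy,
    numeric(1))
  ## the LOO permutation null is biased slightly below 0.5 (anti-majority
  ## artifact), so the band is asymmetric around chance
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.62)
  ## identical feature vectors: accuracy equals the majority-class fraction
  Xc <- matrix(1, 30, 2)
  yc <- factor(rep(c("patient", "control"), c(10, 20)),
               levels = c("patient", "control"))
  repC <- svmCrossval(Xc, yc, scheme = "loo")
  expect_equal(repC$accuracy, 20 / 30)
  expect_error(svmCrossval(d$X, factor(rep("patient", 40),
                                       levels = c("patient", "control")),
                           scheme = "loo"), "class")
})

test_that("LOO accuracy is invariant to subject ordering", {
  d <- sepData(n = 24, gap = 2, seed = 53)
  r1 <- svmCrossval(d$X, d$y, scheme = "loo")
  set.seed(54)
  perm <- sample(24)
  r2 <- svmCrossval(d$X[perm, ], d$y[perm], scheme = "loo")
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("MLDA follows its regularization and contribution contracts", {
  ## identity pooled covariance: direction proportional to the mean
  ## difference
  set.seed(55)
  mu <- c(2, -1, 0.5)
  X <- rbind(sweep(matrix(rnorm(300), 100), 2, -mu / 2),
             sweep(matrix(rnorm(300), 100), 2, mu / 2))
  y <- rep(c("patient", "control"), each = 100)
  d <- icahpm:::mldaDirection(scale(X), y)
  wn <- d$w / sqrt(sum(d$w^2))
  mn <- (d$mu1 - d$mu2) / sqrt(sum((d$mu1 - d$mu2)^2))
  expect_gt(abs(sum(wn * mn)), 0.99)
  ## d > n: finite direction, no failure
  set.seed(56)
  Xs <- matrix(rnorm(10 * 25), 10)
  ys <- rep(c("patient", "control"), each = 5)
  ds <- icahpm:::mldaDirection(Xs, ys)
  expect_true(all(is.finite(ds$w)))
  rep <- mldaFitLOO(Xs, factor(ys, levels = c("patient", "control")))
  expect_true(is.finite(rep$accuracy))
  ## well-separated classes: high LOO accuracy across seeds
  accs <- vapply(1:10, function(s) {
    dd <- sepData(n = 30, d = 4, gap = 4, seed = 500 + s)
    mldaFitLOO(dd$X, dd$y)$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.95))
  ## contributions normalized to the largest coefficient
  dd <- sepData(n = 30, d = 3, gap = 3, seed = 57)
  r <- mldaFitLOO(dd$X, dd$y)
  expect_equal(max(r$contributions), 1)
  expect_named(r$contributions, colnames(dd$X))
  ## contribution ranking invariant to positive rescaling of a feature
  X2 <- dd$X; X2[, 2] <- X2[, 2] * 50
  r2 <- mldaFitLOO(X2, dd$y)
  expect_identical(order(r$contributions), order(r2$contributions))
})

test_that("fold-internal standardization differs from a leaking global mutant", {
  ## constructed set: one extreme outlier makes global statistics leak
  set.seed(58)
  X <- rbind(matrix(rnorm(10 * 2), 10),
             matrix(rnorm(9 * 2, mean = 1.2), 9),
             c(60, 60))
  y <- factor(rep(c("patient", "control"), each = 10),
              levels = c("patient", "control"))
  honestTr <- icahpm:::foldTransform(X[-20, , drop = FALSE],
                                     X[20, , drop = FALSE])
  globalTr <- scale(X)
  ## the held-out outlier is standardized very differently once its own
  ## value no longer enters the statistics (z explodes without leakage)
  expect_gt(abs(honestTr$test[1, 1]), 2 * abs(globalTr[20, 1]))
  expect_gt(abs(honestTr$test[1, 1] - globalTr[20, 1]), 1)
})

test_that("repeated LOO reports across-trial dispersion honestly", {
  d <- sepData(n = 20, gap = 8, seed = 59)
  fm <- structure(list(subjects = paste0("s", 1:20),
                       labels = d$y, features = d$X,
                       featureNames = colnames(d$X)),
                  class = "FeatureMatrix")
  ## complete data, deterministic solver: all trials identical
  r <- repeatedLOO(fm, colnames(d$X), nTrials = 5L, seed = 1L)
  expect_equal(r$accuracy, 1.0)
  expect_equal(r$accuracySd, 0)
  ## missing entries + jitter: trials vary
  fm2 <- fm
  fm2$features[c(3, 9), 1] <- NA
  r2 <- repeatedLOO(fm2, colnames(d$X), nTrials = 8L, seed = 1L,
                    impJitterSd = 0.5)
  expect_true(is.finite(r2$accuracySd))
  expect_error(repeatedLOO(fm, character(), nTrials = 2L), "nonempty")
  expect_error(repeatedLOO(fm, "zzz", nTrials = 2L), "unknown")
})

test_that("classification accuracy grows with planted effect size", {
  wins <- 0
  for (s in 1:6) {
    accs <- vapply(c(0.5, 1.5, 3), function(gap) {
      d <- sepData(n = 24, d = 3, gap = gap, seed = 900 + s)
      svmCrossval(d$X, d$y, scheme = "loo")$accuracy
    }, numeric(1))
    if (accs[1] <= accs[2] + 1e-9 && accs[2] <= accs[3] + 1e-9)
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})
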