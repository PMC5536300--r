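test_that("cohort spec rejects non-stationary VAR naming the spectral radius", {
  A <- array(0, c(4, 4, 1))
  diag(A[, , 1]) <- 1.05
  expect_error(
    cohortSpec(varCoefficients = list(patient = A, control = A)),
    "spectral radius")
  expect_error(cohortSpec(nSources = 200L, nVolumes = 150L,
                          varCoefficients = list(
                            patient = array(0, c(200, 200, 1)),
                            control = array(0, c(200, 200, 1))),
                          amplitudeScale = matrix(1, 200, 2,
                            dimnames = list(NULL, c("patient", "control"))),
                          gridDims = c(20L, 20L, 20L)),
               "nSources")
})

test_that("identical spec and seed give bit-identical cohorts", {
  spec <- cohortSpec(gridDims = c(8L, 8L, 6L), nPerGroup = c(2L, 2L),
                     nVolumes = 40L, seed = 9L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(boldData(a$subjects[[3]]), boldData(b$subjects[[3]]))
  expect_identical(a$truth$severityScores, b$truth$severityScores)
  spec2 <- cohortSpec(gridDims = c(8L, 8L, 6L), nPerGroup = c(2L, 2L),
                      nVolumes = 40L, seed = 10L)
  c <- generateCohort(spec2)
  expect_false(identical(boldData(a$subjects[[1]]), boldData(c$subjects[[1]])))
  ## canonical maps do not depend on the noise realisation
  expect_identical(a$truth$canonicalMaps, c$truth$canonicalMaps)
})

test_that("noiseless data are an exact mixture of the planted maps", {
  spec <- cohortSpec(gridDims = c(8L, 8L, 6L), nPerGroup = c(2L, 2L),
                     nVolumes = 40L, noiseSd = 0, outlierRate = 0, seed = 5L)
  coh <- generateCohort(spec)
  for (i in c(1L, 3L)) {
    X <- boldMatrix(coh$subjects[[i]])
    maps <- coh$truth$subjectMaps[[i]]
    ## voxelwise regression on the planted time courses reproduces the data
    B <- t(qr.solve(t(maps), t(X)))
    expect_lt(max(abs(B %*% maps - X)), 1e-9)
  }
})

test_that("VAR simulation matches the closed-form lag-1 cross-covariance", {
  ## oracle: solve the discrete Lyapunov equation by vectorisation
  A1 <- matrix(c(0.3, 0.8, 0, 0.3), 2, 2, byrow = TRUE)  # edge 1 -> 2
  A <- array(A1, c(2, 2, 1))
  Sig <- matrix(solve(diag(4) - kronecker(A1, A1), as.vector(diag(2))), 2)
  lag1 <- A1 %*% Sig   # cov(x_t, x_{t-1})
  X <- simulateVAR(A, 30000L, seed = 77L)
  emp <- crossprod(X[-1, ], X[-nrow(X), ]) / (nrow(X) - 1)
  expect_lt(max(abs(emp - lag1)), 0.05)
  expect_error(simulateVAR(array(1.2, c(1, 1, 1)), 100L, seed = 1L),
               "spectral radius")
})

test_that("source maps honour jitter and separation contracts", {
  gd <- c(12L, 12L, 10L); vs <- c(3.75, 3.75, 3.5)
  m0 <- makeSourceMaps(gd, vs, 2L, 10, subjectJitterMm = 0, nSubjects = 3L,
                       seed = 4L)
  for (s in m0$subject) expect_equal(s, m0$canonical, tolerance = 1e-12)
  ## sources at opposite corners are spatially uncorrelated
  ctr <- rbind(c(8, 8, 8), c(37, 37, 27))
  m1 <- makeSourceMaps(gd, vs, 2L, 6, 0, 1L, seed = 4L, centersMm = ctr)
  expect_lt(abs(stats::cor(m1$canonical[1, ], m1$canonical[2, ])), 0.05)
  ## 3 mm jitter at 12 mm FWHM: correlation against the analytic
  ## Gaussian-shift bound exp(-d^2 / (4 sigma^2))
  mj <- makeSourceMaps(c(16L, 16L, 12L), vs, 2L, 12, 3, nSubjects = 8L,
                       seed = 4L)
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  bound <- exp(-3^2 / (4 * sigma^2))
  expect_gt(bound, 0.8)
  for (s in mj$subject) {
    for (k in 1:2)
      expect_gt(stats::cor(s[k, ], mj$canonical[k, ]), 0.8)
  }
})

test_that("severity generator hits its target correlation", {
  amps <- rnorm(50)
  s1 <- generateSeverity(amps, 1, seed = 2L)
  expect_equal(stats::cor(amps, s1), 1, tolerance = 1e-10)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s1), 1, tolerance = 1e-12)
  ## null: |r| below the two-sided 99% bound for n = 50
  r0 <- vapply(1:30, function(i) {
    a <- withr::with_seed(100 + i, rnorm(50))
    stats::cor(a, generateSeverity(a, 0, seed = 200 + i))
  }, numeric(1))
  bound99 <- stats::qt(0.995, 48) / sqrt(48 + stats::qt(0.995, 48)^2)
  expect_lt(mean(abs(r0) > bound99), 0.2)
  ## planted -0.30 at n = 1000 recovered within sampling error
  a <- withr::with_seed(7, rnorm(1000))
  s <- generateSeverity(a, -0.30, seed = 8L)
  expect_lt(abs(stats::cor(a, s) - (-0.30)), 0.08)
  expect_error(generateSeverity(amps, -1.2, seed = 1L), "-1, 1")
  expect_error(generateSeverity(rep(1, 10), 0.5, seed = 1L), "equal")
})

test_that("planted group structure is recorded in the ground truth", {
  spec <- cohortSpec(gridDims = c(8L, 8L, 6L), nPerGroup = c(5L, 5L),
                     nVolumes = 40L, seed = 3L)
  coh <- generateCohort(spec)
  tr <- coh$truth
  edges <- tr$varAdjacency
  ## every planted edge has a nonzero coefficient in at least one group
  expect_true(all(edges$coefficient != 0))
  ## patient coefficients are the halved control ones
  ge <- tr$groupEffects$edges
  expect_equal(ge$patientCoef, ge$controlCoef / 2)
  expect_identical(tr$mediatedChains,
                   data.frame(source = 3L, mediator = 4L, target = 2L))
  expect_equal(sum(!is.na(tr$severityScores)), 5)
  expect_equal(length(tr$outlierIndices), 10)
  ## groups only differ as recorded: amplitude table covers sources 1-3
  expect_setequal(tr$groupEffects$amplitude$source, c(1L, 2L, 3L))
})

test_that("cohort IO round-trips through NIfTI, TSV and JSON", {
  spec <- cohortSpec(gridDims = c(6L, 6L, 4L), nPerGroup = c(2L, 2L),
                     nVolumes = 20L, sourceFwhmMm = 6, seed = 12L)
  coh <- generateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "phenotype.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- readCohort(dir)
  expect_length(back, 4)
  expect_equal(boldData(back[[2]]), boldData(coh$subjects[[2]]),
               tolerance = 1e-6)
  expect_equal(motionTrace(back[[2]]), motionTrace(coh$subjects[[2]]),
               tolerance = 1e-6)
  expect_identical(subjectGroup(back[[1]]), "patient")
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_length(gt$outlierIndices, 4)
})
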