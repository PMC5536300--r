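test_that("tanimoto similarity obeys its closed-form contracts", {
  a <- c(0, 1, 2, 3, -1)
  expect_equal(tanimotoSimilarity(a, a), 1)
  expect_equal(tanimotoDistance(a, a), 0)
  b <- c(3, 2, 1, 0, -1)
  expect_equal(tanimotoSimilarity(a, b), tanimotoSimilarity(b, a))
  ## binary mode set-count oracle: |A| = 30, |B| = 20, overlap 10 -> 0.25
  x <- numeric(100); y <- numeric(100)
  x[1:30] <- 3; y[21:40] <- 3
  expect_equal(tanimotoSimilarity(x, y, mode = "binary", zThreshold = 2),
               10 / 40)
  ## disjoint binary supports
  y2 <- numeric(100); y2[61:80] <- 3
  expect_equal(tanimotoSimilarity(x, y2, mode = "binary"), 0)
  expect_error(tanimotoSimilarity(a, c(1, 2)), "mask")
  expect_warning(tanimotoSimilarity(c(-1, -2, 0), c(-3, -1, 0)), "empty")
})

test_that("bidirectional matching returns exactly the mutual best pairs", {
  set.seed(21)
  maps <- matrix(rnorm(4 * 50), 4)
  s <- makeTestICSet(maps, "a")
  m <- bidirectionalMatch(s, s)
  expect_equal(m$a, m$b)
  expect_equal(nrow(m), 4)
  expect_true(all(m$similarity == 1))
  ## constructed trio: A1 <-> B1 mutual, A2's best is B1 but B1 prefers A1
  base <- abs(rnorm(60)) + 0.5
  A1 <- base; B1 <- base + rnorm(60, sd = 0.01)
  A2 <- base + rnorm(60, sd = 0.3)
  A3 <- abs(rnorm(60)); B2 <- abs(rnorm(60)); B3 <- abs(rnorm(60))
  sA <- makeTestICSet(rbind(A1, A2, A3), "a")
  sB <- makeTestICSet(rbind(B1, B2, B3), "b")
  ## verify the construction with a plain-loop similarity table, then the
  ## match
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    S[i, j] <- tanimotoSimilarity(icMaps(sA)[i, ], icMaps(sB)[j, ])
  stopifnot(which.max(S[2, ]) == 1, which.max(S[, 1]) == 1)
  m2 <- bidirectionalMatch(sA, sB)
  expect_true(any(m2$a == 1 & m2$b == 1))
  expect_false(any(m2$a == 2 & m2$b == 1))
})

test_that("cronbach alpha matches its closed forms", {
  set.seed(22)
  m <- matrix(rnorm(300), 3)
  ident <- m[c(1, 1, 1), ]
  expect_equal(cronbachAlpha(ident)$alpha, 1, tolerance = 1e-12)
  ## k = 2 closed form from item variances and covariance
  two <- m[1:2, ]
  v <- apply(two, 1, var); c2 <- cov(two[1, ], two[2, ])
  expect_equal(cronbachAlpha(two)$alpha,
               2 * (1 - (v[1] + v[2]) / (v[1] + v[2] + 2 * c2)),
               tolerance = 1e-12)
  ## independent maps: alpha near 0 across seeds
  alphas <- vapply(1:20, function(s) {
    set.seed(400 + s)
    cronbachAlpha(matrix(rnorm(5 * 1000), 5))$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas)), 0.1)
  expect_error(cronbachAlpha(matrix(1, 3, 10)), "variance")
  expect_error(cronbachAlpha(m[1, , drop = FALSE]), "2")
})

test_that("one-sample t maps handle degenerate voxels", {
  maps <- rbind(c(1, 0, 5), c(2, 0, 5), c(3, 0, 5))
  r <- oneSampleTMap(maps)
  expect_equal(r$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t[2], 0)
  expect_equal(r$t[3], 1e6)
  expect_true(r$degenerate)
  expect_error(oneSampleTMap(maps[1:2, ]), "3")
})

test_that("within-order clustering equals the brute-force construction", {
  ## criterion also exercised at acceptance scale; here a targeted case
  set.seed(23)
  shared <- abs(rnorm(80)) + c(rep(2, 15), rep(0, 65))
  sets <- lapply(1:3, function(i) {
    noise <- matrix(abs(rnorm(2 * 80)), 2)
    makeTestICSet(rbind(shared + rnorm(80, sd = 0.05), noise),
                  paste0("s", i), seed = i)
  })
  got <- formClustersWithinOrder(sets, minSubjectFraction = 0.5)
  gotKeys <- lapply(got, function(cl)
    sort(paste(cl$members$subject, cl$members$component, sep = "|")))
  gotKeys <- gotKeys[order(vapply(gotKeys, paste, character(1),
                                  collapse = ","))]
  oracle <- bruteForceClusters(sets, 0.5)
  expect_identical(gotKeys, oracle)
  ## the shared source forms a cluster across all subjects
  expect_true(any(vapply(got, function(cl)
    all(paste0("s", 1:3) %in% cl$members$subject), logical(1))))
  expect_error(formClustersWithinOrder(sets[1]), "2 subjects")
})

test_that("clustering is invariant to component order and subject labels", {
  set.seed(24)
  shared1 <- abs(rnorm(80)) + c(rep(2, 15), rep(0, 65))
  shared2 <- abs(rnorm(80)) + c(rep(0, 50), rep(2, 20), rep(0, 10))
  rawMaps <- lapply(1:3, function(i)
    rbind(shared1 + rnorm(80, sd = 0.05),
          shared2 + rnorm(80, sd = 0.05),
          abs(rnorm(80))))
  perms <- list(1:3, c(2, 3, 1), c(3, 1, 2))
  setsId <- lapply(1:3, function(i)
    makeTestICSet(rawMaps[[i]], paste0("s", i), seed = i))
  setsPerm <- lapply(1:3, function(i)
    makeTestICSet(rawMaps[[i]][perms[[i]], ], paste0("s", i), seed = i))
  a <- formClustersWithinOrder(setsId)
  b <- formClustersWithinOrder(setsPerm)
  ## compare by which underlying map each member is (undo the permutation)
  keyed <- function(cls, perms) {
    ks <- lapply(cls, function(cl) sort(vapply(seq_len(nrow(cl$members)),
      function(r) {
        s <- as.integer(sub("s", "", cl$members$subject[r]))
        paste0(cl$members$subject[r], "|",
               perms[[s]][cl$members$component[r]])
      }, character(1))))
    ks[order(vapply(ks, paste, character(1), collapse = ","))]
  }
  expect_identical(keyed(a, list(1:3, 1:3, 1:3)), keyed(b, perms))
  ## relabelling subjects permutes but does not change the clusters
  setsRe <- lapply(c(3, 1, 2), function(i)
    makeTestICSet(rawMaps[[i]], paste0("s", i), seed = i))
  c2 <- formClustersWithinOrder(setsRe)
  expect_identical(keyed(a, list(1:3, 1:3, 1:3)),
                   keyed(c2, list(1:3, 1:3, 1:3)))
})

test_that("cross-order matching retains reliable clusters only", {
  set.seed(26)
  shared <- abs(rnorm(120)) + c(rep(3, 20), rep(0, 100))
  mkOrder <- function(o, nsub = 4) {
    sets <- lapply(seq_len(nsub), function(i) {
      m <- rbind(shared + rnorm(120, sd = 0.05),
                 abs(rnorm(120)), abs(rnorm(120)))
      makeTestICSet(m, paste0("s", i), seed = o * 10 + i)
    })
    formClustersWithinOrder(sets)
  }
  perOrder <- list("3" = mkOrder(1), "4" = mkOrder(2), "5" = mkOrder(3))
  got <- matchAcrossOrders(perOrder, alphaThreshold = 0.7)
  expect_gte(length(got), 1)
  main <- got[[1]]
  expect_s4_class(main, "ReproducibleCluster")
  expect_gte(clusterAlpha(main), 0.7)
  expect_equal(sort(unique(clusterMembers(main)$subject)), paste0("s", 1:4))
  expect_equal(nrow(clusterRepresentatives(main)), 4)
  ## unattainable alpha threshold empties the retention
  expect_warning(none <- matchAcrossOrders(perOrder, alphaThreshold = 1.01),
                 "no cluster")
  expect_length(none, 0)
  expect_error(matchAcrossOrders(perOrder[1]), "2 orders")
})
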