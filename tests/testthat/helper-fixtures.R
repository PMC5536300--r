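## Shared fixtures and independent oracles for the test suite.

.fixtureCache <- new.env(parent = emptyenv())

## Build an ICSet directly from a matrix of maps (rows z-scored here), with
## white-noise time courses; used to drive matching tests with hand-built
## spatial configurations.
makeTestICSet <- function(maps, subjectId, order = nrow(maps), tLen = 30L,
                          seed = 1L) {
  maps <- t(apply(maps, 1, function(v) (v - mean(v)) / stats::sd(v)))
  set.seed(seed)
  new("ICSet", subjectId = subjectId, modelOrder = as.integer(nrow(maps)),
      maps = maps, timecourses = matrix(rnorm(tLen * nrow(maps)), tLen),
      converged = rep(TRUE, nrow(maps)), pcaExplainedVariance = 1)
}

## Independent brute-force re-implementation of stage-1 HPM clustering:
## plain double loops for the Tanimoto similarities, explicit mutual-best
## matching, and repeated merging for connected components.
bruteForceClusters <- function(icsets, minSubjectFraction = 0.5) {
  tani <- function(a, b) {
    a <- pmax(a, 0); b <- pmax(b, 0)
    den <- sum(a * a) + sum(b * b) - sum(a * b)
    if (den <= 0) return(0)
    sum(a * b) / den
  }
  ids <- vapply(icsets, function(x) x@subjectId, character(1))
  nodes <- list()
  for (i in seq_along(icsets))
    for (c in seq_len(icsets[[i]]@modelOrder))
      nodes[[length(nodes) + 1]] <- c(i, c)
  edges <- list()
  for (i in seq_along(icsets)) for (j in seq_along(icsets)) {
    if (i >= j) next
    A <- icsets[[i]]@maps; B <- icsets[[j]]@maps
    for (a in seq_len(nrow(A))) {
      simsB <- vapply(seq_len(nrow(B)), function(b) tani(A[a, ], B[b, ]),
                      numeric(1))
      b <- which.max(simsB)
      simsA <- vapply(seq_len(nrow(A)), function(k) tani(B[b, ], A[k, ]),
                      numeric(1))
      if (which.max(simsA) == a)
        edges[[length(edges) + 1]] <- c(i, a, j, b)
    }
  }
  ## connected components by repeated merging
  comp <- seq_along(nodes)
  key <- vapply(nodes, paste, character(1), collapse = "|")
  find <- function(i, c) match(paste(i, c, sep = "|"), key)
  repeat {
    changed <- FALSE
    for (e in edges) {
      u <- find(e[1], e[2]); v <- find(e[3], e[4])
      if (comp[u] != comp[v]) {
        comp[comp == comp[v]] <- comp[u]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2) next
    subj <- vapply(members, function(m) ids[nodes[[m]][1]], character(1))
    if (length(unique(subj)) < minSubjectFraction * length(icsets)) next
    ## one member per subject: highest mean similarity to the other members
    memMaps <- lapply(members, function(m)
      icsets[[nodes[[m]][1]]]@maps[nodes[[m]][2], ])
    meanSim <- vapply(seq_along(members), function(a)
      mean(vapply(seq_along(members)[-a], function(b)
        tani(memMaps[[a]], memMaps[[b]]), numeric(1))), numeric(1))
    keep <- logical(length(members))
    for (s in unique(subj)) {
      idx <- which(subj == s)
      keep[idx[which.max(meanSim[idx])]] <- TRUE
    }
    memKey <- sort(vapply(members[keep], function(m)
      paste(ids[nodes[[m]][1]], nodes[[m]][2], sep = "|"), character(1)))
    out[[length(out) + 1]] <- memKey
  }
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

## The default synthetic study, run end-to-end once per test session and
## cached: cohort at the generator defaults, preprocessing, ICA at the
## desk-scale orders, both HPM stages, per-cluster group statistics, and the
## cluster-to-planted-source assignment.
toyRunFixture <- function() {
  if (!is.null(.fixtureCache$toy)) return(.fixtureCache$toy)
  spec <- cohortSpec(seed = 20L)
  coh <- generateCohort(spec)
  pre <- lapply(coh$subjects, function(s) preprocessSubject(s)$series)
  ica <- lapply(pre, function(s)
    runSubjectICA(s, enumerateModelOrders(10L, 40L), seed = 42L))
  clusters <- runHPM(ica)
  names(clusters) <- vapply(clusters, function(cl) cl@clusterId, character(1))
  covar <- data.frame(
    subject = vapply(pre, subjectId, character(1)),
    group = vapply(pre, subjectGroup, character(1)),
    age = vapply(pre, function(s) s@age, numeric(1)),
    sex = vapply(pre, function(s) s@sex, character(1)),
    severity = vapply(pre, function(s) s@severity, numeric(1)))
  mask <- pre[[1]]@mask
  vox <- pre[[1]]@voxelSizeMm
  truth <- coh$truth
  tmaps <- do.call(rbind, lapply(clusters, clusterTMap))
  corMat <- stats::cor(t(truth$canonicalMaps), t(tmaps))
  assign <- apply(abs(corMat), 2, which.max)
  groupStats <- lapply(clusters, function(cl) {
    reps <- clusterRepresentatives(cl)
    cv <- covar[match(rownames(reps), covar$subject), , drop = FALSE]
    des <- makeGroupDesign(cv)
    fit <- fitVoxelwiseGLM(reps, des$X, des$contrast)
    fw <- estimateSmoothnessFwhm(fit$residuals, mask, vox)
    ext <- monteCarloExtentThreshold(mask, vox, fw, nIter = 1000L, seed = 3L)
    cls <- thresholdClusters(fit$tMap, mask, fit$df, 0.01, ext)
    list(fit = fit, extent = ext, clusters = cls)
  })
  fix <- list(spec = spec, truth = truth, ica = ica, clusters = clusters,
              covar = covar, mask = mask, vox = vox, corMat = corMat,
              assign = assign, groupStats = groupStats)
  .fixtureCache$toy <- fix
  fix
}

## GCI table over the fixture's clusters (named by planted source), with the
## cluster matched to source 4 as the mediator; cached.
toyGCIFixture <- function() {
  if (!is.null(.fixtureCache$gci)) return(.fixtureCache$gci)
  fix <- toyRunFixture()
  cl <- fix$clusters
  names(cl) <- paste0("s", fix$assign)
  tab <- computeGCITable(cl, fix$ica, fix$covar$subject, p = 1L,
                         mediator = "s4")
  grp <- stats::setNames(fix$covar$group, fix$covar$subject)
  out <- list(clusters = cl, table = tab,
              groupTable = gciGroupTable(tab, grp), groups = grp)
  .fixtureCache$gci <- out
  out
}

## VAR chain x -> m -> y with an autocorrelated driver; used for mediated
## Granger-causality checks (a white-noise driver carries no lag-1
## information about its own past, so the chain needs self-dependence to be
## visible at lag 1).
simChain <- function(T, aSelf = 0.5, c1 = 0.8, c2 = 0.8, seed = 1) {
  set.seed(seed)
  x <- numeric(T); m <- numeric(T); y <- numeric(T)
  ex <- rnorm(T); em <- rnorm(T); ey <- rnorm(T)
  for (t in 2:T) {
    x[t] <- aSelf * x[t - 1] + ex[t]
    m[t] <- c1 * x[t - 1] + em[t]
    y[t] <- c2 * m[t - 1] + ey[t]
  }
  list(x = x, m = m, y = y)
}

## Two Gaussian classes separated by `gap` sd in every feature.
sepData <- function(n = 40, d = 2, gap = 10, seed = 51) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * d), n / 2),
             matrix(rnorm(n / 2 * d, mean = gap), n / 2))
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = factor(rep(c("patient", "control"), each = n / 2),
                         levels = c("patient", "control")))
}
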