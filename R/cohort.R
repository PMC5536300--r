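## Synthetic resting-state cohort generator: spatially smooth planted sources,
## VAR-driven time courses with directed group effects, a severity covariate,
## and motion-corrupted outlier volumes. Every downstream stage of the
## pipeline has a recoverable ground truth against this generator.

#' Construct a cohort specification
#'
#' Builds a [CohortSpec-class] with desk-scale defaults: a 16 x 16 x 12 grid
#' at 3.75 x 3.75 x 3.5 mm, 146 volumes at TR 2.2 s, 20 + 20 subjects, and
#' K = 4 Gaussian sources driven by a stationary VAR(1). The default group
#' structure plants the effects the pipeline is designed to recover: the
#' patient-like group has amplitude ratio 0.7 on sources 1 and 3, ratio 1.3
#' on source 2, all planted directed coefficients halved (edge 1 -> 2 and
#' the mediated chain 3 -> 4 -> 2), and a severity score correlated at
#' -0.30 with the amplitude of source 1.
#'
#' @param gridDims integer(3), voxels per axis.
#' @param voxelSizeMm numeric(3), mm per voxel.
#' @param nVolumes volumes per subject.
#' @param trSeconds repetition time, seconds.
#' @param nPerGroup integer(2): patients, controls.
#' @param nSources number of planted sources K.
#' @param sourceFwhmMm FWHM of each Gaussian source, mm.
#' @param sourceCentersMm optional K x 3 matrix of centres (mm); placed
#'   automatically when `NULL`.
#' @param subjectJitterMm max per-subject source translation, mm.
#' @param varOrder VAR lag order.
#' @param varCoefficients list(patient=, control=) of K x K x p arrays;
#'   defaults as described above.
#' @param amplitudeScale K x 2 matrix (patient, control) of amplitude
#'   multipliers; defaults as described above.
#' @param amplitudeJitterSd sd of per-subject log-normal amplitude jitter.
#' @param noiseSd sd of i.i.d. Gaussian voxel noise.
#' @param severityTargetR planted severity-amplitude correlation.
#' @param severitySource source index carrying the severity correlation.
#' @param outlierRate per-volume probability of a planted artifact volume.
#' @param seed master integer seed.
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPerGroup = c(3L, 3L), nVolumes = 40L)
#' spec
#' @export
cohortSpec <- function(gridDims = c(16L, 16L, 12L),
                       voxelSizeMm = c(3.75, 3.75, 3.5),
                       nVolumes = 146L,
                       trSeconds = 2.2,
                       nPerGroup = c(20L, 20L),
                       nSources = 4L,
                       sourceFwhmMm = 12,
                       sourceCentersMm = NULL,
                       subjectJitterMm = 1.5,
                       varOrder = 1L,
                       varCoefficients = NULL,
                       amplitudeScale = NULL,
                       amplitudeJitterSd = 0.10,
                       noiseSd = 2.0,
                       severityTargetR = -0.30,
                       severitySource = 1L,
                       outlierRate = 0.03,
                       seed = 20L) {
  K <- as.integer(nSources)
  p <- as.integer(varOrder)
  if (K >= nVolumes)
    stop(sprintf("nSources (%d) must be < nVolumes (%d)", K,
                 as.integer(nVolumes)))
  if (prod(gridDims) < 10 * K)
    stop("grid voxel count must be >= 10 x nSources")
  if (is.null(varCoefficients)) {
    if (K < 4 || p != 1)
      stop("default varCoefficients need nSources >= 4 and varOrder 1; ",
           "supply varCoefficients explicitly")
    Ac <- array(0, c(K, K, 1))
    for (k in seq_len(K)) Ac[k, k, 1] <- 0.3
    Ac[2, 1, 1] <- 0.35  # direct edge 1 -> 2
    Ac[4, 3, 1] <- 0.35  # chain leg 3 -> 4
    Ac[2, 4, 1] <- 0.35  # chain leg 4 -> 2 (mediated 3 -> 4 -> 2)
    Ap <- Ac
    Ap[2, 1, 1] <- Ac[2, 1, 1] / 2
    Ap[4, 3, 1] <- Ac[4, 3, 1] / 2
    Ap[2, 4, 1] <- Ac[2, 4, 1] / 2
    varCoefficients <- list(patient = Ap, control = Ac)
  }
  if (is.null(amplitudeScale)) {
    amplitudeScale <- matrix(1, K, 2, dimnames = list(NULL, c("patient", "control")))
    if (K >= 3) {
      ## sources 1 and 3 weakened by 0.7 in the patient-like group; source 2
      ## sits at a lower baseline strength and is strengthened by 1.3
      amplitudeScale[1, "patient"] <- 0.7
      amplitudeScale[3, "patient"] <- 0.7
      amplitudeScale[2, "control"] <- 0.6
      amplitudeScale[2, "patient"] <- 0.6 * 1.3
    }
  }
  if (is.null(sourceCentersMm)) {
    sourceCentersMm <- placeSourceCenters(gridDims, voxelSizeMm, K,
                                          sourceFwhmMm)
  }
  new("CohortSpec",
      gridDims = as.integer(gridDims), voxelSizeMm = as.numeric(voxelSizeMm),
      nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
      nPerGroup = as.integer(nPerGroup), nSources = K,
      sourceFwhmMm = sourceFwhmMm, sourceCentersMm = sourceCentersMm,
      subjectJitterMm = subjectJitterMm, varOrder = p,
      varCoefficients = varCoefficients, amplitudeScale = amplitudeScale,
      amplitudeJitterSd = amplitudeJitterSd, noiseSd = noiseSd,
      severityTargetR = severityTargetR,
      severitySource = as.integer(severitySource),
      outlierRate = outlierRate, seed = as.integer(seed))
}

## Greedy farthest-point placement of K source centres inside the grid,
## keeping a margin of one FWHM/2 from the faces. Deterministic (canonical
## source geometry is part of the study design, not of the noise
## realisation). Errors when the grid cannot hold K centres at pairwise
## distance > fwhm.
placeSourceCenters <- function(gridDims, voxelSizeMm, K, fwhmMm) {
  ext <- gridDims * voxelSizeMm
  ## interior box: a blob at the margin ring would lose much of its support
  ## to the grid boundary
  margin <- ext / 4
  lo <- margin; hi <- ext - margin
  if (any(hi <= lo)) stop("grid too small to place sources")
  ## candidate lattice
  grd <- expand.grid(x = seq(lo[1], hi[1], length.out = 6),
                     y = seq(lo[2], hi[2], length.out = 6),
                     z = seq(lo[3], hi[3], length.out = 4))
  cand <- as.matrix(grd)
  pick <- integer(K)
  pick[1] <- 1L
  if (K > 1) {
    for (k in 2:K) {
      d <- apply(cand, 1, function(p)
        min(sqrt(colSums((t(cand[pick[1:(k - 1)], , drop = FALSE]) - p)^2))))
      pick[k] <- which.max(d)
    }
  }
  centers <- cand[pick, , drop = FALSE]
  dmin <- if (K > 1) min(stats::dist(centers)) else Inf
  if (dmin <= fwhmMm)
    stop(sprintf("grid too small: closest source centres %.1f mm apart but FWHM is %.1f mm",
                 dmin, fwhmMm))
  dimnames(centers) <- list(NULL, c("x", "y", "z"))
  centers
}

## Evaluate a unit-peak Gaussian blob centred at `center` (mm) over the grid.
gaussianBlob <- function(gridDims, voxelSizeMm, center, sigmaMm) {
  ax <- lapply(1:3, function(i) ((seq_len(gridDims[i]) - 0.5) * voxelSizeMm[i] - center[i])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  as.vector(exp(-d2 / (2 * sigmaMm^2)))
}

#' Generate per-subject planted source maps
#'
#' Each canonical source is a unit-peak Gaussian blob; each subject's copy is
#' the canonical blob translated by a random offset of magnitude at most
#' `subjectJitterMm` (uniform direction, uniform magnitude). Canonical
#' sources are placed so that pairwise spatial correlation is below 0.3.
#'
#' @param gridDims integer(3) voxels per axis.
#' @param voxelSizeMm numeric(3) mm per voxel.
#' @param nSources number of sources K.
#' @param sourceFwhmMm blob FWHM in mm.
#' @param subjectJitterMm max translation magnitude in mm.
#' @param nSubjects number of subjects.
#' @param seed integer seed.
#' @param centersMm optional K x 3 matrix of centres.
#' @return list with `canonical` (K x M matrix, M = prod(gridDims)),
#'   `subject` (list of K x M matrices, one per subject), `centersMm`.
#' @export
makeSourceMaps <- function(gridDims, voxelSizeMm, nSources, sourceFwhmMm,
                           subjectJitterMm, nSubjects, seed,
                           centersMm = NULL) {
  if (is.null(centersMm))
    centersMm <- placeSourceCenters(gridDims, voxelSizeMm, nSources,
                                    sourceFwhmMm)
  sigma <- fwhmToSigma(sourceFwhmMm)
  canonical <- t(vapply(seq_len(nSources), function(k)
    gaussianBlob(gridDims, voxelSizeMm, centersMm[k, ], sigma),
    numeric(prod(gridDims))))
  if (nSources > 1) {
    cc <- stats::cor(t(canonical))
    offd <- abs(cc[upper.tri(cc)])
    if (any(offd >= 0.3))
      warning(sprintf("canonical sources overlap: max pairwise correlation %.2f >= 0.3",
                      max(offd)))
  }
  subject <- lapply(seq_len(nSubjects), function(i) {
    withSeed(deriveSeed(seed, 11L, i), {
      t(vapply(seq_len(nSources), function(k) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        off <- u * stats::runif(1, 0, subjectJitterMm)
        gaussianBlob(gridDims, voxelSizeMm, centersMm[k, ] + off, sigma)
      }, numeric(prod(gridDims))))
    })
  })
  list(canonical = canonical, subject = subject, centersMm = centersMm)
}

#' Simulate a stationary VAR(p) time series
#'
#' @param A K x K x p coefficient array (`A[i, j, l]`: effect of series j at
#'   lag l on series i).
#' @param nObs length of the returned series.
#' @param seed integer seed.
#' @param burnin discarded initial steps (default 100).
#' @param innovSd innovation sd (default 1, independent across series).
#' @return nObs x K matrix.
#' @export
simulateVAR <- function(A, nObs, seed, burnin = 100L, innovSd = 1) {
  K <- dim(A)[1]; p <- dim(A)[3]
  rho <- spectralRadius(companionMatrix(A))
  if (rho >= 1)
    stop(sprintf("non-stationary VAR: companion spectral radius %.4f >= 1", rho))
  tot <- nObs + burnin
  withSeed(seed, {
    E <- matrix(stats::rnorm(tot * K, sd = innovSd), tot, K)
    X <- matrix(0, tot, K)
    for (t in seq_len(tot)) {
      x <- E[t, ]
      for (l in seq_len(p)) if (t > l) x <- x + A[, , l] %*% X[t - l, ]
      X[t, ] <- x
    }
    X[(burnin + 1):tot, , drop = FALSE]
  })
}

#' Plant a severity score with a target correlation to source amplitude
#'
#' severity = r * standardized(amplitude) + sqrt(1 - r^2) * independent noise,
#' then standardized to mean 0, sd 1, so the population correlation with the
#' amplitudes equals `targetR`.
#'
#' @param amplitudes per-subject source amplitudes (length >= 3, not all
#'   equal).
#' @param targetR target Pearson correlation in [-1, 1].
#' @param seed integer seed.
#' @return standardized severity scores, one per subject.
#' @export
generateSeverity <- function(amplitudes, targetR, seed) {
  if (abs(targetR) > 1) stop("targetR must lie in [-1, 1]")
  if (length(amplitudes) < 3) stop("need at least 3 subjects")
  if (stats::sd(amplitudes) == 0) stop("amplitudes must not all be equal")
  z <- zscoreVec(amplitudes)
  eps <- withSeed(seed, stats::rnorm(length(amplitudes)))
  s <- targetR * z + sqrt(1 - targetR^2) * eps
  zscoreVec(s)
}

#' Generate a synthetic multi-subject BOLD cohort
#'
#' Each subject's 4-D data are the sum over sources of (per-subject jittered
#' spatial map) x (amplitude-scaled VAR time course), plus i.i.d. Gaussian
#' noise. Planted artifact volumes receive a global-signal spike and a motion
#' jump in the subject's motion trace. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [CohortSpec-class].
#' @return list with `subjects` (list of [SubjectSeries-class], patients
#'   first) and `truth`, a ground-truth list with elements `canonicalMaps`
#'   (K x M), `subjectMaps`, `centersMm`, `varAdjacency` (planted directed
#'   edges per group), `mediatedChains`, `groupEffects`, `severityScores`,
#'   `outlierIndices`, `subjectAmplitudes` (n x K), and `mask`.
#' @examples
#' spec <- cohortSpec(gridDims = c(8L, 8L, 6L), nPerGroup = c(2L, 2L),
#'                    nVolumes = 40L, noiseSd = 0.2, seed = 7L)
#' coh <- generateCohort(spec)
#' coh$subjects[[1]]
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  K <- spec@nSources
  M <- prod(spec@gridDims)
  Tn <- spec@nVolumes
  n <- sum(spec@nPerGroup)
  groups <- rep(c("patient", "control"), spec@nPerGroup)
  ids <- sprintf("sub-%03d", seq_len(n))

  maps <- makeSourceMaps(spec@gridDims, spec@voxelSizeMm, K,
                         spec@sourceFwhmMm, spec@subjectJitterMm, n,
                         seed = deriveSeed(spec@seed, 1L),
                         centersMm = spec@sourceCentersMm)
  mask <- array(TRUE, spec@gridDims)
  sexSplit <- function(nn) rep(c("M", "F"), c(round(nn * 27 / 44), nn - round(nn * 27 / 44)))
  sexes <- c(sexSplit(spec@nPerGroup[1]), sexSplit(spec@nPerGroup[2]))
  ages <- withSeed(deriveSeed(spec@seed, 3L), stats::runif(n, 8, 49))

  subjectAmplitudes <- matrix(NA_real_, n, K)
  outlierIndices <- vector("list", n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    A <- spec@varCoefficients[[g]]
    tc <- simulateVAR(A, Tn, seed = deriveSeed(spec@seed, 5L, i))
    amp <- withSeed(deriveSeed(spec@seed, 6L, i),
                    spec@amplitudeScale[, g] *
                      exp(stats::rnorm(K, 0, spec@amplitudeJitterSd)))
    subjectAmplitudes[i, ] <- amp
    X <- sweep(tc, 2, amp, "*") %*% maps$subject[[i]]  # T x M
    if (spec@noiseSd > 0)
      X <- X + withSeed(deriveSeed(spec@seed, 7L, i),
                        matrix(stats::rnorm(Tn * M, sd = spec@noiseSd), Tn, M))
    ## motion trace: slow random walk well under any artifact threshold
    motion <- withSeed(deriveSeed(spec@seed, 8L, i), {
      apply(matrix(stats::rnorm(Tn * 6, sd = 0.02), Tn, 6), 2, cumsum)
    })
    out <- withSeed(deriveSeed(spec@seed, 9L, i),
                    which(stats::runif(Tn) < spec@outlierRate))
    out <- setdiff(out, 1L)  # keep the first volume clean as anchor
    if (length(out)) {
      X[out, ] <- X[out, ] + 5 * max(spec@noiseSd, 0.5)  # global-signal spike
      motion[out, 1] <- motion[out, 1] + 2               # 2-mm translation jump
    }
    outlierIndices[[i]] <- as.integer(out)
    bold <- array(t(X), c(spec@gridDims, Tn))
    subjects[[i]] <- new("SubjectSeries",
      subjectId = ids[i], group = g, age = ages[i], sex = sexes[i],
      severity = NA_real_, bold = bold, mask = mask,
      voxelSizeMm = spec@voxelSizeMm, trSeconds = spec@trSeconds,
      motion = motion)
  }

  patIdx <- which(groups == "patient")
  severityScores <- stats::setNames(rep(NA_real_, n), ids)
  amps <- subjectAmplitudes[patIdx, spec@severitySource]
  if (length(patIdx) >= 3 && stats::sd(amps) > 0) {
    sev <- generateSeverity(amps, spec@severityTargetR,
                            seed = deriveSeed(spec@seed, 4L))
    severityScores[patIdx] <- sev
    for (j in seq_along(patIdx)) subjects[[patIdx[j]]]@severity <- sev[j]
  }

  varAdjacency <- do.call(rbind, lapply(c("patient", "control"), function(g) {
    A <- spec@varCoefficients[[g]]
    idx <- which(A != 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    if (!nrow(idx)) return(NULL)
    data.frame(group = g, source = idx[, 2], target = idx[, 1],
               lag = idx[, 3], coefficient = A[idx])
  }))
  mediatedChains <- data.frame(source = 3L, mediator = 4L, target = 2L)[
    rep(1, K >= 4), , drop = FALSE]
  ampRatio <- spec@amplitudeScale[, "patient"] / spec@amplitudeScale[, "control"]
  groupEffects <- list(
    amplitude = data.frame(source = which(ampRatio != 1),
                           ratio = ampRatio[ampRatio != 1]),
    edges = local({
      e <- varAdjacency[varAdjacency$group == "control", c("source", "target", "lag")]
      if (is.null(e) || !nrow(e)) return(e)
      e$controlCoef <- varAdjacency$coefficient[varAdjacency$group == "control"]
      pc <- merge(e, varAdjacency[varAdjacency$group == "patient", ],
                  by = c("source", "target", "lag"), all.x = TRUE)
      data.frame(source = pc$source, target = pc$target, lag = pc$lag,
                 controlCoef = pc$controlCoef,
                 patientCoef = ifelse(is.na(pc$coefficient), 0, pc$coefficient))
    }))

  truth <- list(canonicalMaps = maps$canonical, subjectMaps = maps$subject,
                centersMm = maps$centersMm, varAdjacency = varAdjacency,
                mediatedChains = mediatedChains, groupEffects = groupEffects,
                severityScores = severityScores,
                outlierIndices = outlierIndices,
                subjectAmplitudes = subjectAmplitudes, mask = mask)
  list(subjects = subjects, truth = truth)
}

#' Write a cohort to disk
#'
#' One 4-D NIfTI-1 file and one 6-column whitespace-separated motion trace
#' per subject, a phenotype TSV (subject_id, group, age, sex, severity), the
#' analysis mask as NIfTI, and a ground-truth JSON (canonical source maps,
#' centres, planted edges, severity scores, and outlier indices; per-subject
#' jittered maps are omitted from the JSON for size).
#'
#' @param cohort output of [generateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pheno <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s@subjectId, group = s@group, age = s@age,
               sex = s@sex, severity = s@severity)))
  utils::write.table(pheno, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in cohort$subjects) {
    im <- RNifti::asNifti(s@bold)
    RNifti::pixdim(im) <- c(s@voxelSizeMm, s@trSeconds)
    RNifti::writeNifti(im, file.path(dir, paste0(s@subjectId, "_bold.nii")))
    utils::write.table(s@motion,
                       file.path(dir, paste0(s@subjectId, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  m <- RNifti::asNifti(array(as.numeric(cohort$subjects[[1]]@mask),
                             dim(cohort$subjects[[1]]@mask)))
  RNifti::pixdim(m) <- cohort$subjects[[1]]@voxelSizeMm
  RNifti::writeNifti(m, file.path(dir, "mask.nii"))
  tr <- cohort$truth
  gt <- list(canonicalMaps = tr$canonicalMaps, centersMm = tr$centersMm,
             varAdjacency = tr$varAdjacency,
             mediatedChains = tr$mediatedChains,
             severityScores = as.list(tr$severityScores),
             outlierIndices = tr$outlierIndices,
             subjectAmplitudes = tr$subjectAmplitudes)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `phenotype.tsv`, per-subject NIfTI and
#'   motion files, and `mask.nii`.
#' @return list of [SubjectSeries-class].
#' @export
readCohort <- function(dir) {
  pheno <- utils::read.delim(file.path(dir, "phenotype.tsv"))
  mask <- array(RNifti::readNifti(file.path(dir, "mask.nii")) > 0.5,
                dim(RNifti::readNifti(file.path(dir, "mask.nii"))))
  lapply(seq_len(nrow(pheno)), function(i) {
    id <- pheno$subject_id[i]
    im <- RNifti::readNifti(file.path(dir, paste0(id, "_bold.nii")))
    pd <- RNifti::pixdim(im)
    motion <- as.matrix(utils::read.table(
      file.path(dir, paste0(id, "_motion.txt"))))
    dimnames(motion) <- NULL
    new("SubjectSeries", subjectId = id, group = pheno$group[i],
        age = pheno$age[i], sex = pheno$sex[i],
        severity = if (is.na(pheno$severity[i])) NA_real_ else pheno$severity[i],
        bold = array(as.numeric(im), dim(im)), mask = mask,
        voxelSizeMm = pd[1:3], trSeconds = if (length(pd) >= 4) pd[4] else NA_real_,
        motion = motion)
  })
}
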