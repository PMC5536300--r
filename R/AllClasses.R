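#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' CohortSpec: parameters of a synthetic resting-state cohort
#'
#' Describes a multi-subject synthetic BOLD cohort: the acquisition grid, the
#' planted spatial sources, the per-group vector-autoregressive (VAR) model
#' driving the source time courses, group amplitude effects, a severity
#' covariate tied to one source's amplitude, and the motion-outlier rate.
#' Construct with [cohortSpec()], which fills study-design defaults.
#'
#' @slot gridDims integer(3), voxels per axis.
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#' @slot nVolumes integer, time points per subject (default 146).
#' @slot trSeconds numeric, repetition time in seconds (default 2.2).
#' @slot nPerGroup integer(2), subjects in the patient-like and control-like
#'   groups.
#' @slot nSources integer, number of planted spatial sources K.
#' @slot sourceFwhmMm numeric, FWHM of the Gaussian source blobs in mm.
#' @slot sourceCentersMm K x 3 matrix of blob centres in mm (filled by the
#'   constructor if not given).
#' @slot subjectJitterMm numeric, max magnitude of the per-subject spatial
#'   translation applied to each source.
#' @slot varOrder integer, VAR lag order p.
#' @slot varCoefficients list with elements `patient` and `control`, each a
#'   K x K x p array; `[i, j, l]` is the effect of source j at lag l on
#'   source i.
#' @slot amplitudeScale K x 2 matrix (columns `patient`, `control`) of
#'   group amplitude multipliers per source.
#' @slot amplitudeJitterSd numeric, sd of the per-subject log-normal
#'   amplitude multiplier (gives subjects distinct amplitudes, which the
#'   severity covariate is planted against).
#' @slot noiseSd numeric, sd of i.i.d. Gaussian voxel noise.
#' @slot severityTargetR numeric in [-1, 1], planted correlation between
#'   severity and the severity source's amplitude.
#' @slot severitySource integer, index of the source carrying the severity
#'   correlation.
#' @slot outlierRate numeric in [0, 1), per-volume probability of a planted
#'   motion/global-signal artifact.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec", representation(
  gridDims = "integer",
  voxelSizeMm = "numeric",
  nVolumes = "integer",
  trSeconds = "numeric",
  nPerGroup = "integer",
  nSources = "integer",
  sourceFwhmMm = "numeric",
  sourceCentersMm = "matrix",
  subjectJitterMm = "numeric",
  varOrder = "integer",
  varCoefficients = "list",
  amplitudeScale = "matrix",
  amplitudeJitterSd = "numeric",
  noiseSd = "numeric",
  severityTargetR = "numeric",
  severitySource = "integer",
  outlierRate = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@gridDims) != 3 || any(object@gridDims < 1))
    msg <- c(msg, "gridDims must be 3 positive integers")
  if (length(object@voxelSizeMm) != 3 || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 positive reals")
  if (object@nVolumes <= object@varOrder + 10)
    msg <- c(msg, "nVolumes must exceed varOrder + 10")
  if (object@nSources >= object@nVolumes)
    msg <- c(msg, sprintf("nSources (%d) must be < nVolumes (%d)",
                          object@nSources, object@nVolumes))
  if (prod(object@gridDims) < 10 * object@nSources)
    msg <- c(msg, "grid voxel count must be >= 10 x nSources")
  if (abs(object@severityTargetR) > 1)
    msg <- c(msg, "severityTargetR must lie in [-1, 1]")
  if (object@outlierRate < 0 || object@outlierRate >= 1)
    msg <- c(msg, "outlierRate must lie in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  for (g in c("patient", "control")) {
    A <- object@varCoefficients[[g]]
    if (is.null(A) || length(dim(A)) != 3 ||
        any(dim(A) != c(object@nSources, object@nSources, object@varOrder))) {
      msg <- c(msg, sprintf("varCoefficients$%s must be a K x K x p array", g))
    } else {
      rho <- spectralRadius(companionMatrix(A))
      if (rho >= 1)
        msg <- c(msg, sprintf(
          "VAR for group '%s' is non-stationary: companion spectral radius %.4f >= 1",
          g, rho))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SubjectSeries: one subject's 4-D BOLD series plus covariates
#'
#' The unit of pipeline input: a 4-D BOLD-like array on a common grid, the
#' analysis mask, per-volume motion parameters, and the subject's covariates.
#'
#' @slot subjectId character scalar.
#' @slot group `"patient"` or `"control"`.
#' @slot age numeric, years.
#' @slot sex `"M"` or `"F"`.
#' @slot severity numeric, standardized severity score (`NA` for controls).
#' @slot bold 4-D numeric array indexed (x, y, z, t).
#' @slot mask 3-D logical array on the same spatial grid.
#' @slot voxelSizeMm numeric(3), mm per voxel.
#' @slot trSeconds numeric, repetition time in seconds.
#' @slot motion T x 6 matrix: 3 translations (mm), 3 rotations (degrees).
#' @export
setClass("SubjectSeries", representation(
  subjectId = "character",
  group = "character",
  age = "numeric",
  sex = "character",
  severity = "numeric",
  bold = "array",
  mask = "array",
  voxelSizeMm = "numeric",
  trSeconds = "numeric",
  motion = "matrix"
))

setValidity("SubjectSeries", function(object) {
  msg <- character()
  d <- dim(object@bold)
  if (length(d) != 4) msg <- c(msg, "bold must be a 4-D array")
  if (!identical(dim(object@mask), d[1:3]))
    msg <- c(msg, "mask dimensions must match the spatial grid of bold")
  if (!any(object@mask)) msg <- c(msg, "mask must be nonempty")
  if (nrow(object@motion) != d[4])
    msg <- c(msg, sprintf("motion has %d rows but bold has %d volumes",
                          nrow(object@motion), d[4]))
  if (ncol(object@motion) != 6) msg <- c(msg, "motion must have 6 columns")
  if (!object@group %in% c("patient", "control"))
    msg <- c(msg, "group must be 'patient' or 'control'")
  if (length(msg)) msg else TRUE
})

#' ICSet: the spatial independent components of one subject at one model order
#'
#' Holds the N z-scored spatial maps (rows, over mask voxels), the associated
#' time courses (columns, post-discard length), per-component convergence
#' flags, and the variance retained by the PCA reduction.
#'
#' @slot subjectId character scalar.
#' @slot modelOrder integer N, number of components.
#' @slot maps N x M numeric matrix of z-scored spatial maps.
#' @slot timecourses T' x N numeric matrix.
#' @slot converged logical(N).
#' @slot pcaExplainedVariance numeric in (0, 1].
#' @export
setClass("ICSet", representation(
  subjectId = "character",
  modelOrder = "integer",
  maps = "matrix",
  timecourses = "matrix",
  converged = "logical",
  pcaExplainedVariance = "numeric"
))

setValidity("ICSet", function(object) {
  msg <- character()
  N <- object@modelOrder
  if (nrow(object@maps) != N)
    msg <- c(msg, sprintf("expected %d map rows, found %d", N, nrow(object@maps)))
  if (ncol(object@timecourses) != N)
    msg <- c(msg, "timecourses must have one column per component")
  if (length(object@converged) != N)
    msg <- c(msg, "converged must have one flag per component")
  zok <- abs(rowMeans(object@maps)) < 1e-6 &
    abs(apply(object@maps, 1, stats::sd) - 1) < 1e-6
  if (!all(zok))
    msg <- c(msg, "each spatial map must be z-scored (mean 0, sd 1)")
  if (length(msg)) msg else TRUE
})

#' ReproducibleCluster: an HPM-selected cluster of matched components
#'
#' A cluster of bidirectionally matched independent components spanning
#' subjects (and, after the second matching stage, model orders), with its
#' Cronbach's alpha reliability, its one-sample t map, and one representative
#' z-map per contributing subject.
#'
#' @slot clusterId character scalar.
#' @slot members data.frame with columns `subject`, `order`, `component`.
#' @slot alpha numeric, Cronbach's alpha over the member maps.
#' @slot tMap numeric vector of one-sample t statistics over mask voxels.
#' @slot degenerateT logical, TRUE if any voxel hit the zero-variance t cap.
#' @slot representatives numeric matrix, one row per contributing subject
#'   (rownames are subject ids): the subject's mean member z-map.
#' @export
setClass("ReproducibleCluster", representation(
  clusterId = "character",
  members = "data.frame",
  alpha = "numeric",
  tMap = "numeric",
  degenerateT = "logical",
  representatives = "matrix"
))

setValidity("ReproducibleCluster", function(object) {
  msg <- character()
  need <- c("subject", "order", "component")
  if (!all(need %in% names(object@members)))
    msg <- c(msg, "members needs columns subject, order, component")
  if (nrow(object@representatives) > 0 &&
      is.null(rownames(object@representatives)))
    msg <- c(msg, "representatives must have subject ids as rownames")
  if (length(msg)) msg else TRUE
})
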