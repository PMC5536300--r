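## Accessors and show() methods for the pipeline's S4 objects.

#' @describeIn SubjectSeries-class number of volumes in a series
#' @param x a `SubjectSeries`.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @export
setMethod("nVolumes", "SubjectSeries", function(x) dim(x@bold)[4])

#' Subject identifier
#' @param x a pipeline object with a subject id.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @export
setMethod("subjectId", "SubjectSeries", function(x) x@subjectId)
#' @export
setMethod("subjectId", "ICSet", function(x) x@subjectId)

#' BOLD data array of a subject series
#' @param x a `SubjectSeries`.
#' @export
boldData <- function(x) x@bold

#' Analysis mask of a subject series
#' @param x a `SubjectSeries`.
#' @export
maskArray <- function(x) x@mask

#' Motion-parameter trace of a subject series
#' @param x a `SubjectSeries`.
#' @export
motionTrace <- function(x) x@motion

#' Diagnostic group of a subject series
#' @param x a `SubjectSeries`.
#' @export
subjectGroup <- function(x) x@group

#' Flatten a subject's BOLD array to a time-by-voxel matrix over the mask
#'
#' @param x a `SubjectSeries`.
#' @return a T x M matrix, M = number of mask voxels.
#' @export
boldMatrix <- function(x) {
  d <- dim(x@bold)
  m <- matrix(x@bold, prod(d[1:3]), d[4])
  t(m[as.vector(x@mask), , drop = FALSE])
}

#' Model order of an ICSet
#' @param x an `ICSet`.
#' @export
modelOrder <- function(x) x@modelOrder

#' Spatial map matrix of an ICSet (components x mask voxels)
#' @param x an `ICSet`.
#' @export
icMaps <- function(x) x@maps

#' Time-course matrix of an ICSet (time x components)
#' @param x an `ICSet`.
#' @export
icTimecourses <- function(x) x@timecourses

#' One independent component of an ICSet
#'
#' View of component `i`: its z-scored spatial map, time course, and
#' convergence flag.
#'
#' @param x an `ICSet`.
#' @param i component index.
#' @return a list with elements `subjectId`, `modelOrder`, `componentIndex`,
#'   `spatialZ`, `timecourse`, `converged`.
#' @export
icMap <- function(x, i) {
  stopifnot(i >= 1, i <= x@modelOrder)
  list(subjectId = x@subjectId, modelOrder = x@modelOrder,
       componentIndex = as.integer(i), spatialZ = x@maps[i, ],
       timecourse = x@timecourses[, i], converged = x@converged[i])
}

#' Cronbach's alpha of a reproducible cluster
#' @param x a `ReproducibleCluster`.
#' @export
clusterAlpha <- function(x) x@alpha

#' One-sample t map of a reproducible cluster
#' @param x a `ReproducibleCluster`.
#' @export
clusterTMap <- function(x) x@tMap

#' Member table of a reproducible cluster
#' @param x a `ReproducibleCluster`.
#' @export
clusterMembers <- function(x) x@members

#' Per-subject representative z-maps of a reproducible cluster
#' @param x a `ReproducibleCluster`.
#' @return matrix with subject ids as rownames.
#' @export
clusterRepresentatives <- function(x) x@representatives

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:",
      paste(object@gridDims, collapse = "x"), "grid,",
      object@nVolumes, "volumes @ TR", object@trSeconds, "s\n")
  cat("  groups:", object@nPerGroup[1], "patient /", object@nPerGroup[2],
      "control;", object@nSources, "sources, VAR(", object@varOrder, ")\n",
      sep = " ")
  cat("  noise sd", object@noiseSd, "| outlier rate", object@outlierRate,
      "| severity r", object@severityTargetR, "on source",
      object@severitySource, "| seed", object@seed, "\n")
})

setMethod("show", "SubjectSeries", function(object) {
  d <- dim(object@bold)
  cat(sprintf("SubjectSeries %s (%s, %s, age %.1f): %dx%dx%d x %d volumes, %d mask voxels\n",
              object@subjectId, object@group, object@sex, object@age,
              d[1], d[2], d[3], d[4], sum(object@mask)))
})

setMethod("show", "ICSet", function(object) {
  cat(sprintf("ICSet %s, order %d: %d maps x %d voxels, %d/%d converged, PCA var %.3f\n",
              object@subjectId, object@modelOrder, nrow(object@maps),
              ncol(object@maps), sum(object@converged),
              length(object@converged), object@pcaExplainedVariance))
})

setMethod("show", "ReproducibleCluster", function(object) {
  cat(sprintf("ReproducibleCluster %s: %d members over %d subjects x %d orders, alpha %.3f\n",
              object@clusterId, nrow(object@members),
              length(unique(object@members$subject)),
              length(unique(object@members$order)), object@alpha))
})
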