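## Preprocessing: initial-volume discard, artifact-volume detection from the
## first-order derivative of the motion parameters and the global mean
## signal, interpolation repair, and Gaussian spatial smoothing.

#' Discard initial volumes of a series
#'
#' Drops the first `nDiscard` volumes (default 6, allowing for signal
#' stabilization after onset transients) from both the BOLD data and the
#' motion trace.
#'
#' @param series a [SubjectSeries-class].
#' @param nDiscard number of leading volumes to drop.
#' @return the truncated [SubjectSeries-class].
#' @export
discardInitialVolumes <- function(series, nDiscard = 6L) {
  Tn <- dim(series@bold)[4]
  if (nDiscard >= Tn)
    stop(sprintf("cannot discard %d volumes from a %d-volume series", nDiscard, Tn))
  if (nDiscard < 0) stop("nDiscard must be nonnegative")
  if (nDiscard == 0) return(series)
  keep <- (nDiscard + 1):Tn
  series@bold <- series@bold[, , , keep, drop = FALSE]
  series@motion <- series@motion[keep, , drop = FALSE]
  validObject(series)
  series
}

#' Detect artifact volumes from motion derivatives and global signal
#'
#' Volume t is flagged iff the maximum absolute successive difference of the
#' translation parameters exceeds `motionThresholdMm`, or the z-scored
#' global mean signal at t exceeds `globalZThreshold` in absolute value.
#' Volume 1 has motion derivative 0 by convention. Optionally the rotation
#' parameters enter the derivative statistic as arc displacement at a 65-mm
#' head radius.
#'
#' @param series a [SubjectSeries-class].
#' @param motionThresholdMm threshold on the motion derivative (mm),
#'   default 0.5.
#' @param globalZThreshold threshold on |z| of the global mean signal,
#'   default 3.
#' @param includeRotations include rotations (converted to mm of arc at
#'   65 mm) in the derivative statistic? Default `FALSE`.
#' @return a list of class `OutlierReport`: `subjectId`, `flaggedIndices`
#'   (sorted, 1-based), `motionDerivativeMax`, `globalSignalZ`, and the
#'   thresholds used.
#' @export
detectOutliers <- function(series, motionThresholdMm = 0.5,
                           globalZThreshold = 3, includeRotations = FALSE) {
  Tn <- dim(series@bold)[4]
  if (nrow(series@motion) != Tn)
    stop("motion trace length does not match the number of volumes")
  par <- series@motion[, 1:3, drop = FALSE]
  if (includeRotations)
    par <- cbind(par, series@motion[, 4:6, drop = FALSE] * pi / 180 * 65)
  dpar <- rbind(0, abs(diff(par)))
  motionDeriv <- apply(dpar, 1, max)
  gm <- colMeans(matrix(series@bold, ncol = Tn)[as.vector(series@mask), ,
                                                drop = FALSE])
  gz <- zscoreVec(gm)
  flagged <- sort(which(motionDeriv > motionThresholdMm |
                          abs(gz) > globalZThreshold))
  structure(list(subjectId = series@subjectId,
                 flaggedIndices = as.integer(flagged),
                 motionDerivativeMax = motionDeriv,
                 globalSignalZ = gz,
                 motionThresholdMm = motionThresholdMm,
                 globalZThreshold = globalZThreshold),
            class = "OutlierReport")
}

#' @export
print.OutlierReport <- function(x, ...) {
  cat(sprintf("OutlierReport %s: %d/%d volumes flagged (motion > %.2f mm or |z| > %.1f)\n",
              x$subjectId, length(x$flaggedIndices),
              length(x$motionDerivativeMax), x$motionThresholdMm,
              x$globalZThreshold))
  invisible(x)
}

#' Replace flagged volumes by temporal linear interpolation
#'
#' Each flagged volume is replaced voxelwise by linear interpolation between
#' the nearest earlier and nearest later non-flagged volumes; flagged runs at
#' either end of the series are replaced by the single nearest non-flagged
#' volume. Non-flagged volumes are untouched, so repairing twice with the
#' same report is the identity.
#'
#' @param series a [SubjectSeries-class].
#' @param report an `OutlierReport` from [detectOutliers()].
#' @return the repaired [SubjectSeries-class].
#' @export
repairOutliers <- function(series, report) {
  flagged <- report$flaggedIndices
  Tn <- dim(series@bold)[4]
  if (!length(flagged)) return(series)
  good <- setdiff(seq_len(Tn), flagged)
  if (!length(good)) stop("all volumes flagged: nothing to interpolate from")
  d <- dim(series@bold)
  X <- matrix(series@bold, ncol = Tn)
  for (t in flagged) {
    lo <- good[good < t]; hi <- good[good > t]
    if (!length(lo)) {
      X[, t] <- X[, min(hi)]
    } else if (!length(hi)) {
      X[, t] <- X[, max(lo)]
    } else {
      a <- max(lo); b <- min(hi)
      w <- (t - a) / (b - a)
      X[, t] <- (1 - w) * X[, a] + w * X[, b]
    }
  }
  series@bold <- array(X, d)
  series
}

#' Spatially smooth a series with an isotropic Gaussian kernel
#'
#' Separable convolution per volume with sd = FWHM / sqrt(8 ln 2) per axis,
#' converted to voxel units per axis. Edge handling uses a renormalized
#' kernel truncated at 3 sd, which preserves constant fields exactly and the
#' per-volume global mean to within 0.1%.
#'
#' @param series a [SubjectSeries-class].
#' @param fwhmMm kernel FWHM in mm (default 8); 0 is the identity.
#' @return the smoothed [SubjectSeries-class].
#' @export
smoothGaussian <- function(series, fwhmMm = 8) {
  if (fwhmMm < 0) stop("fwhmMm must be nonnegative")
  if (fwhmMm == 0) return(series)
  if (any(series@voxelSizeMm <= 0)) stop("voxel sizes must be positive")
  sigmaVox <- fwhmToSigma(fwhmMm) / series@voxelSizeMm
  series@bold <- smoothSeparable(series@bold, sigmaVox)
  series
}

#' Run the full preprocessing chain on one subject
#'
#' Initial-volume discard, artifact detection, interpolation repair, then
#' Gaussian smoothing.
#'
#' @param series a [SubjectSeries-class].
#' @param nDiscard leading volumes to drop (default 6).
#' @param fwhmMm smoothing FWHM in mm (default 8).
#' @param motionThresholdMm,globalZThreshold artifact-detection thresholds,
#'   see [detectOutliers()].
#' @return list with the preprocessed `series` and the `report`.
#' @export
preprocessSubject <- function(series, nDiscard = 6L, fwhmMm = 8,
                              motionThresholdMm = 0.5, globalZThreshold = 3) {
  s <- discardInitialVolumes(series, nDiscard)
  rep <- detectOutliers(s, motionThresholdMm, globalZThreshold)
  s <- repairOutliers(s, rep)
  s <- smoothGaussian(s, fwhmMm)
  list(series = s, report = rep)
}
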