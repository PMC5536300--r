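## Hierarchical Partner Matching: bidirectional Tanimoto matching of spatial
## components across participants within each model order (stage 1), then of
## the resulting cluster maps across model orders (stage 2), with Cronbach's
## alpha selecting the reproducible clusters.

#' Tanimoto similarity between two spatial maps
#'
#' Continuous mode computes \eqn{T = <a,b> / (<a,a> + <b,b> - <a,b>)} on the
#' maps clipped to nonnegative values (negative z set to 0). Binary mode is
#' intersection over union of the suprathreshold supports (z >=
#' `zThreshold`). Symmetric; 1 iff the clipped/thresholded maps are
#' identical; pairs that are empty after clipping get similarity 0 with a
#' warning.
#'
#' @param a,b numeric vectors on the same mask (equal length).
#' @param mode `"continuous"` (default) or `"binary"`.
#' @param zThreshold binarization threshold for binary mode (default 2).
#' @return similarity in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b, mode = c("continuous", "binary"),
                               zThreshold = 2) {
  mode <- match.arg(mode)
  if (length(a) != length(b))
    stop("maps live on different masks (lengths differ)")
  s <- tanimotoMatrix(matrix(a, 1), matrix(b, 1), mode, zThreshold)
  as.numeric(s)
}

#' Tanimoto distance between two spatial maps
#'
#' One minus [tanimotoSimilarity()].
#' @inheritParams tanimotoSimilarity
#' @export
tanimotoDistance <- function(a, b, mode = c("continuous", "binary"),
                             zThreshold = 2) {
  1 - tanimotoSimilarity(a, b, mode, zThreshold)
}

## All-pairs Tanimoto similarity between the rows of A and B.
tanimotoMatrix <- function(A, B, mode = "continuous", zThreshold = 2) {
  if (mode == "continuous") {
    A <- pmax(A, 0); B <- pmax(B, 0)
    cross <- tcrossprod(A, B)
    aa <- rowSums(A^2); bb <- rowSums(B^2)
  } else {
    A <- (A >= zThreshold) + 0; B <- (B >= zThreshold) + 0
    cross <- tcrossprod(A, B)
    aa <- rowSums(A); bb <- rowSums(B)
  }
  den <- outer(aa, bb, "+") - cross
  bad <- den <= 0
  if (any(bad)) {
    warning("map pair(s) empty after clipping/thresholding: similarity set to 0")
    den[bad] <- 1
    cross[bad] <- 0
  }
  S <- cross / den
  pmin(pmax(S, 0), 1)
}

#' Bidirectional best-match pairs between two component sets
#'
#' Component i of A pairs with component j of B iff j is i's most similar
#' component in B and i is j's most similar component in A (mutual best
#' match). Ties break to the lowest component index, deterministically.
#'
#' @param setA,setB [ICSet-class] objects, or numeric matrices with one map
#'   per row.
#' @param mode,zThreshold see [tanimotoSimilarity()].
#' @return data.frame with columns `a`, `b` (component indices) and
#'   `similarity`; zero rows when no pair is mutual.
#' @export
bidirectionalMatch <- function(setA, setB, mode = c("continuous", "binary"),
                               zThreshold = 2) {
  mode <- match.arg(mode)
  A <- if (is(setA, "ICSet")) icMaps(setA) else setA
  B <- if (is(setB, "ICSet")) icMaps(setB) else setB
  if (!nrow(A) || !nrow(B)) stop("both sets must be nonempty")
  S <- tanimotoMatrix(A, B, mode, zThreshold)
  bestB <- apply(S, 1, which.max)   # for each a, best b
  bestA <- apply(S, 2, which.max)   # for each b, best a
  ai <- which(bestA[bestB] == seq_len(nrow(A)))
  data.frame(a = ai, b = bestB[ai],
             similarity = S[cbind(ai, bestB[ai])])
}

#' Cronbach's alpha reliability of a set of maps
#'
#' Treats each map as an item and voxels as observations:
#' alpha = k/(k-1) * (1 - sum(var_i) / var_total), where var_total is the
#' variance over voxels of the summed maps. May be negative.
#'
#' @param maps numeric matrix, one item map per row (k >= 2 rows).
#' @return list with `alpha` and `k`.
#' @export
cronbachAlpha <- function(maps) {
  k <- nrow(maps)
  if (k < 2) stop("Cronbach's alpha needs at least 2 item maps")
  vi <- apply(maps, 1, stats::var)
  vt <- stats::var(colSums(maps))
  if (vt == 0) stop("zero total variance: alpha undefined")
  list(alpha = k / (k - 1) * (1 - sum(vi) / vt), k = k)
}

#' One-sample t map over a set of member maps
#'
#' Per voxel, t = mean / (sd / sqrt(k)) over the k member maps. Voxels with
#' zero variance and zero mean return t = 0; zero variance with nonzero mean
#' returns the cap value (sign of the mean) with the degenerate flag set.
#'
#' @param maps numeric matrix, one member map per row (k >= 3).
#' @param cap t value substituted at degenerate (zero-variance, nonzero-mean)
#'   voxels; default 1e6.
#' @return list with `t` (numeric vector) and `degenerate` (logical flag).
#' @export
oneSampleTMap <- function(maps, cap = 1e6) {
  k <- nrow(maps)
  if (k < 3) stop("one-sample t map needs at least 3 member maps")
  mu <- colMeans(maps)
  sd <- apply(maps, 2, stats::sd)
  t <- rep(0, length(mu))
  ok <- sd > 0
  t[ok] <- mu[ok] / (sd[ok] / sqrt(k))
  deg <- !ok & mu != 0
  t[deg] <- sign(mu[deg]) * cap
  list(t = t, degenerate = any(deg))
}

#' Stage-1 HPM: cluster matched components across subjects at one model order
#'
#' Builds a graph whose nodes are all subjects' components at this order and
#' whose edges are the bidirectional matches of every subject pair; clusters
#' are connected components containing components from at least
#' `minSubjectFraction` of subjects. When transitivity brings two components
#' of one subject into a cluster, the one with the higher mean similarity to
#' the other members is kept.
#'
#' @param icsets list of [ICSet-class] (>= 2 subjects), all at the same
#'   model order.
#' @param minSubjectFraction membership floor as a fraction of subjects
#'   (default 0.5).
#' @param mode,zThreshold see [tanimotoSimilarity()].
#' @return list of within-order clusters; each is a list with `members`
#'   (data.frame subject/order/component), `maps` (one member map per row),
#'   `matchMap` (the cluster's one-sample t map when it has >= 3 members,
#'   otherwise the mean map), `alpha`, and `tMap` (or NULL).
#' @export
formClustersWithinOrder <- function(icsets, minSubjectFraction = 0.5,
                                    mode = c("continuous", "binary"),
                                    zThreshold = 2) {
  mode <- match.arg(mode)
  nSub <- length(icsets)
  if (nSub < 2) stop("within-order matching needs at least 2 subjects")
  ids <- vapply(icsets, subjectId, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  ord <- modelOrder(icsets[[1]])
  nodeName <- function(s, c) paste0(s, "|", c)
  allNodes <- unlist(lapply(icsets, function(x)
    nodeName(subjectId(x), seq_len(modelOrder(x)))))
  edges <- list()
  for (i in seq_len(nSub - 1)) {
    for (j in (i + 1):nSub) {
      m <- bidirectionalMatch(icsets[[i]], icsets[[j]], mode, zThreshold)
      if (nrow(m))
        edges[[length(edges) + 1]] <- data.frame(
          from = nodeName(ids[i], m$a), to = nodeName(ids[j], m$b))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = allNodes)
  comp <- igraph::components(g)
  mapsBySubject <- stats::setNames(lapply(icsets, icMaps), ids)
  out <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    if (length(nodes) < 2) next
    parts <- do.call(rbind, strsplit(nodes, "|", fixed = TRUE))
    mem <- data.frame(subject = parts[, 1], order = ord,
                      component = as.integer(parts[, 2]))
    if (length(unique(mem$subject)) < minSubjectFraction * nSub) next
    maps <- do.call(rbind, lapply(seq_len(nrow(mem)), function(r)
      mapsBySubject[[mem$subject[r]]][mem$component[r], , drop = FALSE]))
    ## one member per subject: highest mean similarity to other members wins
    if (anyDuplicated(mem$subject)) {
      S <- tanimotoMatrix(maps, maps, mode, zThreshold)
      diag(S) <- NA
      meanSim <- rowMeans(S, na.rm = TRUE)
      keep <- unlist(lapply(split(seq_len(nrow(mem)), mem$subject),
                            function(rr) rr[which.max(meanSim[rr])]))
      keep <- sort(keep)
      mem <- mem[keep, , drop = FALSE]
      maps <- maps[keep, , drop = FALSE]
    }
    rownames(mem) <- NULL
    alpha <- tryCatch(cronbachAlpha(maps)$alpha, error = function(e) NA_real_)
    tm <- if (nrow(maps) >= 3) oneSampleTMap(maps) else NULL
    out[[length(out) + 1]] <- list(
      members = mem, maps = maps,
      matchMap = if (is.null(tm)) colMeans(maps) else tm$t,
      alpha = alpha, tMap = if (is.null(tm)) NULL else tm$t)
  }
  if (!length(out))
    warning("no cluster reached the subject-membership floor")
  out
}

#' Stage-2 HPM: match cluster maps across model orders
#'
#' Applies bidirectional matching to the stage-1 cluster maps across every
#' pair of model orders, takes connected components of the resulting
#' order-level graph, and retains components present in at least
#' `minOrdersFraction` of the orders with Cronbach's alpha (over the member
#' cluster maps) at least `alphaThreshold`. Each retained component becomes a
#' [ReproducibleCluster-class]: per-subject representative z-map = the mean
#' of that subject's member components pooled across orders; the final t map
#' is recomputed from the subject representatives.
#'
#' @param perOrderClusters named list (one element per model order) of
#'   stage-1 cluster lists from [formClustersWithinOrder()].
#' @param alphaThreshold reliability floor (default 0.7).
#' @param minOrdersFraction order-presence floor (default 0.5).
#' @param mode,zThreshold see [tanimotoSimilarity()].
#' @return list of [ReproducibleCluster-class]; empty (with a warning) when
#'   nothing is retained.
#' @export
matchAcrossOrders <- function(perOrderClusters, alphaThreshold = 0.7,
                              minOrdersFraction = 0.5,
                              mode = c("continuous", "binary"),
                              zThreshold = 2) {
  mode <- match.arg(mode)
  perOrderClusters <- perOrderClusters[
    vapply(perOrderClusters, length, integer(1)) > 0]
  nOrd <- length(perOrderClusters)
  if (nOrd < 2) stop("cross-order matching needs clusters from >= 2 orders")
  ordNames <- names(perOrderClusters)
  nodeName <- function(o, c) paste0(o, "|", c)
  stack <- lapply(perOrderClusters, function(cl)
    do.call(rbind, lapply(cl, `[[`, "matchMap")))
  allNodes <- unlist(lapply(ordNames, function(o)
    nodeName(o, seq_along(perOrderClusters[[o]]))))
  edges <- list()
  for (i in seq_len(nOrd - 1)) {
    for (j in (i + 1):nOrd) {
      m <- bidirectionalMatch(stack[[i]], stack[[j]], mode, zThreshold)
      if (nrow(m))
        edges[[length(edges) + 1]] <- data.frame(
          from = nodeName(ordNames[i], m$a), to = nodeName(ordNames[j], m$b))
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = allNodes)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    parts <- do.call(rbind, strsplit(nodes, "|", fixed = TRUE))
    if (length(unique(parts[, 1])) < minOrdersFraction * nOrd) next
    memberClusters <- lapply(seq_len(nrow(parts)), function(r)
      perOrderClusters[[parts[r, 1]]][[as.integer(parts[r, 2])]])
    matchMaps <- do.call(rbind, lapply(memberClusters, `[[`, "matchMap"))
    alpha <- if (nrow(matchMaps) >= 2)
      tryCatch(cronbachAlpha(matchMaps)$alpha, error = function(e) NA_real_)
    else NA_real_
    if (is.na(alpha) || alpha < alphaThreshold) next
    members <- do.call(rbind, lapply(memberClusters, `[[`, "members"))
    maps <- do.call(rbind, lapply(memberClusters, `[[`, "maps"))
    bySubj <- split(seq_len(nrow(members)), members$subject)
    reps <- do.call(rbind, lapply(bySubj, function(rr)
      colMeans(maps[rr, , drop = FALSE])))
    rownames(reps) <- names(bySubj)
    tm <- if (nrow(reps) >= 3) oneSampleTMap(reps) else
      list(t = colMeans(reps), degenerate = FALSE)
    rownames(members) <- NULL
    out[[length(out) + 1]] <- new("ReproducibleCluster",
      clusterId = sprintf("cluster%02d", length(out) + 1),
      members = members, alpha = alpha, tMap = tm$t,
      degenerateT = tm$degenerate, representatives = reps)
  }
  if (!length(out))
    warning("no cluster passed the order-presence and alpha thresholds")
  out
}

#' Run both HPM stages over a cohort's ICA results
#'
#' @param icaResults list over subjects of named lists over model orders of
#'   [ICSet-class] (the shape returned by [runSubjectICA()] collected over
#'   subjects).
#' @param minSubjectFraction stage-1 membership floor (default 0.5).
#' @param alphaThreshold stage-2 reliability floor (default 0.7).
#' @param minOrdersFraction stage-2 order-presence floor (default 0.5).
#' @param mode,zThreshold see [tanimotoSimilarity()].
#' @return list of [ReproducibleCluster-class].
#' @export
runHPM <- function(icaResults, minSubjectFraction = 0.5,
                   alphaThreshold = 0.7, minOrdersFraction = 0.5,
                   mode = c("continuous", "binary"), zThreshold = 2) {
  mode <- match.arg(mode)
  orders <- names(icaResults[[1]])
  perOrder <- lapply(orders, function(o) {
    sets <- lapply(icaResults, `[[`, o)
    suppressWarnings(
      formClustersWithinOrder(sets, minSubjectFraction, mode, zThreshold))
  })
  names(perOrder) <- orders
  matchAcrossOrders(perOrder, alphaThreshold, minOrdersFraction, mode,
                    zThreshold)
}
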