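## Granger causality between reproducible-cluster time courses: direct
## indices, mediated (conditioning-drop) indices through a named cluster,
## VAR order selection, and nonparametric group comparisons.

## Build the lagged regressor matrix for series in the columns of Z.
lagMatrix <- function(Z, p) {
  Z <- as.matrix(Z)
  Tn <- nrow(Z)
  out <- do.call(cbind, lapply(seq_len(p), function(l)
    Z[(p - l + 1):(Tn - l), , drop = FALSE]))
  out
}

## Residual sum of squares of y on an intercept plus the given regressors.
rssFit <- function(y, X) {
  X <- cbind(1, X)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    stop("singular regression (constant or collinear series)")
  sum(fit$residuals^2)
}

#' Granger causality index from x to y
#'
#' Fits the restricted model (y on p of its own lags) and the full model
#' (adding p lags of x) by least squares; the index is
#' \eqn{ln(RSS_{restricted} / RSS_{full})}, nonnegative by nesting.
#' Invariant to rescaling either series.
#'
#' @param x candidate cause series.
#' @param y target series.
#' @param p VAR lag order (series length must exceed 10 p).
#' @return nonnegative GCI.
#' @examples
#' set.seed(1)
#' x <- rnorm(2000); y <- 0.8 * c(0, x[-2000]) + rnorm(2000)
#' gci(x, y, 1)  # near ln(1.64)
#' @export
gci <- function(x, y, p = 1L) {
  if (p < 1) stop("p must be >= 1")
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(y) <= 10 * p) stop("series too short for the requested order")
  yT <- y[(p + 1):length(y)]
  Ly <- lagMatrix(cbind(y), p)
  Lx <- lagMatrix(cbind(x), p)
  max(0, log(rssFit(yT, Ly) / rssFit(yT, cbind(Ly, Lx))))
}

#' Mediated Granger causality index from x to y through m
#'
#' The conditioning drop max(0, GCI(x -> y) - GCI(x -> y | m)), where the
#' conditional index adds p lags of the mediator to both the restricted and
#' the full model. Large when x's influence on y is carried by m; near zero
#' when the influence is direct. The alternative path-product definition
#' min(GCI(x -> m), GCI(m -> y)) is available via `method`.
#'
#' @param x candidate cause series.
#' @param y target series.
#' @param m mediator series (distinct from x and y).
#' @param p VAR lag order.
#' @param method `"conditioning"` (default) or `"path"`.
#' @return nonnegative mediated index.
#' @export
gciVia <- function(x, y, m, p = 1L, method = c("conditioning", "path")) {
  method <- match.arg(method)
  if (identical(m, x) || identical(m, y))
    stop("mediator must differ from source and target")
  if (method == "path")
    return(min(gci(x, m, p), gci(m, y, p)))
  max(0, gci(x, y, p) - gciConditional(x, y, m, p))
}

#' Conditional Granger causality index from x to y given m
#'
#' GCI with p lags of m included in both the restricted and full models.
#'
#' @inheritParams gciVia
#' @return nonnegative conditional GCI.
#' @export
gciConditional <- function(x, y, m, p = 1L) {
  if (p < 1) stop("p must be >= 1")
  if (length(y) <= 10 * p) stop("series too short for the requested order")
  yT <- y[(p + 1):length(y)]
  Lym <- lagMatrix(cbind(y, m), p)
  Lx <- lagMatrix(cbind(x), p)
  max(0, log(rssFit(yT, Lym) / rssFit(yT, cbind(Lym, Lx))))
}

#' Select a VAR order by information criterion
#'
#' Fits a joint VAR over the supplied series at each order 1..maxP on the
#' common sample and returns the order minimizing BIC (or AIC) of the
#' multivariate fit; ties break to the smallest order.
#'
#' @param timecourses T x K matrix of series (columns).
#' @param maxP largest order considered.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return the selected integer order.
#' @export
selectVAROrder <- function(timecourses, maxP = 3L, criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  Z <- as.matrix(timecourses)
  Tn <- nrow(Z); K <- ncol(Z)
  if (maxP < 1) stop("maxP must be >= 1")
  if (Tn <= 10 * maxP + K) stop("series too short for the requested maxP")
  Teff <- Tn - maxP
  ic <- vapply(seq_len(maxP), function(p) {
    Y <- Z[(maxP + 1):Tn, , drop = FALSE]
    X <- cbind(1, do.call(cbind, lapply(seq_len(p), function(l)
      Z[(maxP + 1 - l):(Tn - l), , drop = FALSE])))
    B <- qr.solve(X, Y)
    E <- Y - X %*% B
    Sig <- crossprod(E) / Teff
    npar <- K * (1 + K * p)
    ld <- determinant(Sig, logarithm = TRUE)$modulus
    pen <- if (criterion == "BIC") log(Teff) else 2
    as.numeric(ld) + pen * npar / Teff
  }, numeric(1))
  which.min(ic)  # which.min takes the first (smallest order) on ties
}

#' Extract a subject's representative time course for a cluster
#'
#' The standardized time course of the subject's member component; when a
#' subject contributed several member components (pooled across model
#' orders), the first principal component of their time courses,
#' sign-aligned to their mean.
#'
#' @param cluster a [ReproducibleCluster-class].
#' @param icaResults the per-subject per-order ICA results (as passed to
#'   [runHPM()]).
#' @param subject subject id.
#' @return standardized numeric time course, or `NULL` when the subject has
#'   no member in the cluster.
#' @export
subjectTimecourse <- function(cluster, icaResults, subject) {
  mem <- cluster@members
  mem <- mem[mem$subject == subject, , drop = FALSE]
  if (!nrow(mem)) return(NULL)
  bySubject <- stats::setNames(icaResults,
    vapply(icaResults, function(l) subjectId(l[[1]]), character(1)))
  tcs <- vapply(seq_len(nrow(mem)), function(r) {
    set <- bySubject[[subject]][[as.character(mem$order[r])]]
    set@timecourses[, mem$component[r]]
  }, numeric(nrow(bySubject[[subject]][[1]]@timecourses)))
  if (ncol(tcs) == 1) return(zscoreVec(tcs[, 1]))
  tcsS <- apply(tcs, 2, zscoreVec)
  pc1 <- stats::prcomp(tcsS, center = FALSE, scale. = FALSE)$x[, 1]
  if (stats::cor(pc1, rowMeans(tcsS)) < 0) pc1 <- -pc1
  zscoreVec(pc1)
}

#' Per-subject Granger causality indices for cluster pairs
#'
#' Computes the direct GCI for every ordered pair of the named clusters and,
#' when `mediator` is given, the mediated index through it for every ordered
#' pair of the remaining clusters.
#'
#' @param clusters named list of [ReproducibleCluster-class].
#' @param icaResults per-subject per-order ICA results (see [runHPM()]).
#' @param subjects character vector of subject ids.
#' @param p VAR lag order (e.g. from [selectVAROrder()]).
#' @param mediator optional name of the mediating cluster.
#' @return data.frame with columns `subject`, `source`, `target`,
#'   `mediator` (NA for direct), `p`, `gci`; subjects missing a time course
#'   for an edge get NA.
#' @export
computeGCITable <- function(clusters, icaResults, subjects, p = 1L,
                            mediator = NULL) {
  nm <- names(clusters)
  if (is.null(nm)) stop("clusters must be a named list")
  rows <- list()
  for (sub in subjects) {
    tc <- lapply(clusters, subjectTimecourse, icaResults = icaResults,
                 subject = sub)
    direct <- expand.grid(source = nm, target = nm,
                          stringsAsFactors = FALSE)
    direct <- direct[direct$source != direct$target, , drop = FALSE]
    for (r in seq_len(nrow(direct))) {
      s <- direct$source[r]; tg <- direct$target[r]
      val <- if (is.null(tc[[s]]) || is.null(tc[[tg]])) NA_real_ else
        gci(tc[[s]], tc[[tg]], p)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sub, source = s, target = tg, mediator = NA_character_,
        p = p, gci = val)
    }
    if (!is.null(mediator)) {
      others <- setdiff(nm, mediator)
      med <- expand.grid(source = others, target = others,
                         stringsAsFactors = FALSE)
      med <- med[med$source != med$target, , drop = FALSE]
      for (r in seq_len(nrow(med))) {
        s <- med$source[r]; tg <- med$target[r]
        val <- if (is.null(tc[[s]]) || is.null(tc[[tg]]) ||
                   is.null(tc[[mediator]])) NA_real_ else
          gciVia(tc[[s]], tc[[tg]], tc[[mediator]], p)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sub, source = s, target = tg, mediator = mediator,
          p = p, gci = val)
      }
    }
  }
  do.call(rbind, rows)
}

## Wilcoxon rank-sum z (normal approximation with tie correction) and
## two-sided p; exact enumeration p when both groups are small and untied.
rankSumTest <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tieCorr)
  z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  hasTies <- any(ties > 1)
  if (!hasTies && n1 <= 20 && n2 <= 20) {
    U <- W - n1 * (n1 + 1) / 2
    pLo <- stats::pwilcox(U, n1, n2)
    pHi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pLo, pHi))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p)
}

#' Group comparison of Granger causality indices for one edge
#'
#' Per group: median, interquartile range, and Wilcoxon signed-rank p
#' against zero. Across groups: Wilcoxon rank-sum z (normal approximation
#' with tie correction; exact two-sided p for small untied samples), with
#' positive z when the first-named group is larger. A two-sample Welch t is
#' available via `test = "t"`. Subjects with missing values are excluded
#' listwise.
#'
#' @param values per-subject GCI values for one edge.
#' @param groups group label per subject (`"patient"` / `"control"`);
#'   `"patient"` is the first-named group.
#' @param test `"ranksum"` (default) or `"t"`.
#' @return list: `n` (per group), `median`, `iqr` (2 x 2 matrix of
#'   quartiles), `signedRankP` (per group), `z`, `p`, `test`.
#' @export
gciGroupCompare <- function(values, groups, test = c("ranksum", "t")) {
  test <- match.arg(test)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  g1 <- values[groups == "patient"]; g2 <- values[groups == "control"]
  if (length(g1) < 5 || length(g2) < 5)
    stop("need at least 5 non-missing subjects per group")
  sr <- function(v) {
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
  }
  if (test == "ranksum") {
    rs <- rankSumTest(g1, g2)
  } else {
    tt <- stats::t.test(g1, g2)
    rs <- list(z = unname(tt$statistic), p = tt$p.value)
  }
  list(n = c(patient = length(g1), control = length(g2)),
       median = c(patient = stats::median(g1), control = stats::median(g2)),
       iqr = rbind(patient = stats::quantile(g1, c(0.25, 0.75)),
                   control = stats::quantile(g2, c(0.25, 0.75))),
       signedRankP = c(patient = sr(g1), control = sr(g2)),
       z = rs$z, p = rs$p, test = test)
}

#' Tabulate group comparisons over all edges of a GCI table
#'
#' @param gciTable output of [computeGCITable()].
#' @param groups named character vector mapping subject id to group.
#' @param test see [gciGroupCompare()].
#' @return data.frame with one row per edge: source, target, mediator,
#'   per-group median and IQR, signed-rank p values, z, p.
#' @export
gciGroupTable <- function(gciTable, groups, test = c("ranksum", "t")) {
  test <- match.arg(test)
  key <- paste(gciTable$source, gciTable$target, gciTable$mediator,
               sep = "\r")
  rows <- lapply(split(gciTable, key), function(d) {
    cmp <- tryCatch(
      gciGroupCompare(d$gci, groups[d$subject], test),
      error = function(e) NULL)
    if (is.null(cmp)) return(NULL)
    data.frame(source = d$source[1], target = d$target[1],
               mediator = d$mediator[1],
               patientMedian = cmp$median["patient"],
               patientQ1 = cmp$iqr["patient", 1],
               patientQ3 = cmp$iqr["patient", 2],
               controlMedian = cmp$median["control"],
               controlQ1 = cmp$iqr["control", 1],
               controlQ3 = cmp$iqr["control", 2],
               patientSignedRankP = cmp$signedRankP["patient"],
               controlSignedRankP = cmp$signedRankP["control"],
               z = cmp$z, p = cmp$p)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
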