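## Classification of diagnostic groups from regional connectivity and GCI
## features: Gaussian-kernel SVM under LOO / stratified k-fold CV, maximum
## uncertainty LDA with hyperplane feature contributions, and repeated-LOO
## evaluation of feature subsets. Feature standardization and imputation are
## computed inside each training fold (no test-set leakage).

#' Build a subject-by-feature matrix from significant clusters and edges
#'
#' Regional features are the subject's mean representative z over a
#' cluster's surviving voxels; edge features are the subject's GCIs.
#' Constant features are dropped with a warning; subjects missing every
#' feature are excluded with a warning. Missing entries remain NA and are
#' imputed with training-fold medians during cross-validation.
#'
#' @param clusters named list of [ReproducibleCluster-class] that showed a
#'   significant group difference.
#' @param survivingVoxels named list (same names) of mask-voxel index
#'   vectors, e.g. from [thresholdClusters()].
#' @param gciTable rows of a [computeGCITable()] result restricted to the
#'   significant edges (may be NULL).
#' @param subjects ordered character vector of subject ids.
#' @param groups named character vector mapping subject id to group.
#' @return object of class `FeatureMatrix`: list with `subjects`, `labels`
#'   (factor patient/control), `features` (subjects x d matrix, NAs
#'   allowed), `featureNames`.
#' @export
buildFeatures <- function(clusters, survivingVoxels, gciTable, subjects,
                          groups) {
  cols <- list()
  for (nm in names(clusters)) {
    v <- survivingVoxels[[nm]]
    if (is.null(v) || !length(v)) next
    reps <- clusterRepresentatives(clusters[[nm]])
    cols[[paste0("z:", nm)]] <- vapply(subjects, function(s)
      if (s %in% rownames(reps)) mean(reps[s, v]) else NA_real_, numeric(1))
  }
  if (!is.null(gciTable) && nrow(gciTable)) {
    key <- ifelse(is.na(gciTable$mediator),
                  paste0("gci:", gciTable$source, "->", gciTable$target),
                  paste0("gci:", gciTable$source, "->", gciTable$target,
                         "|", gciTable$mediator))
    for (k in unique(key)) {
      d <- gciTable[key == k, , drop = FALSE]
      cols[[k]] <- vapply(subjects, function(s) {
        r <- d$gci[d$subject == s]
        if (length(r)) r[1] else NA_real_
      }, numeric(1))
    }
  }
  if (!length(cols)) stop("no features: need at least one cluster or edge")
  F <- do.call(cbind, cols)
  keep <- apply(F, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(colnames(F)[!keep], collapse = ", "))
  F <- F[, keep, drop = FALSE]
  subjOk <- rowSums(!is.na(F)) > 0
  if (any(!subjOk))
    warning("excluding subject(s) with no observed features: ",
            paste(subjects[!subjOk], collapse = ", "))
  F <- F[subjOk, , drop = FALSE]
  subjects <- subjects[subjOk]
  structure(list(subjects = subjects,
                 labels = factor(groups[subjects],
                                 levels = c("patient", "control")),
                 features = F, featureNames = colnames(F)),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d subjects x %d features (%d patient / %d control)\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == "patient"), sum(x$labels == "control")))
  invisible(x)
}

## Training-fold preprocessing: median imputation then standardization, with
## statistics from the training rows only. Optional jitter (sd in
## standardized units) perturbs imputed entries, giving repeated-LOO trials
## their stochastic element.
foldTransform <- function(train, test, impJitterSd = 0, jitterSeed = NULL) {
  med <- apply(train, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  fill <- function(M) {
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- med[j]
    M
  }
  trNA <- is.na(train); teNA <- is.na(test)
  train <- fill(train); test <- fill(test)
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  std <- function(M) sweep(sweep(M, 2, mu), 2, sd, "/")
  train <- std(train); test <- std(test)
  if (impJitterSd > 0 && !is.null(jitterSeed)) {
    withSeed(jitterSeed, {
      train[trNA] <- train[trNA] + stats::rnorm(sum(trNA), sd = impJitterSd)
      test[teNA] <- test[teNA] + stats::rnorm(sum(teNA), sd = impJitterSd)
    })
  }
  list(train = train, test = test)
}

## Stratified fold assignment, seeded.
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

## Generic cross-validation driver; trainPredict(trainX, trainY, testX) must
## return a factor/character of predicted labels.
crossvalRun <- function(features, labels, folds, trainPredict,
                        impJitterSd = 0, jitterSeed = NULL) {
  pred <- rep(NA_character_, length(labels))
  for (f in sort(unique(folds))) {
    te <- folds == f
    ft <- foldTransform(features[!te, , drop = FALSE],
                        features[te, , drop = FALSE],
                        impJitterSd,
                        if (is.null(jitterSeed)) NULL else
                          deriveSeed(jitterSeed, f))
    pred[te] <- as.character(trainPredict(ft$train, labels[!te], ft$test))
  }
  acc <- mean(pred == as.character(labels))
  isPat <- labels == "patient"
  list(accuracy = acc,
       sensitivity = if (any(isPat)) mean(pred[isPat] == "patient") else NA,
       specificity = if (any(!isPat)) mean(pred[!isPat] == "control") else NA,
       predictions = pred)
}

#' Gaussian-kernel SVM with cross-validation
#'
#' Soft-margin SVM with kernel \eqn{K(u, v) = exp(-||u - v||^2 / (2 w^2))},
#' w = `kernelWidth`, evaluated under leave-one-out or stratified k-fold
#' cross-validation. Per fold, features are median-imputed and standardized
#' on the training subjects only. The gamma-style reading of the width
#' (gamma = `kernelWidth` directly) is available via `widthIsGamma`.
#'
#' @param fm a `FeatureMatrix` from [buildFeatures()], or a plain numeric
#'   matrix (then `labels` is required).
#' @param labels factor with levels patient/control (ignored when `fm` is a
#'   `FeatureMatrix`).
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k folds for `"kfold"` (default 5, stratified).
#' @param kernelWidth Gaussian kernel width (default 0.5).
#' @param cost soft-margin cost (default 1).
#' @param seed seed for the k-fold split.
#' @param widthIsGamma treat `kernelWidth` as gamma instead of a length
#'   scale? Default FALSE.
#' @param impJitterSd sd of jitter on imputed entries (0 = none).
#' @param jitterSeed seed for the jitter stream.
#' @return object of class `ClassificationReport`: list with `scheme`,
#'   `accuracy`, `sensitivity`, `specificity`, `predictions`, `nTrials`.
#' @export
svmCrossval <- function(fm, labels = NULL, scheme = c("loo", "kfold"),
                        k = 5L, kernelWidth = 0.5, cost = 1, seed = 1L,
                        widthIsGamma = FALSE, impJitterSd = 0,
                        jitterSeed = NULL) {
  scheme <- match.arg(scheme)
  X <- if (inherits(fm, "FeatureMatrix")) fm$features else as.matrix(fm)
  y <- if (inherits(fm, "FeatureMatrix")) fm$labels else
    factor(labels, levels = c("patient", "control"))
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 subjects in each of two classes")
  gamma <- if (widthIsGamma) kernelWidth else 1 / (2 * kernelWidth^2)
  folds <- if (scheme == "loo") seq_along(y) else
    stratifiedFolds(y, k, seed)
  tp <- function(trX, trY, teX) {
    fit <- e1071::svm(trX, droplevels(trY), kernel = "radial", gamma = gamma,
                      cost = cost, scale = FALSE)
    as.character(predict(fit, teX))
  }
  res <- crossvalRun(X, y, folds, tp, impJitterSd, jitterSeed)
  structure(c(list(scheme = paste0("svm_", scheme), nTrials = 1L), res),
            class = "ClassificationReport")
}

## Maximum-uncertainty regularized discriminant direction: eigenvalues of
## the pooled within-class covariance below the eigenvalue mean are replaced
## by the mean, making the inverse well-defined even when d > n.
mldaDirection <- function(X, y) {
  mu1 <- colMeans(X[y == "patient", , drop = FALSE])
  mu2 <- colMeans(X[y == "control", , drop = FALSE])
  Sw <- matrix(0, ncol(X), ncol(X))
  for (lv in c("patient", "control")) {
    Xi <- X[y == lv, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / (nrow(X) - 2)
  eg <- eigen(Sw, symmetric = TRUE)
  lam <- eg$values
  lam <- pmax(lam, mean(lam))
  w <- eg$vectors %*% ((crossprod(eg$vectors, mu1 - mu2)) / lam)
  list(w = as.numeric(w), mu1 = mu1, mu2 = mu2)
}

#' Maximum uncertainty LDA with leave-one-out cross-validation
#'
#' The pooled within-class covariance is eigendecomposed and eigenvalues
#' below the eigenvalue mean are replaced by the mean; the discriminant
#' direction is the regularized-inverse times the mean difference, and
#' subjects are assigned to the nearest class mean along it (midpoint
#' threshold). Per-feature contributions are the absolute hyperplane
#' coefficients of the full-sample fit, scaled by the largest.
#'
#' @inheritParams svmCrossval
#' @return a `ClassificationReport` with `contributions` (named, in [0, 1]).
#' @export
mldaFitLOO <- function(fm, labels = NULL) {
  X <- if (inherits(fm, "FeatureMatrix")) fm$features else as.matrix(fm)
  y <- if (inherits(fm, "FeatureMatrix")) fm$labels else
    factor(labels, levels = c("patient", "control"))
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  tp <- function(trX, trY, teX) {
    d <- mldaDirection(trX, as.character(trY))
    score <- as.numeric(sweep(teX, 2, (d$mu1 + d$mu2) / 2) %*% d$w)
    ifelse(score > 0, "patient", "control")
  }
  res <- crossvalRun(X, y, seq_along(y), tp)
  full <- foldTransform(X, X)$train
  w <- mldaDirection(full, as.character(y))$w
  contrib <- abs(w) / max(abs(w))
  names(contrib) <- colnames(X)
  structure(c(list(scheme = "mlda_loo", nTrials = 1L,
                   contributions = contrib), res),
            class = "ClassificationReport")
}

#' Repeated leave-one-out evaluation of a feature subset
#'
#' Runs `nTrials` repetitions of LOO cross-validation on the named feature
#' subset; each trial has its own stochastic elements (jitter on imputed
#' entries and a trial-specific solver seed). With complete data and a
#' deterministic solver all trials coincide and the across-trial sd is 0.
#'
#' @param fm a `FeatureMatrix`.
#' @param subset character vector of feature names to keep.
#' @param nTrials number of repetitions (default 1000).
#' @param seed master seed.
#' @param kernelWidth,cost SVM parameters.
#' @param impJitterSd sd of jitter applied to imputed entries per trial
#'   (default 0.05).
#' @return a `ClassificationReport` with `accuracy` (mean over trials),
#'   `accuracySd`, `nTrials`.
#' @export
repeatedLOO <- function(fm, subset, nTrials = 1000L, seed = 1L,
                        kernelWidth = 0.5, cost = 1, impJitterSd = 0.05) {
  if (!length(subset)) stop("feature subset must be nonempty")
  miss <- setdiff(subset, fm$featureNames)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  sub <- fm
  sub$features <- fm$features[, subset, drop = FALSE]
  sub$featureNames <- subset
  accs <- vapply(seq_len(nTrials), function(tr) {
    svmCrossval(sub, scheme = "loo", kernelWidth = kernelWidth, cost = cost,
                impJitterSd = impJitterSd,
                jitterSeed = deriveSeed(seed, 17L, tr))$accuracy
  }, numeric(1))
  structure(list(scheme = "repeated_loo", nTrials = as.integer(nTrials),
                 accuracy = mean(accs), accuracySd = stats::sd(accs),
                 sensitivity = NA, specificity = NA),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport [%s]: accuracy %.3f", x$scheme,
              x$accuracy))
  if (!is.null(x$accuracySd) && is.finite(x$accuracySd))
    cat(sprintf(" (sd %.3f over %d trials)", x$accuracySd, x$nTrials))
  if (!is.na(x$sensitivity))
    cat(sprintf(", sensitivity %.3f, specificity %.3f", x$sensitivity,
                x$specificity))
  cat("\n")
  if (!is.null(x$contributions)) {
    cat("  contributions:",
        paste(sprintf("%s=%.3f", names(x$contributions), x$contributions),
              collapse = ", "), "\n")
  }
  invisible(x)
}
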