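## Pipeline orchestration: one validated config drives cohort synthesis,
## preprocessing, ICA, HPM, group statistics, Granger causality, and
## classification, with seeds derived per stage from one master seed and a
## JSON manifest describing the run.

pipelineDefaults <- function() {
  list(
    seed = 20L,
    outDir = NULL,
    stages = c("cohort", "preprocess", "ica", "hpm", "groupStats", "gc",
               "classify"),
    cohort = list(gridDims = c(16L, 16L, 12L), voxelSizeMm = c(3.75, 3.75, 3.5),
                  nVolumes = 146L, trSeconds = 2.2, nPerGroup = c(20L, 20L),
                  nSources = 4L, sourceFwhmMm = 12, subjectJitterMm = 1.5,
                  noiseSd = 2.0, severityTargetR = -0.30, severitySource = 1L,
                  outlierRate = 0.03),
    preprocess = list(nDiscard = 6L, fwhmMm = 8, motionThresholdMm = 0.5,
                      globalZThreshold = 3),
    ica = list(orders = "20:130:10", maxIter = 500L, tol = 1e-4),
    hpm = list(minSubjectFraction = 0.5, alphaThreshold = 0.7,
               minOrdersFraction = 0.5, mode = "continuous", zThreshold = 2),
    groupStats = list(voxelP = 0.01, extentThreshold = "auto", fwer = 0.05,
                      mcIterations = 1000L),
    gc = list(maxP = 3L, mediator = NULL, test = "ranksum"),
    classify = list(kernelWidth = 0.5, kfold = 5L, nTrials = 1000L)
  )
}

checkRange <- function(value, key, lo = -Inf, hi = Inf) {
  if (!is.numeric(value) || any(value < lo) || any(value > hi))
    stop(sprintf("config key '%s' out of range: expected [%s, %s], got %s",
                 key, lo, hi, paste(value, collapse = ",")))
  value
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a nested list; merges it over the
#' defaults (which follow the published full-scale analysis: discard 6,
#' FWHM 8 mm, orders 20 to 130 step 10, voxel p 0.01, kernel width 0.5,
#' 5-fold, 1000 trials), rejects unknown keys, range-checks every parameter,
#' and resolves `orders` strings of the form `"lower:upper:step"`.
#'
#' @param raw config source (NULL = all defaults).
#' @return a validated config list of class `PipelineConfig` with resolved
#'   defaults.
#' @export
validateConfig <- function(raw = NULL) {
  user <- if (is.null(raw)) list()
  else if (is.list(raw)) raw
  else if (file.exists(raw)) yaml::read_yaml(raw)
  else yaml::yaml.load(raw)
  if (is.null(user)) user <- list()
  cfg <- pipelineDefaults()
  unknownTop <- setdiff(names(user), names(cfg))
  if (length(unknownTop))
    stop("unknown config key(s): ", paste(unknownTop, collapse = ", "))
  for (top in names(user)) {
    if (is.list(cfg[[top]]) && !is.null(names(cfg[[top]]))) {
      unknown <- setdiff(names(user[[top]]), names(cfg[[top]]))
      if (length(unknown))
        stop(sprintf("unknown config key(s) under '%s': %s", top,
                     paste(unknown, collapse = ", ")))
      cfg[[top]][names(user[[top]])] <- user[[top]]
    } else {
      cfg[[top]] <- user[[top]]
    }
  }
  if (is.character(cfg$ica$orders)) {
    parts <- as.integer(strsplit(cfg$ica$orders, ":")[[1]])
    if (length(parts) != 3 || anyNA(parts))
      stop("config key 'ica.orders' must be a vector or 'lower:upper:step'")
    cfg$ica$orders <- enumerateModelOrders(parts[1], parts[2], parts[3])
  }
  cfg$ica$orders <- as.integer(cfg$ica$orders)
  checkRange(cfg$groupStats$voxelP, "groupStats.voxelP", 0, 1)
  checkRange(cfg$groupStats$fwer, "groupStats.fwer", 0, 1)
  checkRange(cfg$hpm$alphaThreshold, "hpm.alphaThreshold", -Inf, 1.01)
  checkRange(cfg$hpm$minSubjectFraction, "hpm.minSubjectFraction", 0, 1)
  checkRange(cfg$hpm$minOrdersFraction, "hpm.minOrdersFraction", 0, 1)
  checkRange(cfg$preprocess$nDiscard, "preprocess.nDiscard", 0, Inf)
  checkRange(cfg$preprocess$fwhmMm, "preprocess.fwhmMm", 0, Inf)
  checkRange(cfg$cohort$noiseSd, "cohort.noiseSd", 0, Inf)
  checkRange(cfg$cohort$outlierRate, "cohort.outlierRate", 0, 1 - 1e-12)
  checkRange(cfg$cohort$severityTargetR, "cohort.severityTargetR", -1, 1)
  checkRange(cfg$classify$kernelWidth, "classify.kernelWidth", 1e-12, Inf)
  checkRange(cfg$gc$maxP, "gc.maxP", 1, Inf)
  bad <- setdiff(cfg$stages, pipelineDefaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (cohort synthesis, preprocessing,
#' ICA, HPM, voxelwise group statistics with Monte-Carlo extent correction,
#' Granger causality, classification). When `outDir` is set, stage outputs
#' (cluster table TSV, GCI group table TSV, classification JSON) and a run
#' manifest (parameters, seed, output file MD5 hashes) are written there.
#'
#' @param config a `PipelineConfig` from [validateConfig()] (or anything it
#'   accepts).
#' @return a run report list with elements per executed stage: `cohort`,
#'   `preprocessed`, `ica`, `clusters`, `groupStats`, `gc`, `classification`,
#'   `manifest`.
#' @export
runPipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config else
    validateConfig(config)
  report <- list()
  stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  finish <- function() {
    if (!is.null(cfg$outDir)) writePipelineOutputs(cfg, report)
    report$manifest <- buildManifest(cfg, report)
    invisible(report)
  }

  cohort <- stage("cohort", {
    spec <- do.call(cohortSpec, c(cfg$cohort, list(seed = cfg$seed)))
    generateCohort(spec)
  })
  report$cohort <- cohort
  if (!"preprocess" %in% cfg$stages || is.null(cohort)) {
    if (!is.null(cfg$outDir)) writeCohort(cohort, cfg$outDir)
    return(finish())
  }

  pre <- stage("preprocess", lapply(cohort$subjects, function(s)
    preprocessSubject(s, cfg$preprocess$nDiscard, cfg$preprocess$fwhmMm,
                      cfg$preprocess$motionThresholdMm,
                      cfg$preprocess$globalZThreshold)))
  series <- lapply(pre, `[[`, "series")
  report$preprocessed <- list(reports = lapply(pre, `[[`, "report"))

  ica <- stage("ica", lapply(series, function(s)
    runSubjectICA(s, cfg$ica$orders, seed = deriveSeed(cfg$seed, 2L),
                  maxIter = cfg$ica$maxIter, tol = cfg$ica$tol)))
  report$ica <- ica
  if (is.null(ica)) return(finish())

  clusters <- stage("hpm", runHPM(ica,
    minSubjectFraction = cfg$hpm$minSubjectFraction,
    alphaThreshold = cfg$hpm$alphaThreshold,
    minOrdersFraction = cfg$hpm$minOrdersFraction,
    mode = cfg$hpm$mode, zThreshold = cfg$hpm$zThreshold))
  if (!is.null(clusters))
    names(clusters) <- vapply(clusters, function(cl) cl@clusterId, character(1))
  report$clusters <- clusters
  if (is.null(clusters) || !length(clusters)) return(finish())

  covar <- data.frame(
    subject = vapply(series, subjectId, character(1)),
    group = vapply(series, subjectGroup, character(1)),
    age = vapply(series, function(s) s@age, numeric(1)),
    sex = vapply(series, function(s) s@sex, character(1)),
    severity = vapply(series, function(s) s@severity, numeric(1)))
  mask <- series[[1]]@mask
  voxSize <- series[[1]]@voxelSizeMm

  gs <- stage("groupStats", {
    lapply(clusters, function(cl) {
      reps <- clusterRepresentatives(cl)
      subs <- rownames(reps)
      cv <- covar[match(subs, covar$subject), , drop = FALSE]
      des <- makeGroupDesign(cv)
      fit <- fitVoxelwiseGLM(reps, des$X, des$contrast)
      ext <- cfg$groupStats$extentThreshold
      if (identical(ext, "auto")) {
        fw <- estimateSmoothnessFwhm(fit$residuals, mask, voxSize)
        ext <- monteCarloExtentThreshold(mask, voxSize, fw,
                                         cfg$groupStats$voxelP,
                                         cfg$groupStats$fwer,
                                         cfg$groupStats$mcIterations,
                                         seed = deriveSeed(cfg$seed, 31L))
      }
      cls <- thresholdClusters(fit$tMap, mask, fit$df,
                               cfg$groupStats$voxelP, ext)
      sev <- NULL
      if (nrow(cls$table)) {
        v <- cls$voxels[[1]]
        pat <- cv$group == "patient" & !is.na(cv$severity)
        if (sum(pat) >= 3) {
          zscal <- rowMeans(reps[, v, drop = FALSE])
          sev <- tryCatch(severityCorrelation(zscal[pat], cv$severity[pat]),
                          error = function(e) NULL)
        }
      }
      list(fit = fit, extent = ext, clusters = cls, severity = sev)
    })
  })
  report$groupStats <- gs

  gcRes <- stage("gc", {
    subjectsAll <- covar$subject
    tcs <- lapply(clusters, function(cl) {
      m <- do.call(cbind, lapply(subjectsAll, function(s) {
        tc <- subjectTimecourse(cl, ica, s)
        if (is.null(tc)) rep(NA_real_, nrow(series[[1]]@motion)) else tc
      }))
    })
    pooled <- do.call(cbind, lapply(tcs, function(m) rowMeans(m, na.rm = TRUE)))
    p <- selectVAROrder(pooled, maxP = cfg$gc$maxP)
    tab <- computeGCITable(clusters, ica, subjectsAll, p = p,
                           mediator = cfg$gc$mediator)
    grp <- stats::setNames(covar$group, covar$subject)
    list(order = p, table = tab,
         groupTable = gciGroupTable(tab, grp, test = cfg$gc$test))
  })
  report$gc <- gcRes

  cls <- stage("classify", {
    sig <- names(gs)[vapply(gs, function(g) nrow(g$clusters$table) > 0,
                            logical(1))]
    surviving <- lapply(gs, function(g)
      if (nrow(g$clusters$table)) g$clusters$voxels[[1]] else NULL)
    sigEdges <- NULL
    if (!is.null(gcRes) && !is.null(gcRes$groupTable) &&
        nrow(gcRes$groupTable)) {
      gt <- gcRes$groupTable[gcRes$groupTable$p < 0.05, , drop = FALSE]
      if (nrow(gt)) {
        keep <- paste(gcRes$table$source, gcRes$table$target,
                      gcRes$table$mediator) %in%
          paste(gt$source, gt$target, gt$mediator)
        sigEdges <- gcRes$table[keep, , drop = FALSE]
      }
    }
    if (!length(sig) && (is.null(sigEdges) || !nrow(sigEdges))) {
      warning("no significant cluster or edge: skipping classification")
      NULL
    } else {
      grp <- stats::setNames(covar$group, covar$subject)
      fm <- buildFeatures(clusters[sig], surviving[sig], sigEdges,
                          covar$subject, grp)
      list(features = fm,
           svmLoo = svmCrossval(fm, scheme = "loo",
                                kernelWidth = cfg$classify$kernelWidth),
           svmKfold = svmCrossval(fm, scheme = "kfold",
                                  k = cfg$classify$kfold,
                                  kernelWidth = cfg$classify$kernelWidth,
                                  seed = deriveSeed(cfg$seed, 41L)),
           mlda = mldaFitLOO(fm))
    }
  })
  report$classification <- cls
  finish()
}

buildManifest <- function(cfg, report) {
  files <- if (!is.null(cfg$outDir) && dir.exists(cfg$outDir))
    list.files(cfg$outDir, full.names = TRUE) else character()
  hashes <- if (length(files))
    as.list(tools::md5sum(files[!file.info(files)$isdir])) else list()
  list(parameters = unclass(cfg), seed = cfg$seed,
       nClusters = length(report$clusters),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       outputs = hashes)
}

writePipelineOutputs <- function(cfg, report) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  gs <- report$groupStats
  if (!is.null(gs)) {
    tab <- do.call(rbind, lapply(names(gs), function(nm) {
      t <- gs[[nm]]$clusters$table
      if (!nrow(t)) return(NULL)
      cbind(cluster = nm, t)
    }))
    if (!is.null(tab))
      utils::write.table(tab, file.path(cfg$outDir, "cluster_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$gc) && !is.null(report$gc$groupTable))
    utils::write.table(report$gc$groupTable,
                       file.path(cfg$outDir, "gci_group_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$classification)) {
    cl <- report$classification
    jsonlite::write_json(
      list(svm_loo = cl$svmLoo[c("accuracy", "sensitivity", "specificity")],
           svm_kfold = cl$svmKfold[c("accuracy", "sensitivity", "specificity")],
           mlda = cl$mlda[c("accuracy", "sensitivity", "specificity")],
           contributions = as.list(cl$mlda$contributions)),
      file.path(cfg$outDir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(buildManifest(cfg, report),
                       file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}
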