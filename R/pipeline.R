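#' @include AllClasses.R standardize.R pca.R pls.R fuse.R classifiers.R evaluate.R interpret.R synthetic.R io.R
NULL

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full identification run:
#' data source (CSV tables or a synthetic scenario), task, feature-extraction
#' method, classifier and its parameters, split size and seed.
#'
#' @param scenario a \code{ScenarioConfig} from [scenarioConfig()], or NULL
#'   when reading CSV tables.
#' @param sourcePaths named character vector of per-source feature-table CSV
#'   paths (names are source names), or NULL when simulating.
#' @param labelsPath path to the \code{sample_id,class} label CSV (required
#'   with \code{sourcePaths}).
#' @param task \code{"authenticity"} (binary: positive class vs all others,
#'   collapsed to \code{"OTHER"}) or \code{"species"} (multi-class).
#' @param positiveClass the target species (default \code{"BS"}).
#' @param featureMethod \code{"pca"} (unsupervised PC scores, leakage-free
#'   projection) or \code{"plsda"} (supervised latent variables).
#' @param varianceThreshold cumulative explained-variance fraction for PC
#'   retention (default 0.90).
#' @param classifier \code{"plsda"}, \code{"svm"} (binary task only) or
#'   \code{"bpnn"}.
#' @param classifierParams list of back-end parameters: for svm
#'   \code{gGrid,cGrid,folds}; for bpnn
#'   \code{hidden,learningRate,momentum,iterations}; for plsda \code{nLv}
#'   (fixed latent-variable count, otherwise chosen by LOOCV).
#' @param tau assignment threshold for PLS-DA / BP-NN (default 0.5).
#' @param nCalibration Kennard-Stone calibration-set size (default 100).
#' @param standardizationMode \code{"calibration"} (default, leakage-free) or
#'   \code{"pooled"}.
#' @param maxLv upper bound of the LOOCV latent-variable search (default 15).
#' @param calibrationCv \code{"auto"} (LOO for plsda/svm, refit-only for
#'   bpnn), \code{"loo"}, or \code{"none"}.
#' @param sources optional subset of source names to use.
#' @param seed single top-level seed; per-stage seeds are derived by fixed
#'   offsets (SVM folds seed+1, BP-NN weights seed+2).
#' @param outputDir optional directory for CSV/JSON stage outputs.
#' @param verbose emit per-stage log messages (default TRUE).
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(scenario = NULL, sourcePaths = NULL,
    labelsPath = NULL, task = c("authenticity", "species"),
    positiveClass = "BS", featureMethod = c("pca", "plsda"),
    varianceThreshold = 0.90, classifier = c("plsda", "svm", "bpnn"),
    classifierParams = list(), tau = 0.5, nCalibration = 100L,
    standardizationMode = c("calibration", "pooled"), maxLv = 15L,
    calibrationCv = c("auto", "loo", "none"), sources = NULL, seed = 1L,
    outputDir = NULL, verbose = TRUE) {
  task <- match.arg(task)
  featureMethod <- match.arg(featureMethod)
  classifier <- match.arg(classifier)
  standardizationMode <- match.arg(standardizationMode)
  calibrationCv <- match.arg(calibrationCv)
  if (is.null(scenario) == is.null(sourcePaths))
    stop("exactly one of 'scenario' and 'sourcePaths' must be given",
      call. = FALSE)
  if (!is.null(sourcePaths) && is.null(labelsPath))
    stop("'labelsPath' is required with 'sourcePaths'", call. = FALSE)
  if (classifier == "svm" && task == "species")
    stop("the SVM back-end is binary only and cannot be used for the ",
      "multi-class species task; choose plsda or bpnn", call. = FALSE)
  structure(list(scenario = scenario, sourcePaths = sourcePaths,
    labelsPath = labelsPath, task = task, positiveClass = positiveClass,
    featureMethod = featureMethod, varianceThreshold = varianceThreshold,
    classifier = classifier, classifierParams = classifierParams, tau = tau,
    nCalibration = as.integer(nCalibration),
    standardizationMode = standardizationMode, maxLv = as.integer(maxLv),
    calibrationCv = calibrationCv, sources = sources,
    seed = as.integer(seed), outputDir = outputDir, verbose = verbose),
    class = "PipelineConfig")
}

#' RunReport: results of a full pipeline run
#'
#' @slot config the generating \code{PipelineConfig}.
#' @slot split the \linkS4class{SplitResult}.
#' @slot componentCounts retained components per source.
#' @slot fusedWidth total fused feature count.
#' @slot featureModels per-source \linkS4class{PCAModel} or
#'   \linkS4class{PLSFeatureModel} objects.
#' @slot classifier the trained classifier.
#' @slot calibration list with \code{refit} and (optionally) \code{cv}
#'   \linkS4class{EvaluationReport}s.
#' @slot validation \linkS4class{EvaluationReport} of the validation set.
#' @slot auc one-vs-rest validation AUC for the positive class.
#' @slot contributions \linkS4class{ContributionReport}.
#' @slot predictions list with \code{calibration} and \code{validation}
#'   \linkS4class{Prediction}s.
#' @export
setClass("RunReport",
  slots = c(config = "list", split = "SplitResult",
    componentCounts = "integer", fusedWidth = "integer",
    featureModels = "list", classifier = "ANY", calibration = "list",
    validation = "EvaluationReport", auc = "numeric",
    contributions = "ContributionReport", predictions = "list"))

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %s task, %s features, %s classifier\n",
    object@config$task, object@config$featureMethod,
    object@config$classifier))
  cat(sprintf("  components per source: %s (fused width %d)\n",
    paste(sprintf("%s=%d", names(object@componentCounts),
      object@componentCounts), collapse = ", "), object@fusedWidth))
  if (!is.null(object@calibration$cv))
    cat(sprintf("  calibration accuracy (LOO CV): %.4f\n",
      object@calibration$cv@acOverall))
  cat(sprintf("  calibration accuracy (refit):  %.4f\n",
    object@calibration$refit@acOverall))
  cat(sprintf("  validation accuracy:           %.4f (AUC %.4f)\n",
    object@validation@acOverall, object@auc))
})

.log <- function(verbose, ...) if (verbose) message("[senseFuse] ", ...)

.taskLabels <- function(labels, task, positiveClass) {
  if (task == "species") return(as.factor(labels))
  lab <- ifelse(as.character(labels) == positiveClass, positiveClass, "OTHER")
  factor(lab, levels = c(positiveClass, "OTHER"))
}

.trainClassifier <- function(config, features, labels) {
  p <- config$classifierParams
  switch(config$classifier,
    plsda = {
      nLv <- p$nLv
      if (is.null(nLv))
        nLv <- selectNlvLOOCV(features, labels,
          min(config$maxLv, ncol(features)))
      trainPLSDA(features, labels, nLv = nLv, tau = config$tau)
    },
    svm = trainSVMGrid(features, labels,
      gGrid = if (is.null(p$gGrid)) defaultGammaGrid() else p$gGrid,
      cGrid = if (is.null(p$cGrid)) defaultCostGrid() else p$cGrid,
      folds = if (is.null(p$folds)) 10L else p$folds,
      seed = config$seed + 1L),
    bpnn = trainBPNN(features, labels,
      hidden = if (is.null(p$hidden)) c(10L, 10L) else p$hidden,
      learningRate = if (is.null(p$learningRate)) 0.01 else p$learningRate,
      momentum = if (is.null(p$momentum)) 0.5 else p$momentum,
      iterations = if (is.null(p$iterations)) 500L else p$iterations,
      seed = config$seed + 2L, tau = config$tau))
}

# leave-one-out retraining with the already-selected hyperparameters
.looPredictions <- function(config, model, features, labels) {
  n <- nrow(features)
  classes <- levels(labels)
  scores <- matrix(NA_real_, n, length(classes),
    dimnames = list(rownames(features), classes))
  tau <- switch(config$classifier, svm = 0, config$tau)
  for (i in seq_len(n)) {
    tr <- features[-i, , drop = FALSE]
    fit <- switch(config$classifier,
      plsda = trainPLSDA(tr, labels[-i],
        nLv = min(model@pls@nLv, .matrixRank(scale(tr, scale = FALSE))),
        tau = config$tau),
      svm = {
        m <- .svmFit(tr, labels[-i], model@g, model@cost)
        methods::new("SVMClassifier", g = model@g, cost = model@cost,
          fit = m, classes = classes,
          nSupportVectors = as.integer(m$tot.nSV),
          cvErrors = model@cvErrors, foldIds = model@foldIds, tau = 0)
      },
      bpnn = trainBPNN(tr, labels[-i], hidden = model@hidden,
        learningRate = model@learningRate, momentum = model@momentum,
        iterations = model@iterations, seed = model@seed, tau = config$tau))
    scores[i, ] <- predictionScores(
      classify(fit, features[i, , drop = FALSE]))[1L, classes]
  }
  .newPrediction(scores, classes, tau)
}

#' Run the full mid-level fusion pipeline
#'
#' Executes, in order: data generation or loading; Kennard-Stone split;
#' per-source standardization with calibration statistics; per-source PCA
#' score projection or PLS latent-variable extraction; mid-level fusion;
#' classifier training on the fused calibration features; evaluation on the
#' calibration set (leave-one-out cross-validated and refit) and the
#' validation set; and contribution analysis. A rerun with an identical
#' config and seed reproduces every number exactly. No stage reads validation
#' labels before evaluation.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @return A \linkS4class{RunReport}.
#' @examples
#' cfg <- pipelineConfig(
#'   scenario = scenarioConfig(seed = 3),
#'   task = "authenticity", featureMethod = "pca", classifier = "plsda",
#'   calibrationCv = "none", verbose = FALSE)
#' runPipeline(cfg)
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  verbose <- isTRUE(config$verbose)

  ## data
  if (!is.null(config$scenario)) {
    dataset <- generateDataset(config$scenario)
    .log(verbose, "generated synthetic dataset: ",
      length(sampleIds(dataset)), " samples, scenario '",
      config$scenario$scenario, "'")
  } else {
    blockList <- mapply(readFeatureTable, config$sourcePaths,
      names(config$sourcePaths), SIMPLIFY = FALSE)
    dataset <- assembleDataset(unname(blockList), config$labelsPath)
    .log(verbose, "loaded ", length(blockList), " source tables")
  }
  if (!is.null(config$sources)) {
    keep <- blocks(dataset)[config$sources]
    dataset <- MultiSourceDataset(keep,
      structure(as.character(classLabels(dataset)),
        names = sampleIds(dataset)))
  }
  labels <- .taskLabels(classLabels(dataset), config$task,
    config$positiveClass)
  names(labels) <- sampleIds(dataset)

  ## split
  split <- splitDataset(dataset, config$nCalibration)
  calIds <- split@calibrationIds
  valIds <- split@validationIds
  missing <- setdiff(levels(labels), as.character(labels[calIds]))
  if (length(missing))
    stop("degenerate split: class(es) absent from calibration set: ",
      paste(missing, collapse = ", "), call. = FALSE)
  .log(verbose, "Kennard-Stone split: ", length(calIds), " calibration / ",
    length(valIds), " validation")

  ## per-source extraction
  calScores <- list(); valScores <- list(); featureModels <- list()
  for (b in blocks(dataset)) {
    src <- sourceName(b)
    std <- standardizeBlock(b, calIds, mode = config$standardizationMode)
    calStd <- std$values[calIds, , drop = FALSE]
    valStd <- std$values[valIds, , drop = FALSE]
    if (config$featureMethod == "pca") {
      fitStd <- if (config$standardizationMode == "calibration") calStd
        else standardizeBlock(b, calIds, mode = "calibration")$values[
          calIds, , drop = FALSE]
      model <- fitPCA(fitStd, config$varianceThreshold,
        standardization = std$params, sourceName = src)
      calScores[[src]] <- projectScores(model, calStd)
      valScores[[src]] <- projectScores(model, valStd)
      .log(verbose, src, ": retained ", model@kSelected, " PCs (",
        round(100 * sum(model@varianceRatios[seq_len(model@kSelected)]), 1),
        "% variance)")
    } else {
      nLv <- suppressWarnings(selectNlvLOOCV(calStd, labels[calIds],
        min(config$maxLv, ncol(calStd))))
      model <- fitPLS(calStd, labels[calIds], nLv,
        sourceName = src, standardization = std$params)
      calScores[[src]] <- model@calibScores
      valScores[[src]] <- plsScores(model, valStd)
      .log(verbose, src, ": retained ", nLv, " LVs (LOOCV)")
    }
    featureModels[[src]] <- model
  }

  ## fusion
  fusedCal <- fuseBlocks(calScores)
  fusedVal <- fuseBlocks(valScores)
  counts <- vapply(calScores, ncol, integer(1))
  .log(verbose, "fused width: ", ncol(featureValues(fusedCal)))

  ## classifier
  calLab <- labels[calIds]; valLab <- labels[valIds]
  model <- .trainClassifier(config, featureValues(fusedCal), calLab)
  .log(verbose, "trained ", config$classifier, " classifier")

  ## evaluation
  calPred <- classify(model, featureValues(fusedCal))
  valPred <- classify(model, featureValues(fusedVal))
  calRefit <- evaluatePredictions(calLab, calPred, config$positiveClass)
  valReport <- evaluatePredictions(valLab, valPred, config$positiveClass)
  doLoo <- switch(config$calibrationCv,
    loo = TRUE, none = FALSE, auto = config$classifier != "bpnn")
  calCv <- NULL
  if (doLoo) {
    cvPred <- .looPredictions(config, model, featureValues(fusedCal), calLab)
    calCv <- evaluatePredictions(calLab, cvPred, config$positiveClass)
    .log(verbose, "calibration LOO-CV accuracy: ",
      round(calCv@acOverall, 4))
  }
  auc <- rocAuc(predictionScores(valPred)[, config$positiveClass],
    as.character(valLab), config$positiveClass)$auc
  .log(verbose, "validation accuracy: ", round(valReport@acOverall, 4),
    " (AUC ", round(auc, 4), ")")

  ## interpretation
  contributions <- rankContributions(fusedCal, calLab,
    models = if (config$featureMethod == "pca") featureModels else list())

  report <- methods::new("RunReport", config = unclass(config),
    split = split, componentCounts = counts,
    fusedWidth = as.integer(ncol(featureValues(fusedCal))),
    featureModels = featureModels, classifier = model,
    calibration = list(refit = calRefit, cv = calCv),
    validation = valReport, auc = auc, contributions = contributions,
    predictions = list(calibration = calPred, validation = valPred))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeFusedFeatures(fusedCal,
      file.path(config$outputDir, "fused_calibration.csv"))
    writeFusedFeatures(fusedVal,
      file.path(config$outputDir, "fused_validation.csv"))
    exportReport(valReport, file.path(config$outputDir, "validation.json"))
    exportReport(calRefit,
      file.path(config$outputDir, "calibration_refit.json"))
    if (!is.null(calCv))
      exportReport(calCv, file.path(config$outputDir, "calibration_cv.json"))
    exportContributions(contributions,
      file.path(config$outputDir, "contributions.csv"))
    .log(verbose, "wrote stage outputs to ", config$outputDir)
  }
  report
}
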