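## End-to-end orchestration: repeated compound-level splits, per-split
## schema building + featurization + training + evaluation, aggregation
## into a mean +/- sd metric table, averaged curves, importance report
## and the naive baseline - all traceable to a single master seed.

#' Train and evaluate on one split plan
#'
#' Builds the bin schema and instrument vocabulary from the training side
#' only, featurizes both sides, prunes training-empty bins, trains the
#' classifier (optionally tuning on a grid with compound-grouped CV) and
#' scores the held-out side.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param plan A [SplitPlan-class].
#' @param binWidth bin width in Th (default 0.1).
#' @param strategy peak-descriptor strategy (default `"intensity"`).
#' @param params hyperparameters (ignored when `tune = TRUE`).
#' @param algorithm `"randomForest"` or `"xgboost"`.
#' @param seed fit seed.
#' @param tune if `TRUE`, grid-search `grid` by grouped CV first.
#' @param grid,folds grid search settings (see [tuneHyperparameters()]).
#' @return list with elements `model`, `metrics` (test), `trainMetrics`,
#'   `scores` (test `p_bitter`), `truth` (test labels), `plan`.
#' @export
evaluateSplit <- function(x, plan, binWidth = 0.1, strategy = "intensity",
                          params = defaultParams(),
                          algorithm = "randomForest", seed = 1,
                          tune = FALSE, grid = defaultGrid(algorithm),
                          folds = 5) {
  sp <- normalizeIntensities(spectra(x))
  labs <- spectrumLabels(x)
  trIdx <- splitIndices(x, plan, "train")
  teIdx <- splitIndices(x, plan, "test")
  train <- sp[trIdx]; test <- sp[teIdx]

  schema <- buildBinSchema(train, binWidth)
  vocab <- buildInstrumentVocab(train)
  trMat <- featurizeSpectra(train, schema, vocab, strategy)
  pruned <- pruneEmptyBins(trMat, schema)

  if (tune) {
    params <- tuneHyperparameters(pruned$matrix, labs[trIdx],
                                  compoundKeys(train), grid = grid,
                                  folds = folds, seed = seed,
                                  algorithm = algorithm)$params
  }
  model <- trainModel(pruned$matrix, labs[trIdx], params, seed = seed,
                      algorithm = algorithm, schema = pruned$schema,
                      vocab = vocab, strategy = strategy)
  teMat <- featurizeSpectra(test, pruned$schema, vocab, strategy)
  p <- predictProbMatrix(model, teMat)
  pred <- ifelse(p >= 0.5, "bitter", "nonbitter")
  pTrain <- predictProbMatrix(model, pruned$matrix)
  list(model = model,
       metrics = confusionCounts(labs[teIdx], pred),
       trainMetrics = confusionCounts(
         labs[trIdx], ifelse(pTrain >= 0.5, "bitter", "nonbitter")),
       scores = p, truth = labs[teIdx], plan = plan)
}

#' Run the full repeated-split evaluation pipeline
#'
#' Draws `repeats` compound-level splits, runs [evaluateSplit()] on each,
#' and aggregates: dataset composition, mean +/- sd of the six metrics on
#' the training and test sides, averaged ROC and precision-recall curves
#' with bootstrap bands, the naive-baseline metrics, the best split's
#' model (highest test balanced accuracy, ties broken by F1) and its
#' top-feature importance report. Fully reproducible from `seed`.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param binWidth,strategy,algorithm,params,tune,grid,folds see
#'   [evaluateSplit()].
#' @param testFraction,repeats split settings (defaults 0.2 and 20).
#' @param seed master seed; every random stage derives from it.
#' @param nBoot bootstrap resamples for the curve bands.
#' @param topK features to report from the best model.
#' @return list of class `"PipelineReport"`: `composition`,
#'   `testMetrics`, `trainMetrics`, `naiveMetrics`, `roc`, `pr`,
#'   `bestModel`, `bestSplit`, `importance`, `perSplit`, `seeds`,
#'   `configHash`, `versions`.
#' @export
runPipeline <- function(x, binWidth = 0.1, strategy = "intensity",
                        algorithm = "randomForest",
                        params = defaultParams(), tune = FALSE,
                        grid = defaultGrid(algorithm), folds = 5,
                        testFraction = 0.2, repeats = 20, seed = 1,
                        nBoot = 1000, topK = 20) {
  config <- list(binWidth = binWidth, strategy = strategy,
                 algorithm = algorithm, params = params, tune = tune,
                 testFraction = testFraction, repeats = repeats,
                 seed = seed)
  plans <- makeSplits(x, testFraction = testFraction, repeats = repeats,
                      seed = seed)
  fitSeeds <- deriveSeeds(seed + 1L, repeats)
  naiveSeeds <- deriveSeeds(seed + 2L, repeats)
  perSplit <- lapply(seq_len(repeats), function(r)
    evaluateSplit(x, plans[[r]], binWidth = binWidth, strategy = strategy,
                  params = params, algorithm = algorithm,
                  seed = fitSeeds[r], tune = tune, grid = grid,
                  folds = folds))

  labs <- spectrumLabels(x)
  naiveMetrics <- lapply(seq_len(repeats), function(r) {
    trIdx <- splitIndices(x, plans[[r]], "train")
    teIdx <- splitIndices(x, plans[[r]], "test")
    nm <- naiveFit(labs[trIdx])
    confusionCounts(labs[teIdx],
                    naivePredict(nm, length(teIdx), naiveSeeds[r]))
  })

  testBA <- vapply(perSplit, function(e)
    metricScores(e$metrics)["balanced_accuracy"], numeric(1))
  testF1 <- vapply(perSplit, function(e)
    metricScores(e$metrics)["f1"], numeric(1))
  best <- order(-testBA, -testF1)[1]

  scoreList <- lapply(perSplit, `[[`, "scores")
  truthList <- lapply(perSplit, `[[`, "truth")
  roc <- pr <- NULL
  usable <- sum(vapply(truthList, function(t) length(unique(t)) == 2,
                       logical(1)))
  if (usable >= 2) {
    roc <- averageCurves(scoreList, truthList, "roc", nBoot = nBoot,
                         seed = seed + 3L)
    pr <- averageCurves(scoreList, truthList, "pr", nBoot = nBoot,
                        seed = seed + 3L)
  }

  structure(list(
    composition = compositionSummary(x),
    testMetrics = summarizeMetrics(lapply(perSplit, `[[`, "metrics")),
    trainMetrics = summarizeMetrics(lapply(perSplit, `[[`, "trainMetrics")),
    naiveMetrics = summarizeMetrics(naiveMetrics),
    roc = roc, pr = pr,
    bestModel = perSplit[[best]]$model, bestSplit = best,
    importance = featureImportanceReport(perSplit[[best]]$model, topK),
    perSplit = perSplit,
    seeds = list(master = seed, fits = fitSeeds, naive = naiveSeeds),
    configHash = configHash(config),
    versions = c(R = as.character(getRversion()),
                 bitterspec = as.character(utils::packageVersion("bitterspec"))),
    config = config), class = "PipelineReport")
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Pipeline report (", x$config$repeats, " splits, seed ",
      x$seeds$master, ", config ", substr(x$configHash, 1, 8), ")\n\n",
      sep = "")
  cat("Dataset composition:\n"); print(x$composition)
  cat("\nTest metrics (mean +/- sd over splits):\n")
  print(transform(x$testMetrics, mean = round(mean, 3), sd = round(sd, 3)))
  cat("\nNaive baseline on the same test splits:\n")
  print(transform(x$naiveMetrics, mean = round(mean, 3), sd = round(sd, 3)))
  if (!is.null(x$roc))
    cat(sprintf("\nMean ROC AUC %.3f; mean PR average precision %.3f\n",
                mean(x$roc@auc), mean(x$pr@auc)))
  cat("\nTop features of the best split's model:\n")
  print(head(transform(x$importance, percent = round(percent, 2)), 10))
  invisible(x)
}

#' Compare compound-level and spectrum-level splitting on the same data
#'
#' Paired demonstration of the leakage hazard: for each repeat, one
#' compound-level and one spectrum-level split are drawn from the same
#' data and evaluated identically. When spectra of one compound resemble
#' each other, the spectrum-level split lets near-duplicates of training
#' spectra into the test set and inflates the apparent balanced accuracy.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param repeats paired repeats (default 5).
#' @param seed master seed.
#' @param ... passed to [evaluateSplit()].
#' @return `data.frame` with columns `repeat_index`, `ba_compound`,
#'   `ba_spectrum`.
#' @export
compareSplitLevels <- function(x, repeats = 5, seed = 1, ...) {
  cPlans <- makeSplits(x, repeats = repeats, seed = seed, by = "compound")
  sPlans <- makeSplits(x, repeats = repeats, seed = seed, by = "spectrum")
  fitSeeds <- deriveSeeds(seed + 1L, repeats)
  ba <- function(plan, r) {
    ev <- evaluateSplit(x, plan, seed = fitSeeds[r], ...)
    unname(metricScores(ev$metrics)["balanced_accuracy"])
  }
  data.frame(
    repeat_index = seq_len(repeats),
    ba_compound = vapply(seq_len(repeats), function(r) ba(cPlans[[r]], r),
                         numeric(1)),
    ba_spectrum = vapply(seq_len(repeats), function(r) ba(sPlans[[r]], r),
                         numeric(1)))
}
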