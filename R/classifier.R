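## Tree-ensemble training with grouped cross-validated grid search, the
## naive prevalence baseline, importance reporting and the learning curve.
##
## Random forests are fitted with ranger (probability forests, impurity
## importance); gradient-boosted trees with xgboost. Hyperparameter
## search is an exhaustive grid evaluated by k-fold cross-validation whose
## folds are grouped by compound, for the same reason the outer split is:
## spectra of one compound must never straddle a fold boundary.

#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train xgb.DMatrix xgb.importance
NULL

#' Default hyperparameter grid
#'
#' Standard random-forest / boosted-tree ranges covering ensemble size,
#' tree depth, features per split, minimum leaf size and class weighting
#' (the datasets are class-imbalanced, so balanced weighting is always a
#' candidate). `max_depth = NA` means unlimited depth.
#'
#' @param algorithm `"randomForest"` or `"xgboost"`.
#' @return `data.frame` with one row per hyperparameter combination.
#' @export
defaultGrid <- function(algorithm = c("randomForest", "xgboost")) {
  algorithm <- match.arg(algorithm)
  expand.grid(
    num_trees = c(100L, 300L, 500L),
    max_depth = c(NA_integer_, 10L, 30L),
    mtry = c("sqrt", "0.1"),
    min_node_size = c(1L, 3L),
    class_weight = c("none", "balanced"),
    stringsAsFactors = FALSE)
}

resolveMtry <- function(mtry, p) {
  if (identical(mtry, "sqrt")) return(max(1L, floor(sqrt(p))))
  v <- suppressWarnings(as.numeric(mtry))
  if (is.na(v)) stop("mtry must be 'sqrt', a fraction or an integer")
  if (v < 1) max(1L, floor(v * p)) else as.integer(v)
}

defaultParams <- function() {
  list(num_trees = 300L, max_depth = NA_integer_, mtry = "sqrt",
       min_node_size = 1L, class_weight = "balanced")
}

#' Train a spectrum-level bitterness classifier
#'
#' @param mat feature matrix from [featurizeSpectra()] (pruned).
#' @param labels per-spectrum labels (`"bitter"` / `"nonbitter"`).
#' @param params hyperparameter list with entries `num_trees`,
#'   `max_depth` (`NA` = unlimited), `mtry` (`"sqrt"`, a fraction, or an
#'   integer), `min_node_size`, `class_weight` (`"none"`/`"balanced"`).
#' @param seed training seed; the fit is reproducible given the seed.
#' @param algorithm `"randomForest"` (ranger) or `"xgboost"`.
#' @param schema,vocab,strategy featurization state to freeze into the
#'   bundle so the model is self-sufficient for prediction.
#' @return A [BitterModel-class].
#' @export
trainModel <- function(mat, labels, params = defaultParams(), seed = 1,
                       algorithm = c("randomForest", "xgboost"),
                       schema = NULL, vocab = NULL, strategy = "intensity") {
  algorithm <- match.arg(algorithm)
  labels <- checkLabels(labels)
  if (nrow(mat) == 0) stop("empty feature matrix")
  if (nrow(mat) != length(labels))
    stop("feature matrix rows must match label length")
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class")
  params <- modifyList(defaultParams(), params)
  y <- factor(labels, levels = CLASS_LEVELS)
  p <- ncol(mat)

  if (algorithm == "randomForest") {
    cw <- if (identical(params$class_weight, "balanced")) {
      tab <- table(y)
      as.numeric(length(y) / (2 * tab[CLASS_LEVELS]))
    } else NULL
    fit <- ranger::ranger(
      x = mat, y = y, probability = TRUE,
      num.trees = params$num_trees,
      mtry = resolveMtry(params$mtry, p),
      min.node.size = params$min_node_size,
      max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
      class.weights = cw, importance = "impurity",
      seed = as.integer(seed), num.threads = 1)
    imp <- fit$variable.importance
  } else {
    ylog <- as.numeric(y == "bitter")
    spw <- if (identical(params$class_weight, "balanced"))
      sum(ylog == 0) / sum(ylog == 1) else 1
    fit <- withSeed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = if (is.na(params$max_depth)) 6 else params$max_depth,
                    min_child_weight = params$min_node_size,
                    colsample_bynode = resolveMtry(params$mtry, p) / p,
                    scale_pos_weight = spw, nthread = 1,
                    seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(mat, label = ylog),
      nrounds = params$num_trees, verbose = 0))
    gain <- xgboost::xgb.importance(model = fit)
    imp <- setNames(numeric(p), colnames(mat))
    imp[gain$Feature] <- gain$Gain
  }
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp) else imp[] <- 1 / length(imp)

  new("BitterModel", algorithm = algorithm, params = params, fit = fit,
      schema = if (is.null(schema)) fallbackSchema(mat) else schema,
      vocab = if (is.null(vocab)) fallbackVocab() else vocab,
      strategy = strategy, prevalence = mean(labels == "bitter"),
      importance = imp, seed = as.integer(seed))
}

# Placeholder featurization state for models trained on a bare matrix
# (unit tests, learning curves on precomputed features).
fallbackSchema <- function(mat) {
  n <- max(1L, ncol(mat) - 3L)
  new("BinSchema", origin = 0, width = 1, nBinsTotal = n, retained = seq_len(n))
}
fallbackVocab <- function() {
  new("InstrumentVocab", msTypeCodes = c("EI-MS" = 1L, "ESI-MS/MS" = 2L),
      ionModeCodes = c("positive" = 1L))
}

# Per-spectrum P(bitter) on an already-featurized matrix.
predictProbMatrix <- function(model, mat) {
  if (model@algorithm == "randomForest") {
    unname(predict(model@fit, data = mat,
                   num.threads = 1)$predictions[, "bitter"])
  } else {
    unname(predict(model@fit, xgboost::xgb.DMatrix(mat)))
  }
}

#' Grid-search hyperparameters with compound-grouped cross-validation
#'
#' Evaluates every grid row by k-fold cross-validation on the training
#' matrix, optimizing balanced accuracy. Folds are assigned at the
#' compound level (stratified by class), so all spectra of a compound land
#' in one fold. Ties between combinations are broken toward the smaller
#' ensemble, then the shallower tree.
#'
#' @param mat training feature matrix.
#' @param labels per-spectrum labels.
#' @param groups per-spectrum compound keys (grouping unit for folds).
#' @param grid `data.frame` of candidate combinations
#'   (see [defaultGrid()]).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for fold assignment and fits.
#' @param algorithm passed to [trainModel()].
#' @return `list(params = best combination as a list, results =
#'   data.frame of per-combination mean CV balanced accuracy)`.
#' @export
tuneHyperparameters <- function(mat, labels, groups, grid = defaultGrid(),
                                folds = 5, seed = 1,
                                algorithm = c("randomForest", "xgboost")) {
  algorithm <- match.arg(algorithm)
  labels <- checkLabels(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class")
  stopifnot(nrow(grid) >= 1)
  cmpLabel <- tapply(labels, groups, function(l) l[1])
  foldOf <- withSeed(seed, {
    out <- integer(0)
    for (cl in CLASS_LEVELS) {
      keys <- sample(names(cmpLabel)[cmpLabel == cl])
      out <- c(out, setNames(rep_len(seq_len(folds), length(keys)), keys))
    }
    out
  })
  foldId <- unname(foldOf[as.character(groups)])

  seeds <- deriveSeeds(seed, nrow(grid) * folds)
  cvBA <- vapply(seq_len(nrow(grid)), function(g) {
    prm <- as.list(grid[g, , drop = FALSE])
    bas <- vapply(seq_len(folds), function(f) {
      tr <- foldId != f
      if (length(unique(labels[tr])) < 2 || !any(!tr)) return(NA_real_)
      m <- trainModel(mat[tr, , drop = FALSE], labels[tr], prm,
                      seed = seeds[(g - 1L) * folds + f],
                      algorithm = algorithm)
      pred <- ifelse(predictProbMatrix(m, mat[!tr, , drop = FALSE]) >= 0.5,
                     "bitter", "nonbitter")
      balancedAccuracy(labels[!tr], pred)
    }, numeric(1))
    mean(bas, na.rm = TRUE)
  }, numeric(1))

  depth <- ifelse(is.na(grid$max_depth), Inf, grid$max_depth)
  best <- order(-cvBA, grid$num_trees, depth)[1]
  list(params = as.list(grid[best, , drop = FALSE]),
       results = cbind(grid, cv_balanced_accuracy = cvBA))
}

#' Naive prevalence baseline
#'
#' `naiveFit` records the training prevalence of bitter spectra;
#' `naivePredict` draws independent labels, predicting bitter with that
#' probability regardless of the spectrum. Because prediction is
#' independent of the truth, the baseline's expected balanced accuracy is
#' 0.5 for any prevalence, while its precision tracks the evaluation
#' set's bitter fraction.
#'
#' @param labels training spectrum labels.
#' @return `naiveFit`: a [NaiveModel-class].
#' @export
naiveFit <- function(labels) {
  new("NaiveModel", pBitter = mean(checkLabels(labels) == "bitter"))
}

#' @rdname naiveFit
#' @param model A [NaiveModel-class].
#' @param n number of predictions to draw.
#' @param seed RNG seed.
#' @return `naivePredict`: character vector of `n` labels.
#' @export
naivePredict <- function(model, n, seed = 1) {
  withSeed(seed, ifelse(runif(n) < model@pBitter, "bitter", "nonbitter"))
}

#' Ranked feature-importance report
#'
#' Importance fractions are expressed as percentages (summing to 100 over
#' all features) and the `topK` most important features returned in
#' descending order. Instrument features keep their names; bins are
#' labeled by their m/z interval.
#'
#' @param model A [BitterModel-class].
#' @param topK number of features to report (default 20; capped at the
#'   feature count).
#' @return `data.frame` with columns `feature`, `percent`.
#' @export
featureImportanceReport <- function(model, topK = 20) {
  imp <- sort(featureImportance(model), decreasing = TRUE)
  k <- min(topK, length(imp))
  data.frame(feature = names(imp)[seq_len(k)],
             percent = unname(imp[seq_len(k)]) * 100,
             row.names = NULL)
}

#' Training-set-size learning curve
#'
#' Holds out one fixed compound-level test split, then retrains on nested
#' subsamples of the training compounds (per class) and records the test
#' balanced accuracy at each training fraction.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param fractions training-set fractions in (0, 1].
#' @param repeats subsample repeats per fraction.
#' @param seed master seed.
#' @param binWidth,strategy,params,algorithm passed through to
#'   featurization and training.
#' @return `data.frame` with columns `fraction`, `mean_ba`, `sd_ba`,
#'   `n_train_compounds`.
#' @export
learningCurve <- function(x, fractions = c(0.25, 0.5, 1), repeats = 3,
                          seed = 1, binWidth = 0.1, strategy = "intensity",
                          params = defaultParams(),
                          algorithm = "randomForest") {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  plan <- makeSplits(x, repeats = 1, seed = seed)[[1]]
  cmp <- as.data.frame(compoundTable(x))
  trainCmp <- cmp[cmp$compound_key %in% trainKeys(plan), , drop = FALSE]
  seeds <- deriveSeeds(seed + 1L, length(fractions) * repeats)
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    bas <- c(); nUsed <- NA_integer_
    for (r in seq_len(repeats)) {
      s <- seeds[(i - 1L) * repeats + r]
      sub <- withSeed(s, unlist(lapply(split(trainCmp$compound_key,
                                             trainCmp$label), function(k) {
        sample(k, max(1L, round(length(k) * f)))
      }), use.names = FALSE))
      subLabels <- trainCmp$label[match(sub, trainCmp$compound_key)]
      if (length(unique(subLabels)) < 2) {
        warning("fraction ", f, " leaves a single class; skipped")
        next
      }
      subPlan <- new("SplitPlan", repeatIndex = 1L, seed = as.integer(s),
                     trainKeys = sub,
                     testKeys = testKeys(plan), by = "compound")
      ev <- evaluateSplit(x, subPlan, binWidth = binWidth,
                          strategy = strategy, params = params,
                          algorithm = algorithm, seed = s)
      bas <- c(bas, unname(metricScores(ev$metrics)["balanced_accuracy"]))
      nUsed <- length(sub)
    }
    rows[[i]] <- data.frame(fraction = f,
                            mean_ba = if (length(bas)) mean(bas) else NA_real_,
                            sd_ba = if (length(bas) > 1) sd(bas) else NA_real_,
                            n_train_compounds = nUsed)
  }
  do.call(rbind, rows)
}

#' Save / load a trained model bundle
#'
#' The bundle is self-sufficient: classifier state, frozen bin schema,
#' instrument vocabulary, strategy and seed travel together, and a
#' reloaded bundle reproduces predictions bitwise.
#'
#' @param model A [BitterModel-class].
#' @param path file path for the serialized bundle.
#' @return `loadModel` returns the [BitterModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "BitterModel"))
  model
}
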