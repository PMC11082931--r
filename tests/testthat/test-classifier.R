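# Shared small feature set: one informative bin column, rest noise.
informativeMatrix <- function(n = 80, p = 10, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(c("bitter", "nonbitter"), length.out = n)
    mat <- cbind(ms_type_code = 1, ion_mode_code = 1,
                 collision_energy_eV = 20,
                 matrix(runif(n * p), n,
                        dimnames = list(NULL, sprintf("[%d.0 to %d.1]",
                                                      100 + seq_len(p),
                                                      100 + seq_len(p)))))
    mat[, 5] <- as.numeric(labels == "bitter") * 100
    list(mat = mat, labels = labels)
  })
}

test_that("training is reproducible: same seed, same predictions", {
  d <- informativeMatrix()
  for (alg in c("randomForest", "xgboost")) {
    m1 <- trainModel(d$mat, d$labels, seed = 5, algorithm = alg)
    m2 <- trainModel(d$mat, d$labels, seed = 5, algorithm = alg)
    expect_identical(bitterspec:::predictProbMatrix(m1, d$mat),
                     bitterspec:::predictProbMatrix(m2, d$mat))
  }
})

test_that("degenerate training inputs are refused", {
  d <- informativeMatrix()
  expect_error(trainModel(d$mat[0, , drop = FALSE], character(0)), "empty")
  expect_error(trainModel(d$mat, rep("bitter", nrow(d$mat))),
               "single class")
})

test_that("model bundle round-trips through save/load bitwise", {
  d <- informativeMatrix()
  m <- trainModel(d$mat, d$labels, seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(bitterspec:::predictProbMatrix(m, d$mat),
                   bitterspec:::predictProbMatrix(m2, d$mat))
})

test_that("grid search returns the single combination when there is one", {
  d <- informativeMatrix()
  grid <- data.frame(num_trees = 50L, max_depth = NA_integer_,
                     mtry = "sqrt", min_node_size = 1L,
                     class_weight = "none", stringsAsFactors = FALSE)
  tuned <- tuneHyperparameters(d$mat, d$labels,
                               groups = seq_len(nrow(d$mat)), grid = grid,
                               folds = 3, seed = 1)
  expect_equal(tuned$params$num_trees, 50L)
  expect_equal(nrow(tuned$results), 1L)
})

test_that("grid search prefers the clearly stronger combination", {
  d <- informativeMatrix(n = 120)
  # a healthy forest vs a crippled one (single stump-like tree)
  grid <- data.frame(num_trees = c(100L, 1L),
                     max_depth = c(NA_integer_, 1L),
                     mtry = c("sqrt", "1"),
                     min_node_size = c(1L, 50L),
                     class_weight = "none", stringsAsFactors = FALSE)
  tuned <- tuneHyperparameters(d$mat, d$labels,
                               groups = seq_len(nrow(d$mat)), grid = grid,
                               folds = 3, seed = 4)
  expect_equal(tuned$params$num_trees, 100L)
  expect_gt(tuned$results$cv_balanced_accuracy[1],
            tuned$results$cv_balanced_accuracy[2])
})

test_that("grouped CV keeps all spectra of a compound in one fold and separable data scores high", {
  d <- tinySeparableSet(seed = 9)
  lss <- d$labeled
  s <- normalizeIntensities(spectra(lss))
  schema <- buildBinSchema(s)
  vocab <- buildInstrumentVocab(s)
  pr <- pruneEmptyBins(featurizeSpectra(s, schema, vocab, "intensity"),
                       schema)
  grid <- data.frame(num_trees = 100L, max_depth = NA_integer_,
                     mtry = "sqrt", min_node_size = 1L,
                     class_weight = "none", stringsAsFactors = FALSE)
  tuned <- tuneHyperparameters(pr$matrix, spectrumLabels(lss),
                               groups = compoundKeys(s), grid = grid,
                               folds = 5, seed = 3)
  expect_gte(tuned$results$cv_balanced_accuracy[1], 0.9)
})

test_that("naive baseline reproduces prevalence-driven metrics", {
  # evaluating p = 0.66 on a 66%-bitter set: precision and recall both
  # land near two thirds, balanced accuracy near one half
  n <- 3000
  labels <- rep(c("bitter", "nonbitter"), c(round(0.66 * n), n - round(0.66 * n)))
  nm <- naiveFit(labels)
  expect_equal(nm@pBitter, round(0.66 * n) / n)
  sc <- rowMeans(vapply(1:30, function(s) {
    pred <- naivePredict(nm, n, seed = s)
    metricScores(confusionCounts(labels, pred))[c("precision", "recall",
                                                  "balanced_accuracy")]
  }, numeric(3)))
  expect_equal(unname(sc["precision"]), 0.66, tolerance = 0.02)
  expect_equal(unname(sc["recall"]), 0.66, tolerance = 0.02)
  expect_equal(unname(sc["balanced_accuracy"]), 0.5, tolerance = 0.02)
})

test_that("forced naive extremes behave analytically", {
  labels <- rep(c("bitter", "nonbitter"), c(40, 60))
  always <- new("NaiveModel", pBitter = 1)
  pred <- naivePredict(always, 100, seed = 1)
  sc <- metricScores(confusionCounts(labels, pred))
  expect_equal(unname(sc["recall"]), 1)
  expect_equal(unname(sc["precision"]), 0.4)   # prevalence
})

test_that("importance percents sum to 100 and the informative bin ranks first", {
  d <- informativeMatrix()
  for (alg in c("randomForest", "xgboost")) {
    m <- trainModel(d$mat, d$labels, seed = 7, algorithm = alg)
    rep <- featureImportanceReport(m, topK = 1000)
    expect_equal(sum(rep$percent), 100, tolerance = 0.01)
    expect_equal(rep$feature[1], colnames(d$mat)[5])
    expect_true(all(diff(rep$percent) <= 1e-12))   # descending
  }
  # topK larger than the feature count returns everything
  m <- trainModel(d$mat, d$labels, seed = 7)
  expect_equal(nrow(featureImportanceReport(m, topK = 10000)),
               ncol(d$mat))
})

test_that("signal-bearing training beats its permuted-label counterpart", {
  d <- tinySeparableSet(seed = 13)
  plan <- makeSplits(d$labeled, repeats = 1, seed = 2)[[1]]
  real <- evaluateSplit(d$labeled, plan, seed = 6)
  perm <- evaluateSplit(permuteLabels(d$labeled, seed = 3), plan, seed = 6)
  baReal <- metricScores(real$metrics)["balanced_accuracy"]
  baPerm <- metricScores(perm$metrics)["balanced_accuracy"]
  expect_gt(baReal, unname(baPerm))
  expect_gte(unname(baReal), 0.9)
})

test_that("learning curve improves with training fraction and is reproducible", {
  d <- generateSynthetic(syntheticPreset("separable", seed = 17,
                                         nBitter = 30, nNonbitter = 30))
  lc1 <- learningCurve(d$labeled, fractions = c(0.15, 1), repeats = 2,
                       seed = 21, params = list(num_trees = 100L))
  lc2 <- learningCurve(d$labeled, fractions = c(0.15, 1), repeats = 2,
                       seed = 21, params = list(num_trees = 100L))
  expect_equal(lc1, lc2)
  expect_lte(lc1$mean_ba[1], lc1$mean_ba[2] + 0.05)
})
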