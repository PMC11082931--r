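test_that("confusion counts agree with an independent tabulation", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    truth <- sample(c("bitter", "nonbitter"), n, replace = TRUE)
    pred <- sample(c("bitter", "nonbitter"), n, replace = TRUE)
    cm <- confusionCounts(truth, pred)
    v <- confusionVector(cm)
    tab <- table(factor(truth, c("bitter", "nonbitter")),
                 factor(pred, c("bitter", "nonbitter")))
    expect_equal(unname(v), c(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]))
    expect_equal(sum(v), n)
    # metric identities
    sc <- metricScores(cm)
    with(as.list(v), {
      if (tp + fp > 0) expect_equal(unname(sc["precision"]), tp / (tp + fp))
      if (tp + fn > 0) expect_equal(unname(sc["recall"]), tp / (tp + fn))
      if (tn + fp > 0) expect_equal(unname(sc["specificity"]), tn / (tn + fp))
      expect_equal(unname(sc["accuracy"]), (tp + tn) / n)
      if (tp + fn > 0 && tn + fp > 0)
        expect_equal(unname(sc["balanced_accuracy"]),
                     (tp / (tp + fn) + tn / (tn + fp)) / 2)
    })
  }
})

test_that("edge-case confusion matrices score as expected", {
  truth <- rep(c("bitter", "nonbitter"), c(4, 2))
  perfect <- metricScores(confusionCounts(truth, truth))
  expect_equal(unname(perfect[c("precision", "recall", "balanced_accuracy",
                                "f1", "accuracy")]), rep(1, 5))
  # everything called bitter on a 2/3-bitter set
  all_b <- metricScores(confusionCounts(truth, rep("bitter", 6)))
  expect_equal(unname(all_b["recall"]), 1)
  expect_equal(unname(all_b["precision"]), 2 / 3)
  expect_equal(unname(all_b["specificity"]), 0)
  expect_equal(unname(all_b["balanced_accuracy"]), 0.5)
  # undefined ratios are NaN, never 0
  none <- metricScores(confusionCounts(rep("nonbitter", 3),
                                       rep("nonbitter", 3)))
  expect_true(is.nan(none["precision"]))
  expect_true(is.nan(none["recall"]))
  expect_error(confusionCounts(truth, truth[-1]), "equal length")
})

test_that("F1 recomputed from printed precision/recall matches printed tables", {
  f1of <- function(p, r) {
    cmLike <- 2 * p * r / (p + r)
    floor(cmLike * 100 + 0.5) / 100
  }
  # external set 1, external set 2, single-spectrum-per-compound runs
  expect_equal(f1of(0.67, 0.93), 0.78)
  expect_equal(f1of(0.58, 0.99), 0.73)
  expect_equal(f1of(0.66, 0.93), 0.77)
})

test_that("printed compound-level metrics invert to a unique confusion matrix", {
  fits <- inferConfusionMatrix(nPos = 67, nNeg = 39, precision = 0.67,
                               recall = 0.93, balanced_accuracy = 0.57)
  expect_equal(nrow(fits), 1L)
  expect_equal(as.integer(fits[1, ]), c(62L, 5L, 31L, 8L))
  # and that matrix reproduces the printed F1 too
  sc <- metricScores(new("ConfusionMetrics", tp = 62L, fn = 5L, fp = 31L,
                         tn = 8L))
  expect_equal(floor(sc[["f1"]] * 100 + 0.5) / 100, 0.78)
})

test_that("trivial and contradictory inversions behave", {
  exact <- inferConfusionMatrix(nPos = 12, nNeg = 9, precision = 1,
                                recall = 1, specificity = 1)
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$tp, 12L)
  expect_equal(exact$tn, 9L)
  none <- inferConfusionMatrix(nPos = 10, nNeg = 10, precision = 0,
                               recall = 1)
  expect_equal(nrow(none), 0L)
})

test_that("inversion is the inverse of counting + rounding on random matrices", {
  set.seed(31)
  for (i in 1:15) {
    nPos <- sample(5:40, 1); nNeg <- sample(5:40, 1)
    tp <- sample(0:nPos, 1); fp <- sample(0:nNeg, 1)
    sc <- metricScores(new("ConfusionMetrics", tp = tp, fp = fp,
                           fn = nPos - tp, tn = nNeg - fp))
    r2 <- function(x) if (is.nan(x)) NULL else floor(x * 100 + 0.5) / 100
    fits <- inferConfusionMatrix(nPos, nNeg, precision = r2(sc[["precision"]]),
                                 recall = r2(sc[["recall"]]),
                                 balanced_accuracy = r2(sc[["balanced_accuracy"]]),
                                 f1 = r2(sc[["f1"]]))
    expect_true(any(fits$tp == tp & fits$fp == fp))
  }
})

test_that("averaged curves: identical repeats give a zero-width band", {
  truth <- rep(c("bitter", "nonbitter"), 30)
  scores <- seq(1, 0, length.out = 60)
  cs <- averageCurves(list(scores, scores, scores), list(truth, truth, truth),
                      type = "roc", nBoot = 200, seed = 1)
  expect_equal(cs@lower, cs@mean)
  expect_equal(cs@upper, cs@mean)
})

test_that("perfect scores give AUC 1 and random scores hover at 0.5", {
  set.seed(2)
  truth <- sample(rep(c("bitter", "nonbitter"), 100))
  perfect <- as.numeric(truth == "bitter")
  cs <- averageCurves(list(perfect, perfect), list(truth, truth),
                      type = "roc", nBoot = 100, seed = 1)
  expect_equal(unique(cs@auc), 1)

  rnd <- lapply(1:20, function(i) runif(200))
  tr <- lapply(1:20, function(i) sample(rep(c("bitter", "nonbitter"), 100)))
  rc <- averageCurves(rnd, tr, type = "roc", nBoot = 100, seed = 3)
  expect_equal(mean(rc@auc), 0.5, tolerance = 0.05)
  # PR curve of a random scorer hovers at the prevalence
  pc <- averageCurves(rnd, tr, type = "pr", nBoot = 100, seed = 3)
  expect_equal(mean(pc@auc), 0.5, tolerance = 0.07)
})

test_that("single-class repeats are excluded with a warning", {
  truth <- rep(c("bitter", "nonbitter"), 10)
  oneClass <- rep("bitter", 20)
  expect_warning(
    cs <- averageCurves(list(runif(20), runif(20), runif(20)),
                        list(truth, truth, oneClass), nBoot = 50),
    "single class")
  expect_length(cs@auc, 2)
})

test_that("trapezoidal ROC AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  truth <- sample(rep(c("bitter", "nonbitter"), 50))
  scores <- runif(100) + 0.3 * (truth == "bitter")
  cs <- averageCurves(list(scores, scores), list(truth, truth),
                      type = "roc", nBoot = 50, seed = 1)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("nonbitter", "bitter"),
    direction = "<", quiet = TRUE)))
  expect_equal(cs@auc[1], ref, tolerance = 1e-8)
})

test_that("bin popularity counts peaks per class and flags the surplus", {
  entries <- data.frame(compound_key = c("B1", "N1"),
                        label = c("bitter", "nonbitter"))
  s <- SpectrumSet(
    data.frame(accession = c("b1", "b2", "n1"),
               compound_key = c("B1", "B1", "N1"),
               ms_type = "EI-MS", ion_mode = "unknown"),
    list(cbind(c(100.02, 100.05), c(1, 1)),   # 2 bitter peaks in bin 1
         cbind(100.07, 1),                    # +1 bitter peak in bin 1
         cbind(c(100.03, 150.0), c(1, 1))))   # 1 nonbitter in bin 1
  lss <- attachSpectra(entries, s)
  schema <- buildBinSchema(spectra(lss), width = 0.1)
  pop <- binPopularity(lss, schema)
  b1 <- pop[pop$bin == 1, ]
  expect_equal(b1$bitter, 3)
  expect_equal(b1$nonbitter, 1)
  expect_equal(b1$surplus, "bitter")
  # conservation: totals equal in-range peaks per class
  expect_equal(sum(pop$bitter), 3)
  expect_equal(sum(pop$nonbitter), 2)
  # a bin with no peaks counts (0, 0)
  empty <- pop[pop$bitter == 0 & pop$nonbitter == 0, ]
  expect_true(all(empty$surplus == "none"))
})
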