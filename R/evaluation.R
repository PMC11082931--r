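## Confusion-count bookkeeping, the six derived metrics, averaged ROC and
## precision-recall curves with bootstrap bands over repeated splits, a
## consistency checker that inverts rounded printed metrics back to
## integer confusion matrices, and per-class bin popularity counts.

#' Confusion counts from label vectors
#'
#' "bitter" is the positive class. Derived scores are available through
#' [metricScores()].
#'
#' @param truth,predicted equal-length label vectors
#'   (`"bitter"`/`"nonbitter"`).
#' @return A [ConfusionMetrics-class].
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- checkLabels(truth); predicted <- checkLabels(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  new("ConfusionMetrics",
      tp = sum(truth == "bitter" & predicted == "bitter"),
      fp = sum(truth == "nonbitter" & predicted == "bitter"),
      fn = sum(truth == "bitter" & predicted == "nonbitter"),
      tn = sum(truth == "nonbitter" & predicted == "nonbitter"))
}

#' @describeIn confusionCounts the six derived scores: precision, recall
#'   (sensitivity), specificity, accuracy, balanced accuracy and F1. A
#'   zero-denominator ratio is reported as `NaN`, never as 0.
#' @param object A [ConfusionMetrics-class].
#' @param ... unused.
#' @export
setMethod("metricScores", "ConfusionMetrics", function(object, ...) {
  tp <- object@tp; fp <- object@fp; fn <- object@fn; tn <- object@tn
  div <- function(a, b) if (b == 0) NaN else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  c(precision = precision, recall = recall, specificity = specificity,
    accuracy = div(tp + tn, tp + fp + fn + tn),
    balanced_accuracy = (recall + specificity) / 2,
    f1 = if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
      NaN else 2 * precision * recall / (precision + recall))
})

#' Recover integer confusion matrices from rounded printed metrics
#'
#' Published tables report metrics rounded to two decimals. Given the
#' class sizes, this enumerates every integer confusion matrix
#' (`tp` in 0..nPos, `fp` in 0..nNeg) and returns those whose
#' half-up-rounded metrics match every supplied value - a consistency
#' check for printed tables, and, when the solution is unique, an exact
#' reconstruction of the underlying counts.
#'
#' @param nPos,nNeg positive (bitter) and negative class sizes.
#' @param precision,recall,specificity,accuracy,balanced_accuracy,f1
#'   printed values to match (any subset; `NULL` = unconstrained).
#' @param digits decimals the table was rounded to (default 2).
#' @return `data.frame` with columns `tp`, `fn`, `fp`, `tn`, one row per
#'   feasible matrix (zero rows flags an inconsistent table).
#' @export
inferConfusionMatrix <- function(nPos, nNeg, precision = NULL, recall = NULL,
                                 specificity = NULL, accuracy = NULL,
                                 balanced_accuracy = NULL, f1 = NULL,
                                 digits = 2) {
  want <- list(precision = precision, recall = recall,
               specificity = specificity, accuracy = accuracy,
               balanced_accuracy = balanced_accuracy, f1 = f1)
  want <- want[!vapply(want, is.null, logical(1))]
  nPos <- as.integer(nPos); nNeg <- as.integer(nNeg)
  out <- list()
  for (tp in 0:nPos) for (fp in 0:nNeg) {
    cm <- new("ConfusionMetrics", tp = tp, fp = as.integer(fp),
              fn = nPos - tp, tn = as.integer(nNeg - fp))
    sc <- metricScores(cm)
    ok <- all(vapply(names(want), function(nm) {
      v <- sc[[nm]]
      !is.nan(v) && roundHalfUp(v, digits) == want[[nm]]
    }, logical(1)))
    if (ok) out[[length(out) + 1L]] <- c(tp = tp, fn = nPos - tp,
                                         fp = fp, tn = nNeg - fp)
  }
  if (length(out) == 0)
    return(data.frame(tp = integer(0), fn = integer(0), fp = integer(0),
                      tn = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# One repeat's curve interpolated onto a common x grid.
# ROC: TPR over FPR, linear interpolation between operating points.
# PR: interpolated-precision envelope over recall (max precision among
# operating points with recall >= r), the standard step-wise convention.
curveOnGrid <- function(scores, truth, grid, type) {
  y <- truth == "bitter"
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  nPos <- sum(y); nNeg <- sum(!y)
  if (type == "roc") {
    fpr <- c(0, fp / nNeg); tpr <- c(0, tp / nPos)
    list(y = approx(fpr, tpr, xout = grid, method = "linear",
                    ties = max, rule = 2)$y,
         auc = sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2))
  } else {
    rec <- tp / nPos; prec <- tp / (tp + fp)
    env <- vapply(grid, function(r) {
      ok <- rec >= r - 1e-12
      if (!any(ok)) 0 else max(prec[ok])
    }, numeric(1))
    # average precision: sum of precision at each new positive found
    ap <- sum(prec[y] * (1 / nPos))
    list(y = env, auc = ap)
  }
}

#' Average classifier curves over repeated splits
#'
#' Each repeat's ROC (or precision-recall) curve is interpolated onto a
#' common grid; the mean curve and a 95% percentile bootstrap band for
#' the mean are computed pointwise by resampling the repeats (not the
#' individual spectra - the uncertainty quantified is across splits).
#' Repeats whose truth contains a single class are excluded with a
#' warning.
#'
#' @param scoreList list (one element per repeat) of per-spectrum
#'   `p_bitter` scores.
#' @param truthList matching list of truth label vectors.
#' @param type `"roc"` or `"pr"`.
#' @param gridStep x-axis grid step (default 0.01).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return A [CurveSummary-class]; `@auc` holds one area per repeat
#'   (trapezoidal AUC for ROC, average precision for PR).
#' @export
averageCurves <- function(scoreList, truthList, type = c("roc", "pr"),
                          gridStep = 0.01, nBoot = 1000, seed = 1) {
  type <- match.arg(type)
  stopifnot(length(scoreList) == length(truthList))
  ok <- vapply(truthList, function(t)
    length(unique(checkLabels(t))) == 2, logical(1))
  if (!all(ok))
    warning("excluding ", sum(!ok), " repeat(s) with a single class")
  scoreList <- scoreList[ok]; truthList <- truthList[ok]
  if (length(scoreList) < 2)
    stop("need at least two usable repeats to average curves")
  grid <- seq(0, 1, by = gridStep)
  curves <- mapply(function(s, t) curveOnGrid(s, t, grid, type),
                   scoreList, truthList, SIMPLIFY = FALSE)
  ymat <- do.call(rbind, lapply(curves, `[[`, "y"))
  meanCurve <- colMeans(ymat)
  R <- nrow(ymat)
  bootMeans <- withSeed(seed, {
    idx <- matrix(sample.int(R, R * nBoot, replace = TRUE), nrow = nBoot)
    t(apply(idx, 1, function(ii) colMeans(ymat[ii, , drop = FALSE])))
  })
  band <- apply(bootMeans, 2, quantile, probs = c(0.025, 0.975))
  new("CurveSummary", type = type, grid = grid, mean = meanCurve,
      lower = pmin(band[1, ], meanCurve), upper = pmax(band[2, ], meanCurve),
      auc = vapply(curves, `[[`, numeric(1), "auc"))
}

#' Per-class peak popularity of selected bins
#'
#' Counts peaks (not spectra) per class falling into each requested bin,
#' and flags which class has the surplus - the companion view to the
#' importance ranking, showing whether an important bin is populated
#' mostly by bitter or by nonbitter spectra.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param schema A [BinSchema-class].
#' @param bins bin indices (into the full grid) to count; defaults to all
#'   retained bins.
#' @return `data.frame` with columns `bin`, `label`, `bitter`,
#'   `nonbitter`, `surplus`.
#' @export
binPopularity <- function(x, schema, bins = retainedBins(schema)) {
  labs <- spectrumLabels(x)
  counts <- sapply(CLASS_LEVELS, function(cl) {
    pk <- do.call(rbind, peaksList(spectra(x))[labs == cl])
    v <- integer(schema@nBinsTotal)
    if (!is.null(pk) && nrow(pk) > 0) {
      idx <- binIndex(pk[, 1], schema@origin, schema@width)
      idx <- idx[idx >= 1L & idx <= schema@nBinsTotal]
      tab <- table(idx)
      v[as.integer(names(tab))] <- as.integer(tab)
    }
    v[bins]
  })
  counts <- matrix(counts, ncol = 2,
                   dimnames = list(NULL, CLASS_LEVELS))
  lo <- schema@origin + (bins - 1L) * schema@width
  data.frame(
    bin = bins,
    label = sprintf("[%s to %s]", formatMz(lo), formatMz(lo + schema@width)),
    bitter = counts[, "bitter"],
    nonbitter = counts[, "nonbitter"],
    surplus = ifelse(counts[, "bitter"] > counts[, "nonbitter"], "bitter",
                     ifelse(counts[, "bitter"] < counts[, "nonbitter"],
                            "nonbitter", "none")),
    row.names = NULL)
}

#' Mean and standard deviation of metrics over repeated splits
#'
#' @param metricsList list of [ConfusionMetrics-class], one per repeat.
#' @return `data.frame` with one row per metric (`mean`, `sd`).
#' @export
summarizeMetrics <- function(metricsList) {
  sc <- do.call(rbind, lapply(metricsList, metricScores))
  data.frame(metric = colnames(sc),
             mean = colMeans(sc, na.rm = TRUE),
             sd = apply(sc, 2, sd, na.rm = TRUE),
             row.names = NULL)
}
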