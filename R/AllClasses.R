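#' SpectrumSet: a collection of experimental mass spectra
#'
#' Container pairing per-spectrum metadata (a [S4Vectors::DataFrame] with
#' columns `accession`, `compound_key`, `smiles`, `ms_type`, `ion_mode`,
#' `collision_energy_eV`) with a list of peak matrices (two columns,
#' `mz` and `intensity`, rows sorted by ascending m/z, ties broken by
#' descending intensity). A collision energy of 0 encodes "unknown".
#'
#' @slot meta `DataFrame` of per-spectrum metadata, one row per spectrum.
#' @slot peaks `list` of numeric matrices, one per spectrum.
#'
#' @section Invariants:
#' Accessions are unique within the set; every peak has `mz > 0` and
#' `intensity >= 0`; peaks are sorted ascending by m/z.
#'
#' @export
setClass("SpectrumSet",
  representation(meta = "DataFrame", peaks = "list"))

MS_TYPES <- c("EI-MS", "ESI-MS/MS", "other")
ION_MODES <- c("positive", "negative", "unknown")
CLASS_LEVELS <- c("nonbitter", "bitter")

setValidity("SpectrumSet", function(object) {
  m <- object@meta
  need <- c("accession", "compound_key", "smiles", "ms_type", "ion_mode",
            "collision_energy_eV")
  if (!all(need %in% colnames(m)))
    return(paste("meta must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) != length(object@peaks))
    return("number of metadata rows must equal number of peak matrices")
  if (anyDuplicated(m$accession))
    return("duplicate accessions within a SpectrumSet")
  if (!all(m$ms_type %in% MS_TYPES))
    return("ms_type values must be one of EI-MS, ESI-MS/MS, other")
  if (!all(m$ion_mode %in% ION_MODES))
    return("ion_mode values must be one of positive, negative, unknown")
  if (any(m$collision_energy_eV < 0))
    return("collision_energy_eV must be >= 0 (0 encodes unknown)")
  for (p in object@peaks) {
    if (!is.matrix(p) || ncol(p) != 2)
      return("each peak entry must be a two-column matrix (mz, intensity)")
    if (nrow(p) > 0) {
      if (any(p[, 1] <= 0)) return("all m/z values must be positive")
      if (any(p[, 2] < 0)) return("all intensities must be nonnegative")
      if (is.unsorted(p[, 1])) return("peaks must be sorted ascending by m/z")
    }
  }
  TRUE
})

#' Construct a SpectrumSet
#'
#' @param meta `data.frame` or `DataFrame` of per-spectrum metadata. Missing
#'   optional columns (`smiles`, `collision_energy_eV`) are filled with
#'   defaults (`NA`, `0`).
#' @param peaks list of two-column matrices or data.frames (`mz`,
#'   `intensity`), one per metadata row. Peaks are sorted on construction.
#' @return A [SpectrumSet-class] object.
#' @examples
#' s <- SpectrumSet(
#'   data.frame(accession = "A1", compound_key = "K1",
#'              ms_type = "EI-MS", ion_mode = "unknown"),
#'   list(cbind(mz = c(77, 51), intensity = c(100, 40))))
#' peaksList(s)[[1]]
#' @export
SpectrumSet <- function(meta, peaks) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  meta <- S4Vectors::DataFrame(meta)
  if (is.null(meta$smiles)) meta$smiles <- NA_character_
  meta$smiles <- as.character(meta$smiles)
  if (is.null(meta$collision_energy_eV)) meta$collision_energy_eV <- 0
  meta$collision_energy_eV <- as.numeric(meta$collision_energy_eV)
  canonical <- c("accession", "compound_key", "smiles", "ms_type",
                 "ion_mode", "collision_energy_eV")
  meta <- meta[, c(canonical, setdiff(colnames(meta), canonical)),
               drop = FALSE]
  peaks <- lapply(peaks, sortPeaks)
  new("SpectrumSet", meta = meta, peaks = unname(peaks))
}

# ascending m/z, ties by descending intensity (deterministic ordering)
sortPeaks <- function(p) {
  p <- as.matrix(as.data.frame(p))
  if (ncol(p) != 2) stop("peak matrix must have two columns (mz, intensity)")
  dimnames(p) <- list(NULL, c("mz", "intensity"))
  storage.mode(p) <- "double"
  p[order(p[, 1], -p[, 2]), , drop = FALSE]
}

#' @rdname bitterspec-generics
#' @export
setMethod("accessions", "SpectrumSet", function(x) x@meta$accession)
#' @rdname bitterspec-generics
#' @export
setMethod("compoundKeys", "SpectrumSet", function(x) x@meta$compound_key)
#' @rdname bitterspec-generics
#' @export
setMethod("msTypes", "SpectrumSet", function(x) x@meta$ms_type)
#' @rdname bitterspec-generics
#' @export
setMethod("ionModes", "SpectrumSet", function(x) x@meta$ion_mode)
#' @rdname bitterspec-generics
#' @export
setMethod("collisionEnergies", "SpectrumSet", function(x) x@meta$collision_energy_eV)
#' @rdname bitterspec-generics
#' @export
setMethod("peaksList", "SpectrumSet", function(x) x@peaks)
#' @rdname bitterspec-generics
#' @export
setMethod("spectrumMeta", "SpectrumSet", function(x) x@meta)

#' @describeIn SpectrumSet-class number of spectra in the set.
#' @param x A `SpectrumSet`.
#' @export
setMethod("length", "SpectrumSet", function(x) nrow(x@meta))

#' @describeIn SpectrumSet-class subset spectra by index, accession or
#'   logical mask.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@meta$accession)
  new("SpectrumSet", meta = x@meta[i, , drop = FALSE], peaks = x@peaks[i])
})

setMethod("show", "SpectrumSet", function(object) {
  n <- length(object)
  cat("SpectrumSet with", n, "spectra\n")
  if (n > 0) {
    cat("  ms_type:", paste(sprintf("%s (%d)", names(table(msTypes(object))),
        table(msTypes(object))), collapse = ", "), "\n")
    cat("  compounds:", length(unique(compoundKeys(object))), "\n")
    np <- vapply(object@peaks, nrow, integer(1))
    cat("  peaks per spectrum: median", stats::median(np),
        sprintf("[%d-%d]", min(np), max(np)), "\n")
  }
})

#' Concatenate SpectrumSet objects
#' @param x,... `SpectrumSet` objects.
#' @return A combined [SpectrumSet-class].
#' @export
setMethod("c", "SpectrumSet", function(x, ...) {
  sets <- c(list(x), list(...))
  new("SpectrumSet",
      meta = do.call(rbind, lapply(sets, function(s) s@meta)),
      peaks = do.call(c, lapply(sets, function(s) s@peaks)))
})

#' BinSchema: frozen m/z interval grid learned from a training set
#'
#' Half-open fixed-width intervals `[lo, lo + width)` tiling the m/z range
#' of the training peaks. After empty-bin pruning, `retained` records which
#' bin indices survive; the schema is then frozen and reused unchanged at
#' prediction time.
#'
#' @slot origin lowest bin edge (Th).
#' @slot width bin width (Th), default 0.1.
#' @slot nBinsTotal number of bins before pruning.
#' @slot retained strictly increasing integer vector of kept bin indices.
#' @export
setClass("BinSchema",
  representation(origin = "numeric", width = "numeric",
                 nBinsTotal = "integer", retained = "integer"))

setValidity("BinSchema", function(object) {
  if (length(object@width) != 1 || object@width <= 0)
    return("width must be a single positive number")
  if (object@nBinsTotal < 1L) return("schema must have at least one bin")
  r <- object@retained
  if (length(r) == 0) return("retained must be nonempty")
  if (is.unsorted(r, strictly = TRUE)) return("retained must be strictly increasing")
  if (min(r) < 1L || max(r) > object@nBinsTotal)
    return("retained indices out of range")
  TRUE
})

#' @rdname bitterspec-generics
#' @export
setMethod("retainedBins", "BinSchema", function(x) x@retained)

#' @rdname bitterspec-generics
#' @export
setMethod("binEdges", "BinSchema", function(x)
  x@origin + x@width * (0:x@nBinsTotal))

#' @rdname bitterspec-generics
#' @export
setMethod("binLabels", "BinSchema", function(x) {
  lo <- x@origin + (x@retained - 1L) * x@width
  sprintf("[%s to %s]", formatMz(lo), formatMz(lo + x@width))
})

formatMz <- function(x) {
  out <- format(round(x, 4), trim = TRUE, scientific = FALSE)
  # keep at least one decimal so labels read as interval limits
  ifelse(grepl("\\.", out), out, paste0(out, ".0"))
}

setMethod("show", "BinSchema", function(object) {
  cat(sprintf("BinSchema: %d/%d bins retained, width %g Th, range [%g, %g)\n",
      length(object@retained), object@nBinsTotal, object@width,
      object@origin, object@origin + object@nBinsTotal * object@width))
})

#' InstrumentVocab: natural-number codes for instrument categories
#'
#' MS type and ion mode are coded as natural numbers (starting at 1) fixed
#' at training time and persisted with the model; categories unseen in
#' training map to the reserved code 0 at prediction time.
#'
#' @slot msTypeCodes named integer vector.
#' @slot ionModeCodes named integer vector.
#' @export
setClass("InstrumentVocab",
  representation(msTypeCodes = "integer", ionModeCodes = "integer"))

setValidity("InstrumentVocab", function(object) {
  for (v in list(object@msTypeCodes, object@ionModeCodes)) {
    if (length(v) == 0) return("code maps must be nonempty")
    if (is.null(names(v)) || any(!nzchar(names(v))))
      return("code maps must be named")
    if (any(v < 1L) || anyDuplicated(v))
      return("codes must be distinct positive integers")
  }
  TRUE
})

setMethod("show", "InstrumentVocab", function(object) {
  cat("InstrumentVocab\n  ms_type: ",
      paste(sprintf("%s=%d", names(object@msTypeCodes), object@msTypeCodes),
            collapse = ", "),
      "\n  ion_mode:",
      paste(sprintf("%s=%d", names(object@ionModeCodes), object@ionModeCodes),
            collapse = ", "), "\n")
})

#' LabeledSpectrumSet: spectra joined with compound-level taste labels
#'
#' Holds a [SpectrumSet-class] plus a compound table (`compound_key`,
#' `label`) restricted to compounds that have at least one spectrum.
#'
#' @slot spectra the spectra.
#' @slot compounds `DataFrame` with columns `compound_key`, `label`.
#' @export
setClass("LabeledSpectrumSet",
  representation(spectra = "SpectrumSet", compounds = "DataFrame"))

setValidity("LabeledSpectrumSet", function(object) {
  cmp <- object@compounds
  if (!all(c("compound_key", "label") %in% colnames(cmp)))
    return("compounds must have columns compound_key, label")
  if (anyDuplicated(cmp$compound_key)) return("duplicate compound keys")
  if (!all(cmp$label %in% CLASS_LEVELS))
    return("labels must be 'bitter' or 'nonbitter'")
  sk <- unique(compoundKeys(object@spectra))
  if (!setequal(sk, cmp$compound_key))
    return("compound table must exactly cover compounds with spectra")
  TRUE
})

#' @rdname bitterspec-generics
#' @export
setMethod("spectra", "LabeledSpectrumSet", function(x) x@spectra)
#' @rdname bitterspec-generics
#' @export
setMethod("compoundTable", "LabeledSpectrumSet", function(x) x@compounds)
#' @describeIn LabeledSpectrumSet-class number of spectra.
#' @param x A `LabeledSpectrumSet`.
#' @export
setMethod("length", "LabeledSpectrumSet", function(x) length(x@spectra))

setMethod("show", "LabeledSpectrumSet", function(object) {
  s <- compositionSummary(object)
  cat("LabeledSpectrumSet\n")
  print(s)
})

#' SplitPlan: one compound-level train/test partition
#'
#' @slot repeatIndex 1-based repeat number.
#' @slot seed RNG seed used to draw this plan.
#' @slot trainKeys,testKeys disjoint compound-key sets covering all
#'   compounds with spectra.
#' @slot by `"compound"` (leakage-free) or `"spectrum"` (keys are
#'   accessions; used only to demonstrate leakage).
#' @export
setClass("SplitPlan",
  representation(repeatIndex = "integer", seed = "integer",
                 trainKeys = "character", testKeys = "character",
                 by = "character"))

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@trainKeys, object@testKeys)) > 0)
    return("train and test keys must be disjoint")
  if (length(object@testKeys) == 0 || length(object@trainKeys) == 0)
    return("both sides of the split must be nonempty")
  TRUE
})

#' @rdname bitterspec-generics
#' @export
setMethod("trainKeys", "SplitPlan", function(x) x@trainKeys)
#' @rdname bitterspec-generics
#' @export
setMethod("testKeys", "SplitPlan", function(x) x@testKeys)

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan #%d (%s-level): %d train / %d test keys, seed %d\n",
      object@repeatIndex, object@by, length(object@trainKeys),
      length(object@testKeys), object@seed))
})

#' BitterModel: trained spectrum-to-bitterness classifier bundle
#'
#' Self-sufficient for prediction: carries the fitted ensemble, the frozen
#' [BinSchema-class], the [InstrumentVocab-class], the peak-descriptor
#' strategy and the training prevalence of bitter spectra.
#'
#' @slot algorithm `"randomForest"` or `"xgboost"`.
#' @slot params hyperparameters used for the fit.
#' @slot fit fitted ensemble object.
#' @slot schema,vocab frozen featurization state.
#' @slot strategy `"intensity"`, `"binary"` or `"count"`.
#' @slot prevalence training fraction of bitter spectra.
#' @slot importance named per-feature importance fractions (sum to 1).
#' @slot seed training seed.
#' @export
setClass("BitterModel",
  representation(algorithm = "character", params = "list", fit = "ANY",
                 schema = "BinSchema", vocab = "InstrumentVocab",
                 strategy = "character", prevalence = "numeric",
                 importance = "numeric", seed = "integer"))

setValidity("BitterModel", function(object) {
  if (!object@algorithm %in% c("randomForest", "xgboost"))
    return("algorithm must be randomForest or xgboost")
  if (!object@strategy %in% c("intensity", "binary", "count"))
    return("strategy must be intensity, binary or count")
  imp <- object@importance
  if (length(imp) > 0) {
    if (any(imp < -1e-12)) return("importance entries must be nonnegative")
    if (abs(sum(imp) - 1) > 1e-6) return("importance must sum to 1")
  }
  TRUE
})

#' @rdname bitterspec-generics
#' @export
setMethod("featureImportance", "BitterModel", function(object) object@importance)
#' @rdname bitterspec-generics
#' @export
setMethod("binSchema", "BitterModel", function(object) object@schema)
#' @rdname bitterspec-generics
#' @export
setMethod("instrumentVocab", "BitterModel", function(object) object@vocab)

setMethod("show", "BitterModel", function(object) {
  cat(sprintf("BitterModel (%s, strategy=%s)\n", object@algorithm,
              object@strategy))
  cat(sprintf("  features: %d (3 instrument + %d bins)\n",
      length(object@importance), length(object@schema@retained)))
  cat(sprintf("  training prevalence of bitter spectra: %.3f\n",
      object@prevalence))
})

#' NaiveModel: prevalence-based baseline classifier
#'
#' Predicts every spectrum bitter with a fixed probability equal to the
#' training prevalence of bitter spectra, independent of the spectrum
#' itself; its expected balanced accuracy is 0.5 for any prevalence.
#'
#' @slot pBitter probability in \[0, 1\].
#' @export
setClass("NaiveModel", representation(pBitter = "numeric"))

setValidity("NaiveModel", function(object) {
  p <- object@pBitter
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    return("pBitter must be a single probability in [0, 1]")
  TRUE
})

setMethod("show", "NaiveModel", function(object)
  cat(sprintf("NaiveModel: P(bitter) = %.2f\n", object@pBitter)))

#' ConfusionMetrics: confusion counts with derived scores
#'
#' @slot tp,fp,fn,tn nonnegative integer confusion counts ("bitter" is the
#'   positive class).
#' @export
setClass("ConfusionMetrics",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer"))

setValidity("ConfusionMetrics", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) return("confusion counts must be nonnegative")
  TRUE
})

#' @rdname bitterspec-generics
#' @export
setMethod("confusionVector", "ConfusionMetrics", function(object)
  c(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn))

setMethod("show", "ConfusionMetrics", function(object) {
  cat(sprintf("ConfusionMetrics (tp=%d fp=%d fn=%d tn=%d)\n",
      object@tp, object@fp, object@fn, object@tn))
  print(round(metricScores(object), 4))
})

#' CurveSummary: mean classifier curve with bootstrap band over splits
#'
#' @slot type `"roc"` or `"pr"`.
#' @slot grid x-axis grid (false-positive rate or recall, increasing).
#' @slot mean,lower,upper mean curve and 95% bootstrap band (pointwise).
#' @slot auc per-repeat area-under-curve values.
#' @export
setClass("CurveSummary",
  representation(type = "character", grid = "numeric", mean = "numeric",
                 lower = "numeric", upper = "numeric", auc = "numeric"))

setValidity("CurveSummary", function(object) {
  if (is.unsorted(object@grid, strictly = TRUE))
    return("grid must be strictly increasing")
  n <- length(object@grid)
  if (length(object@mean) != n || length(object@lower) != n ||
      length(object@upper) != n)
    return("curve vectors must match grid length")
  if (any(object@lower > object@mean + 1e-9) ||
      any(object@upper < object@mean - 1e-9))
    return("band must contain the mean pointwise")
  TRUE
})

setMethod("show", "CurveSummary", function(object) {
  cat(sprintf("CurveSummary (%s): %d repeats, mean AUC %.3f (sd %.3f)\n",
      toupper(object@type), length(object@auc), mean(object@auc),
      sd(object@auc)))
})

#' PredictionResult: per-spectrum votes aggregated to one compound label
#'
#' @slot perSpectrum `data.frame` with columns `accession`, `p_bitter`,
#'   `label`.
#' @slot compoundKey the compound the votes belong to.
#' @slot compoundLabel majority-vote label.
#' @slot nBitterVotes,nNonbitterVotes vote counts (sum to spectra count).
#' @slot tieBroken `TRUE` if the label came from the seeded coin flip.
#' @export
setClass("PredictionResult",
  representation(perSpectrum = "data.frame", compoundKey = "character",
                 compoundLabel = "character", nBitterVotes = "integer",
                 nNonbitterVotes = "integer", tieBroken = "logical"))

setValidity("PredictionResult", function(object) {
  if (object@nBitterVotes + object@nNonbitterVotes != nrow(object@perSpectrum))
    return("votes must sum to the number of spectra")
  if (!object@compoundLabel %in% CLASS_LEVELS)
    return("compoundLabel must be bitter or nonbitter")
  if (!object@tieBroken) {
    maj <- if (object@nBitterVotes > object@nNonbitterVotes) "bitter" else "nonbitter"
    if (object@compoundLabel != maj)
      return("compoundLabel must be the vote majority unless tieBroken")
  }
  TRUE
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult for %s: %s (%d bitter / %d nonbitter votes%s)\n",
      object@compoundKey, object@compoundLabel, object@nBitterVotes,
      object@nNonbitterVotes,
      if (object@tieBroken) ", tie broken at random" else ""))
})
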