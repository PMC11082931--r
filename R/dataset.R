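## Labeled-compound assembly and repeated compound-level splitting.
##
## Compounds are identified by full-length InChIKey (or a surrogate key);
## duplicates across sources are collapsed and label conflicts dropped.
## Train/test partitions are drawn by compound, stratified within class,
## so that all spectra of one compound fall on the same side of the split.

#' Deduplicate labeled compounds by key
#'
#' Collapses repeated entries of one compound key. If the same key carries
#' conflicting labels across sources the compound is dropped entirely with
#' a warning: taste-label conflicts cannot be adjudicated automatically.
#'
#' @param entries `data.frame` with columns `compound_key`, `label`, and
#'   optionally `smiles`, `source`.
#' @return Deduplicated `data.frame`, one row per compound key.
#' @export
dedupCompounds <- function(entries) {
  entries$label <- checkLabels(entries$label)
  if (is.null(entries$smiles)) entries$smiles <- NA_character_
  if (is.null(entries$source)) entries$source <- NA_character_
  keys <- unique(entries$compound_key)
  nlab <- vapply(keys, function(k)
    length(unique(entries$label[entries$compound_key == k])), integer(1))
  conflicted <- keys[nlab > 1]
  if (length(conflicted) > 0)
    warning("dropping ", length(conflicted),
            " compound(s) with conflicting labels: ",
            paste(head(conflicted, 5), collapse = ", "),
            if (length(conflicted) > 5) ", ...")
  keep <- setdiff(keys, conflicted)
  entries[match(keep, entries$compound_key), , drop = FALSE]
}

#' Attach spectra to labeled compounds
#'
#' Joins a compound label table with a spectrum collection on
#' `compound_key`. Only compounds with at least one spectrum are kept;
#' spectra of unlabeled compounds are discarded.
#'
#' @param entries deduplicated compound `data.frame` (`compound_key`,
#'   `label`).
#' @param records A [SpectrumSet-class].
#' @return A [LabeledSpectrumSet-class].
#' @export
attachSpectra <- function(entries, records) {
  keep <- compoundKeys(records) %in% entries$compound_key
  records <- records[which(keep)]
  withSpec <- entries$compound_key %in% compoundKeys(records)
  cmp <- DataFrame(compound_key = entries$compound_key[withSpec],
                   label = entries$label[withSpec])
  new("LabeledSpectrumSet", spectra = records, compounds = cmp)
}

#' Dataset composition summary
#'
#' Per-class compound and spectrum counts, in the style of a dataset
#' composition table.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @return `data.frame` with columns `label`, `n_compounds`, `n_spectra`.
#' @export
compositionSummary <- function(x) {
  cmp <- as.data.frame(compoundTable(x))
  specLab <- spectrumLabels(x)
  out <- data.frame(
    label = CLASS_LEVELS,
    n_compounds = vapply(CLASS_LEVELS, function(l) sum(cmp$label == l), integer(1)),
    n_spectra = vapply(CLASS_LEVELS, function(l) sum(specLab == l), integer(1)),
    row.names = NULL)
  out
}

#' Per-spectrum class labels of a labeled set
#'
#' @param x A [LabeledSpectrumSet-class].
#' @return character vector, one label per spectrum.
#' @export
spectrumLabels <- function(x) {
  cmp <- compoundTable(x)
  unname(setNames(cmp$label, cmp$compound_key)[compoundKeys(spectra(x))])
}

#' Draw repeated stratified compound-level train/test splits
#'
#' Within each class independently, a fraction `testFraction` of the
#' compounds (rounded to nearest, minimum 1) is drawn into the test set;
#' the rest train. All spectra of a compound follow the compound, so no
#' spectrum of a test compound is ever seen in training. With
#' `by = "spectrum"` the partition is instead drawn over individual
#' spectra (stratified by spectrum label, keys are accessions) - this mode
#' exists to demonstrate the information leakage such splits cause and
#' should not be used for honest evaluation.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param testFraction test proportion per class (default 0.2).
#' @param repeats number of independent splits (default 20).
#' @param seed master seed; per-repeat seeds derive from it.
#' @param by `"compound"` (default) or `"spectrum"`.
#' @return list of [SplitPlan-class] objects, length `repeats`.
#' @export
makeSplits <- function(x, testFraction = 0.2, repeats = 20, seed = 1,
                       by = c("compound", "spectrum")) {
  by <- match.arg(by)
  stopifnot(testFraction > 0, testFraction < 1)
  if (by == "compound") {
    cmp <- as.data.frame(compoundTable(x))
    units <- split(cmp$compound_key, cmp$label)
  } else {
    units <- split(accessions(spectra(x)), spectrumLabels(x))
  }
  if (length(units) < 2 || any(lengths(units) < 2))
    stop("need at least 2 ", by, "s per class to split")
  seeds <- deriveSeeds(seed, repeats)
  lapply(seq_len(repeats), function(r) {
    withSeed(seeds[r], {
      test <- unlist(lapply(units, function(u) {
        nTest <- max(1L, roundHalfUp(length(u) * testFraction, 0))
        sample(u, nTest)
      }), use.names = FALSE)
      new("SplitPlan", repeatIndex = as.integer(r),
          seed = as.integer(seeds[r]),
          trainKeys = setdiff(unlist(units, use.names = FALSE), test),
          testKeys = test, by = by)
    })
  })
}

#' Spectrum row indices of one side of a split
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param plan A [SplitPlan-class].
#' @param side `"train"` or `"test"`.
#' @return integer indices into `spectra(x)`.
#' @export
splitIndices <- function(x, plan, side = c("train", "test")) {
  side <- match.arg(side)
  keys <- if (side == "train") trainKeys(plan) else testKeys(plan)
  id <- if (plan@by == "compound") compoundKeys(spectra(x)) else
    accessions(spectra(x))
  which(id %in% keys)
}
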