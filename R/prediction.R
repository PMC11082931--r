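## Applying a trained model to new spectra and aggregating per-spectrum
## predictions into one compound-level label by majority vote, with a
## seeded fair coin for exact ties.

#' Per-spectrum bitterness prediction
#'
#' New spectra are intensity-normalized (for the intensity strategy) and
#' featurized under the model's frozen bin schema and instrument
#' vocabulary; instrument categories unseen in training map to the
#' reserved code 0. A spectrum whose peaks all fall outside the trained
#' m/z range is refused with an error rather than silently classified.
#'
#' @param model A [BitterModel-class].
#' @param x A [SpectrumSet-class] of new spectra.
#' @param threshold per-spectrum decision threshold on `p_bitter`
#'   (default 0.5; a spectrum is labeled bitter iff `p_bitter >=
#'   threshold`).
#' @return `data.frame` with columns `accession`, `p_bitter`, `label`.
#' @export
predictSpectra <- function(model, x, threshold = 0.5) {
  if (length(x) == 0) stop("no spectra to predict")
  if (model@strategy == "intensity") x <- normalizeIntensities(x)
  schema <- binSchema(model)
  hi <- schema@origin + schema@nBinsTotal * schema@width
  inRange <- vapply(peaksList(x), function(p)
    sum(p[, 1] >= schema@origin & p[, 1] < hi), integer(1))
  if (any(inRange == 0))
    stop("refusing to predict spectra with no peak in the trained m/z ",
         "range: ", paste(accessions(x)[inRange == 0], collapse = ", "))
  mat <- featurizeSpectra(x, schema, instrumentVocab(model), model@strategy)
  p <- predictProbMatrix(model, mat)
  data.frame(accession = accessions(x), p_bitter = p,
             label = ifelse(p >= threshold, "bitter", "nonbitter"),
             row.names = NULL)
}

#' Majority vote over per-spectrum labels
#'
#' The compound label is the most frequent per-spectrum label; an exact
#' tie is resolved by a seeded fair coin so the outcome is reproducible
#' yet unbiased across ties.
#'
#' @param labels per-spectrum label vector.
#' @param tieSeed seed for the tie-breaking coin.
#' @return `list(label = , tieBroken = )`.
#' @export
voteLabel <- function(labels, tieSeed = 1) {
  labels <- checkLabels(labels)
  nb <- sum(labels == "bitter"); nn <- sum(labels == "nonbitter")
  if (nb != nn)
    return(list(label = if (nb > nn) "bitter" else "nonbitter",
                tieBroken = FALSE))
  list(label = withSeed(tieSeed, sample(CLASS_LEVELS, 1)), tieBroken = TRUE)
}

#' Compound-level prediction by majority vote
#'
#' Predicts every spectrum of one compound, then aggregates the
#' per-spectrum labels by majority vote ([voteLabel()]).
#'
#' @param model A [BitterModel-class].
#' @param x A [SpectrumSet-class]; all spectra must belong to one
#'   compound.
#' @param tieSeed seed for tie resolution (kept separate from the
#'   training seed so the two randomness sources are independent).
#' @param threshold per-spectrum decision threshold.
#' @return A [PredictionResult-class].
#' @export
predictCompound <- function(model, x, tieSeed = 1, threshold = 0.5) {
  if (length(x) == 0) stop("no spectra supplied for the compound")
  keys <- unique(compoundKeys(x))
  if (length(keys) > 1)
    stop("spectra of several compounds supplied; use predictCompounds()")
  per <- predictSpectra(model, x, threshold)
  v <- voteLabel(per$label, tieSeed)
  new("PredictionResult", perSpectrum = per, compoundKey = keys,
      compoundLabel = v$label,
      nBitterVotes = sum(per$label == "bitter"),
      nNonbitterVotes = sum(per$label == "nonbitter"),
      tieBroken = v$tieBroken)
}

#' Compound-level predictions for a multi-compound collection
#'
#' Groups spectra by compound key and applies [predictCompound()] to each
#' group; per-compound tie seeds derive deterministically from `tieSeed`.
#'
#' @param model A [BitterModel-class].
#' @param x A [SpectrumSet-class].
#' @param tieSeed master tie seed.
#' @param threshold per-spectrum decision threshold.
#' @return `data.frame` with one row per compound: `compound_key`,
#'   `label`, `n_bitter_votes`, `n_nonbitter_votes`, `tie_broken`.
#' @export
predictCompounds <- function(model, x, tieSeed = 1, threshold = 0.5) {
  keys <- unique(compoundKeys(x))
  seeds <- deriveSeeds(tieSeed, length(keys))
  rows <- lapply(seq_along(keys), function(i) {
    res <- predictCompound(model, x[which(compoundKeys(x) == keys[i])],
                           tieSeed = seeds[i], threshold = threshold)
    data.frame(compound_key = keys[i], label = res@compoundLabel,
               n_bitter_votes = res@nBitterVotes,
               n_nonbitter_votes = res@nNonbitterVotes,
               tie_broken = res@tieBroken)
  })
  do.call(rbind, rows)
}
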