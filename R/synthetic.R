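## Synthetic class-conditional fragment spectra.
##
## The generator emulates the structure of a curated spectral dataset:
## labeled compounds with a skewed number of spectra per compound (many
## for bitter compounds, few for nonbitter ones, as in combined
## EI + tandem collections), spectra composed of shared fragments,
## class-specific fragments appearing with probability `classSignal`,
## compound-specific "fingerprint" fragments (the reason spectra of one
## compound resemble each other and spectrum-level splits leak), uniform
## noise peaks, jittered m/z and heavy-tailed (log-normal) intensities.

#' Synthetic dataset configuration
#'
#' Defaults emulate a combined EI-MS + ESI-MS/MS collection at desk
#' scale: more nonbitter than bitter compounds, but far more spectra per
#' bitter compound, giving a surplus of bitter spectra.
#'
#' @param nBitter,nNonbitter compound counts per class.
#' @param spectraPerCompound named list (`bitter`, `nonbitter`) of
#'   probability vectors over 1..k spectra per compound.
#' @param mzRange m/z interval fragments and noise are drawn from (Th).
#' @param nSharedFragments,nBitterFragments,nNonbitterFragments sizes of
#'   the shared and class-specific fragment pools (drawn disjointly).
#' @param nFingerprintFragments compound-specific fragments per compound.
#' @param sharedSignal,classSignal,fingerprintSignal per-spectrum
#'   inclusion probability of each fragment of the respective pool;
#'   `classSignal = 0` makes the two classes statistically identical.
#' @param noisePeaks mean number of uniform noise peaks per spectrum.
#' @param mzJitterSd Gaussian m/z jitter standard deviation (Th).
#' @param intensityMeanlog,intensitySdlog log-normal intensity model.
#' @param instrumentMix named proportions of `EI-MS` vs `ESI-MS/MS`.
#' @param collisionEnergies candidate collision energies (eV) for tandem
#'   spectra; EI spectra get energy 0 (unknown).
#' @param seed generator seed.
#' @return a `list` of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(
    nBitter = 60, nNonbitter = 88,
    spectraPerCompound = list(
      bitter = setNames(c(.10, .10, .10, .15, .25, .20, .10),
                        c(1, 2, 3, 6, 9, 12, 15)),
      nonbitter = setNames(c(.35, .25, .15, .10, .06, .04, .03, .02), 1:8)),
    mzRange = c(50, 500),
    nSharedFragments = 30, nBitterFragments = 12, nNonbitterFragments = 12,
    nFingerprintFragments = 6,
    sharedSignal = 0.5, classSignal = 0.8, fingerprintSignal = 0.9,
    noisePeaks = 4, mzJitterSd = 0.01,
    intensityMeanlog = 3, intensitySdlog = 1,
    instrumentMix = c("EI-MS" = 0.3, "ESI-MS/MS" = 0.7),
    collisionEnergies = c(10, 20, 35, 45),
    seed = 1) {
  cfg <- list(nBitter = nBitter, nNonbitter = nNonbitter,
              spectraPerCompound = spectraPerCompound, mzRange = mzRange,
              nSharedFragments = nSharedFragments,
              nBitterFragments = nBitterFragments,
              nNonbitterFragments = nNonbitterFragments,
              nFingerprintFragments = nFingerprintFragments,
              sharedSignal = sharedSignal, classSignal = classSignal,
              fingerprintSignal = fingerprintSignal,
              noisePeaks = noisePeaks, mzJitterSd = mzJitterSd,
              intensityMeanlog = intensityMeanlog,
              intensitySdlog = intensitySdlog,
              instrumentMix = instrumentMix,
              collisionEnergies = collisionEnergies, seed = seed)
  stopifnot(cfg$classSignal >= 0, cfg$classSignal <= 1,
            cfg$mzRange[2] > cfg$mzRange[1],
            cfg$nSharedFragments + cfg$nBitterFragments +
              cfg$nNonbitterFragments > 0)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Named synthetic presets
#'
#' \describe{
#'   \item{`"separable"`}{`classSignal = 1`, disjoint class fragment
#'     pools, little noise: a classifier should approach perfect test
#'     balanced accuracy.}
#'   \item{`"null"`}{`classSignal = 0` and identical per-class spectrum
#'     counts: the classes are statistically identical and any honest
#'     estimate of balanced accuracy must hover at 0.5.}
#'   \item{`"imbalanced"`}{weak class signal but strong compound
#'     fingerprints under the skewed per-compound spectrum counts: the
#'     configuration in which spectrum-level splits inflate performance
#'     relative to compound-level splits.}
#' }
#'
#' @param preset preset name.
#' @param seed generator seed.
#' @param ... overrides passed on to [syntheticConfig()].
#' @return a `"SyntheticConfig"`.
#' @export
syntheticPreset <- function(preset = c("separable", "null", "imbalanced"),
                            seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    separable = list(classSignal = 1, noisePeaks = 2,
                     nFingerprintFragments = 4, seed = seed),
    null = list(classSignal = 0,
                spectraPerCompound = list(
                  bitter = setNames(c(.4, .3, .2, .1), 1:4),
                  nonbitter = setNames(c(.4, .3, .2, .1), 1:4)),
                seed = seed),
    imbalanced = list(classSignal = 0.05, fingerprintSignal = 0.95,
                      nFingerprintFragments = 8, seed = seed))
  do.call(syntheticConfig, modifyList(base, list(...)))
}

#' Generate a labeled synthetic spectral dataset
#'
#' Fully reproducible from `config$seed`. Every compound receives at
#' least one spectrum; every spectrum at least one peak. Intensities are
#' min-max normalized to 0-100 as real ingested spectra are.
#'
#' @param config a `"SyntheticConfig"` from [syntheticConfig()] /
#'   [syntheticPreset()].
#' @return `list(compounds = data.frame, spectra = SpectrumSet,
#'   truth = data.frame, labeled = LabeledSpectrumSet)`.
#' @export
generateSynthetic <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, {
    # disjoint fragment pools on a 0.5 Th lattice so pools never collide
    lattice <- seq(config$mzRange[1] + 0.25, config$mzRange[2] - 0.25,
                   by = 0.5)
    nPool <- config$nSharedFragments + config$nBitterFragments +
      config$nNonbitterFragments
    if (length(lattice) < nPool) stop("mzRange too narrow for fragment pools")
    pool <- sample(lattice, nPool)
    shared <- pool[seq_len(config$nSharedFragments)]
    bitterFrag <- pool[config$nSharedFragments +
                         seq_len(config$nBitterFragments)]
    nonbitterFrag <- pool[config$nSharedFragments + config$nBitterFragments +
                            seq_len(config$nNonbitterFragments)]
    latticeLeft <- setdiff(lattice, pool)

    nCmp <- config$nBitter + config$nNonbitter
    labels <- rep(CLASS_LEVELS[c(2, 1)], c(config$nBitter, config$nNonbitter))
    keys <- sprintf("SYN-%s-%04d", ifelse(labels == "bitter", "B", "N"),
                    seq_len(nCmp))
    fingerprints <- lapply(seq_len(nCmp), function(i)
      sample(latticeLeft, config$nFingerprintFragments))

    metaRows <- list(); peaks <- list()
    for (i in seq_len(nCmp)) {
      dist <- config$spectraPerCompound[[labels[i]]]
      nSpec <- as.integer(sample(names(dist), 1, prob = dist))
      classFrag <- if (labels[i] == "bitter") bitterFrag else nonbitterFrag
      for (j in seq_len(nSpec)) {
        mz <- c(shared[runif(length(shared)) < config$sharedSignal],
                classFrag[runif(length(classFrag)) < config$classSignal],
                fingerprints[[i]][runif(config$nFingerprintFragments) <
                                    config$fingerprintSignal],
                runif(rpois(1, config$noisePeaks),
                      config$mzRange[1], config$mzRange[2]))
        if (length(mz) == 0) mz <- sample(shared, 1)
        mz <- pmax(mz + rnorm(length(mz), 0, config$mzJitterSd), 1e-6)
        int <- rlnorm(length(mz), config$intensityMeanlog,
                      config$intensitySdlog)
        msType <- sample(names(config$instrumentMix), 1,
                         prob = config$instrumentMix)
        metaRows[[length(metaRows) + 1L]] <- data.frame(
          accession = sprintf("%s-S%02d", keys[i], j),
          compound_key = keys[i], smiles = NA_character_,
          ms_type = msType,
          ion_mode = if (msType == "EI-MS") "unknown" else "positive",
          collision_energy_eV = if (msType == "EI-MS") 0 else
            sample(config$collisionEnergies, 1),
          stringsAsFactors = FALSE)
        peaks[[length(peaks) + 1L]] <- cbind(mz = mz, intensity = int)
      }
    }
    spectra <- normalizeIntensities(
      SpectrumSet(do.call(rbind, metaRows), peaks))
    compounds <- data.frame(compound_key = keys, smiles = NA_character_,
                            label = labels, source = "synthetic",
                            stringsAsFactors = FALSE)
    list(compounds = compounds, spectra = spectra,
         truth = compounds[, c("compound_key", "label")],
         labeled = attachSpectra(compounds, spectra))
  })
}

#' Permute compound labels
#'
#' Shuffles the class labels over compounds while leaving every
#' spectrum-compound attachment untouched - the permutation null for
#' classifier performance.
#'
#' @param x A [LabeledSpectrumSet-class].
#' @param seed permutation seed.
#' @return A [LabeledSpectrumSet-class] with permuted labels.
#' @export
permuteLabels <- function(x, seed = 1) {
  cmp <- compoundTable(x)
  cmp$label <- withSeed(seed, sample(cmp$label))
  new("LabeledSpectrumSet", spectra = spectra(x), compounds = cmp)
}
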