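## Binned-spectrum featurization.
##
## The descriptor vector for a spectrum concatenates three instrument
## descriptors (MS-type code, ion-mode code, collision energy in eV) with
## one descriptor per retained m/z bin. Bins are half-open fixed-width
## intervals [lo, lo + width) tiling the m/z range observed in the
## training peaks; bins that contain no training peak are pruned and the
## resulting schema is frozen into the model.

INSTRUMENT_COLS <- c("ms_type_code", "ion_mode_code", "collision_energy_eV")

# Bin index of an m/z value under a schema; 1e-9 relative guard so that a
# value sitting exactly on an edge (up to float error) lands in the upper
# bin, matching the half-open convention in exact arithmetic.
binIndex <- function(mz, origin, width) {
  as.integer(floor((mz - origin) / width + 1e-9)) + 1L
}

#' Build the m/z bin grid from training spectra
#'
#' Bins of width `width` tile the interval from the minimum to the maximum
#' m/z observed across all training peaks, as half-open intervals
#' `[lo, lo + width)`. The grid always covers every training peak;
#' empty-bin pruning is a separate later step ([pruneEmptyBins()]), so
#' `retained` initially lists every bin.
#'
#' @param x A [SpectrumSet-class] of training spectra (>= 1 peak overall).
#' @param width bin width in Th (default 0.1).
#' @return A [BinSchema-class].
#' @examples
#' s <- SpectrumSet(data.frame(accession = "A", compound_key = "K",
#'                             ms_type = "EI-MS", ion_mode = "unknown"),
#'                  list(cbind(c(50, 50.25, 51), c(10, 20, 30))))
#' buildBinSchema(s, width = 0.1)   # 11 bins, last one [51.0, 51.1)
#' @export
buildBinSchema <- function(x, width = 0.1) {
  stopifnot(width > 0)
  allMz <- unlist(lapply(peaksList(x), function(p) p[, 1]))
  if (length(allMz) == 0) stop("cannot build a bin schema without peaks")
  origin <- min(allMz)
  n <- binIndex(max(allMz), origin, width)
  new("BinSchema", origin = origin, width = width, nBinsTotal = n,
      retained = seq_len(n))
}

#' Build instrument-category code maps from training spectra
#'
#' MS type and ion mode are coded as natural numbers in a fixed canonical
#' order restricted to the categories observed in training. The map is
#' persisted with the model; at prediction time an unseen category maps to
#' the reserved code 0 (0 already means "unknown" for collision energy).
#'
#' @param x A [SpectrumSet-class] of training spectra.
#' @return An [InstrumentVocab-class].
#' @export
buildInstrumentVocab <- function(x) {
  codeFor <- function(seen, canonical) {
    lev <- canonical[canonical %in% seen]
    if (length(lev) == 0) lev <- canonical[1]
    setNames(seq_along(lev), lev)
  }
  new("InstrumentVocab",
      msTypeCodes = codeFor(unique(msTypes(x)), MS_TYPES),
      ionModeCodes = codeFor(unique(ionModes(x)), ION_MODES))
}

lookupCode <- function(values, codes) {
  out <- unname(codes[values])
  out[is.na(out)] <- 0L
  as.numeric(out)
}

#' Featurize spectra under a frozen bin schema
#'
#' Converts each spectrum into the concatenated instrument + bin
#' descriptor vector. Three peak-descriptor strategies are supported:
#' \describe{
#'   \item{`"intensity"`}{each bin holds the total intensity of the peaks
#'     falling in it; if any bin total exceeds 100 the bin vector of that
#'     spectrum is min-max rescaled back to the 0-100 interval.}
#'   \item{`"binary"`}{1 if at least one peak falls in the bin, else 0.}
#'   \item{`"count"`}{the number of peaks falling in the bin.}
#' }
#' Peaks outside the trained m/z range are dropped (the schema is frozen);
#' the number of dropped peaks is available as
#' `attr(result, "dropped_peaks")`.
#'
#' @param x A [SpectrumSet-class] (intensity-normalized for the intensity
#'   strategy).
#' @param schema A [BinSchema-class] (pruned or unpruned).
#' @param vocab An [InstrumentVocab-class].
#' @param strategy `"intensity"`, `"binary"` or `"count"`.
#' @return Numeric matrix, one row per spectrum; columns are
#'   `ms_type_code`, `ion_mode_code`, `collision_energy_eV`, then one
#'   column per retained bin labeled `[lo to hi]`.
#' @export
featurizeSpectra <- function(x, schema, vocab,
                             strategy = c("intensity", "binary", "count")) {
  strategy <- match.arg(strategy)
  nBins <- schema@nBinsTotal
  ret <- schema@retained
  dropped <- 0L
  rows <- lapply(peaksList(x), function(p) {
    idx <- binIndex(p[, 1], schema@origin, schema@width)
    ok <- idx >= 1L & idx <= nBins
    dropped <<- dropped + sum(!ok)
    idx <- idx[ok]
    v <- numeric(nBins)
    if (length(idx) > 0) {
      if (strategy == "intensity") {
        sums <- tapply(p[ok, 2], idx, sum)
        v[as.integer(names(sums))] <- sums
        if (max(v) > 100) {
          lo <- min(v); hi <- max(v)
          v <- (v - lo) / (hi - lo) * 100
        }
      } else {
        tab <- table(idx)
        v[as.integer(names(tab))] <- as.integer(tab)
        if (strategy == "binary") v <- as.numeric(v > 0)
      }
    }
    v[ret]
  })
  mat <- cbind(
    ms_type_code = lookupCode(msTypes(x), vocab@msTypeCodes),
    ion_mode_code = lookupCode(ionModes(x), vocab@ionModeCodes),
    collision_energy_eV = collisionEnergies(x),
    do.call(rbind, rows))
  colnames(mat) <- c(INSTRUMENT_COLS, binLabels(schema))
  rownames(mat) <- accessions(x)
  attr(mat, "dropped_peaks") <- dropped
  mat
}

#' Remove bins that contained no training peak
#'
#' Columns of the training feature matrix that are all-zero across every
#' training spectrum correspond to bins never populated during training;
#' they are removed and the schema's `retained` list is updated. The
#' pruned schema is then frozen: prediction-time featurization uses it
#' unchanged. Instrument columns are never pruned.
#'
#' @param mat training feature matrix from [featurizeSpectra()].
#' @param schema the [BinSchema-class] the matrix was built under.
#' @return `list(matrix = , schema = )` with pruned columns/indices.
#' @export
pruneEmptyBins <- function(mat, schema) {
  binCols <- setdiff(colnames(mat), INSTRUMENT_COLS)
  stopifnot(length(binCols) == length(schema@retained))
  occupied <- colSums(abs(mat[, binCols, drop = FALSE])) > 0
  if (!any(occupied)) stop("all bins are empty; nothing to retain")
  schema@retained <- schema@retained[occupied]
  validObject(schema)
  list(matrix = mat[, c(INSTRUMENT_COLS, binCols[occupied]), drop = FALSE],
       schema = schema)
}
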