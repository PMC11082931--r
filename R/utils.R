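#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

# Derive a stream of child seeds (< 2^31) from one master seed, so that
# every random stage of a run traces back to a single integer.
deriveSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restoreSeed(old))
  set.seed(as.integer(masterSeed))
  sample.int(.Machine$integer.max - 1L, n)
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Run expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restoreSeed(old))
  set.seed(as.integer(seed))
  expr
}

# Half-up decimal rounding, matching how printed tables round .675 -> .68
# (base round() rounds half to even).
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Balanced accuracy straight from label vectors; positive class "bitter".
balancedAccuracy <- function(truth, predicted) {
  unname(metricScores(confusionCounts(truth, predicted))["balanced_accuracy"])
}

checkLabels <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS))
    stop("labels must be 'bitter' or 'nonbitter'")
  labels
}
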