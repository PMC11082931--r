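#' @import methods
#' @importFrom stats approx quantile rbinom rlnorm rnorm runif sd setNames predict
#' @importFrom utils head read.delim write.table modifyList
NULL

#' Accessor generics for spectrum collections and model objects
#'
#' Small accessor generics in the Bioconductor style: slot access goes
#' through these rather than through `@`.
#'
#' @param x,object An object of the appropriate class.
#' @param ... Further arguments for methods.
#' @return The corresponding slot value (see the class documentation).
#' @name bitterspec-generics
#' @keywords internal
NULL

#' @rdname bitterspec-generics
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname bitterspec-generics
#' @export
setGeneric("compoundKeys", function(x) standardGeneric("compoundKeys"))

#' @rdname bitterspec-generics
#' @export
setGeneric("msTypes", function(x) standardGeneric("msTypes"))

#' @rdname bitterspec-generics
#' @export
setGeneric("ionModes", function(x) standardGeneric("ionModes"))

#' @rdname bitterspec-generics
#' @export
setGeneric("collisionEnergies", function(x) standardGeneric("collisionEnergies"))

#' @rdname bitterspec-generics
#' @export
setGeneric("peaksList", function(x) standardGeneric("peaksList"))

#' @rdname bitterspec-generics
#' @export
setGeneric("spectrumMeta", function(x) standardGeneric("spectrumMeta"))

#' @rdname bitterspec-generics
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' @rdname bitterspec-generics
#' @export
setGeneric("retainedBins", function(x) standardGeneric("retainedBins"))

#' @rdname bitterspec-generics
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname bitterspec-generics
#' @export
setGeneric("compoundTable", function(x) standardGeneric("compoundTable"))

#' @rdname bitterspec-generics
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname bitterspec-generics
#' @export
setGeneric("trainKeys", function(x) standardGeneric("trainKeys"))

#' @rdname bitterspec-generics
#' @export
setGeneric("testKeys", function(x) standardGeneric("testKeys"))

#' @rdname bitterspec-generics
#' @export
setGeneric("metricScores", function(object, ...) standardGeneric("metricScores"))

#' @rdname bitterspec-generics
#' @export
setGeneric("confusionVector", function(object) standardGeneric("confusionVector"))

#' @rdname bitterspec-generics
#' @export
setGeneric("featureImportance", function(object) standardGeneric("featureImportance"))

#' @rdname bitterspec-generics
#' @export
setGeneric("binSchema", function(object) standardGeneric("binSchema"))

#' @rdname bitterspec-generics
#' @export
setGeneric("instrumentVocab", function(object) standardGeneric("instrumentVocab"))
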