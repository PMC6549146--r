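#' @rdname MethylSet
#' @param object,x a `MethylSet` or `QCReport`.
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname MethylSet
#' @export
setGeneric("detectionP", function(object) standardGeneric("detectionP"))

#' @rdname MethylSet
#' @export
setGeneric("probeManifest", function(object) standardGeneric("probeManifest"))

#' @rdname MethylSet
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' Per-sample bisulfite conversion efficiency
#'
#' Conversion efficiency is scored as the median beta value of the ten
#' designated fully-methylated control probes (six type I, four type II) in
#' each sample; incomplete conversion depresses the score below 1. The score
#' enters downstream association models as a covariate.
#'
#' @param object a [MethylSet-class] (computes the score) or a
#'   [QCReport-class] (returns the stored score).
#' @return named numeric vector, one value in \code{[0, 1]} per sample.
#' @export
#' @examples
#' man <- simulateManifest(200, seed = 1)
#' sim <- simulateCohort(man, nSamples = 8, seed = 1)
#' bisulfiteEfficiency(sim$mset)
setGeneric("bisulfiteEfficiency",
           function(object) standardGeneric("bisulfiteEfficiency"))

#' @rdname QCReport-class
#' @param object a `QCReport`.
#' @export
setGeneric("removedProbes", function(object) standardGeneric("removedProbes"))

#' @rdname QCReport-class
#' @export
setGeneric("removedSamples",
           function(object) standardGeneric("removedSamples"))
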