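#' @include AllClasses.R
NULL

#' @export
setGeneric("completeness", function(object, ...) standardGeneric("completeness"))

#' @export
setGeneric("contamination", function(object, ...) standardGeneric("contamination"))

#' @export
setGeneric("strainHeterogeneity", function(object, ...)
    standardGeneric("strainHeterogeneity"))

#' @export
setGeneric("passedQc", function(object, ...) standardGeneric("passedQc"))

#' @export
setGeneric("genes", function(object, ...) standardGeneric("genes"))

#' @export
setGeneric("contigNames", function(object, ...) standardGeneric("contigNames"))

#' @export
setGeneric("contigLengths", function(object, ...) standardGeneric("contigLengths"))

#' @export
setGeneric("contigSequences", function(object, ...)
    standardGeneric("contigSequences"))

#' @export
setGeneric("binId", function(object, ...) standardGeneric("binId"))

#' @export
setGeneric("markerCounts", function(object, ...) standardGeneric("markerCounts"))

#' @export
setGeneric("estimateQuality", function(object, config = pipelineConfig(), ...)
    standardGeneric("estimateQuality"))
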