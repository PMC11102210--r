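#' @rdname quantifySamples
#' @export
setGeneric("quantifySamples", function(x, manifest, ...)
    standardGeneric("quantifySamples"))

#' @rdname aggregateCategory
#' @export
setGeneric("aggregateCategory", function(x, classification, category, ...)
    standardGeneric("aggregateCategory"))

#' @rdname richnessByClass
#' @export
setGeneric("richnessByClass", function(x, classification, ...)
    standardGeneric("richnessByClass"))

#' @rdname SpikeInManifest-class
#' @export
setGeneric("controlNames", function(x) standardGeneric("controlNames"))

#' @rdname SpikeInManifest-class
#' @export
setGeneric("addedMasses", function(x) standardGeneric("addedMasses"))

#' @rdname CMUExperiment-accessors
#' @export
setGeneric("cmuValues", function(x) standardGeneric("cmuValues"))

#' @rdname CMUExperiment-accessors
#' @export
setGeneric("calibrationCurves", function(x) standardGeneric("calibrationCurves"))
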