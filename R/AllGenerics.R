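#' @rdname EnhancerCatalog-class
#' @param object an object.
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname EnhancerCatalog-class
#' @export
setGeneric("support", function(object) standardGeneric("support"))

#' @rdname EnhancerCatalog-class
#' @export
setGeneric("catalogGroup", function(object) standardGeneric("catalogGroup"))

#' @rdname PairedDesign-class
#' @param object an object.
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))

#' @rdname PairedDesign-class
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))

#' @rdname PairedDesign-class
#' @export
setGeneric("tumorSamples", function(object) standardGeneric("tumorSamples"))

#' @rdname PairedDesign-class
#' @export
setGeneric("normalSamples", function(object) standardGeneric("normalSamples"))

#' @rdname FunnelResult-class
#' @param object an object.
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))

#' @rdname FunnelResult-class
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname FunnelResult-class
#' @export
setGeneric("auditTable", function(object) standardGeneric("auditTable"))

#' @rdname SyntheticCohort-class
#' @param object an object.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
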