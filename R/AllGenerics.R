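#' @rdname ReferenceSet-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("spikeInClasses", function(x) standardGeneric("spikeInClasses"))

#' @rdname ReferenceSet-class
#' @export
setGeneric("contigClass", function(x, contig) standardGeneric("contigClass"))

#' @rdname ModificationMap-class
#' @export
setGeneric("modSites", function(x) standardGeneric("modSites"))

#' @rdname ReadSet-class
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))

#' @rdname ReadSet-class
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))

#' @rdname ReadSet-class
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))

#' @rdname SiteCountTable-class
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))

#' @rdname SpikeInReport-class
#' @export
setGeneric("conversionRates", function(x) standardGeneric("conversionRates"))

#' @rdname SpikeInReport-class
#' @export
setGeneric("nonConversionError",
           function(x) standardGeneric("nonConversionError"))

#' @rdname HmcCallSet-class
#' @export
setGeneric("hmcCalls", function(x) standardGeneric("hmcCalls"))

#' @rdname HmcCallSet-class
#' @export
setGeneric("highConfidenceSites",
           function(x) standardGeneric("highConfidenceSites"))

#' @rdname KineticFit-class
#' @export
setGeneric("kcat", function(x) standardGeneric("kcat"))

#' @rdname KineticFit-class
#' @export
setGeneric("Km", function(x) standardGeneric("Km"))

#' @rdname KineticFit-class
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
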