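#' @rdname ChromatinMap-class
#' @param x a \code{ChromatinMap}.
#' @export
setGeneric("stateFragments", function(x) standardGeneric("stateFragments"))

#' @rdname ChromatinMap-class
#' @export
setGeneric("chromatinDomains",
           function(x) standardGeneric("chromatinDomains"))

#' @rdname ChromatinMap-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ChromatinMap-class
#' @export
setGeneric("mappedLength", function(x) standardGeneric("mappedLength"))

#' @rdname ChromatinMap-class
#' @export
setGeneric("gapLength", function(x) standardGeneric("gapLength"))

#' @rdname Arrangement-class
#' @param x an \code{Arrangement}.
#' @export
setGeneric("domainLengths", function(x) standardGeneric("domainLengths"))

#' @rdname Arrangement-class
#' @export
setGeneric("spacerLengths", function(x) standardGeneric("spacerLengths"))

#' @rdname ShuffleResult-class
#' @param x a \code{ShuffleResult}.
#' @export
setGeneric("pEnrich", function(x) standardGeneric("pEnrich"))

#' @rdname ShuffleResult-class
#' @export
setGeneric("pDeplete", function(x) standardGeneric("pDeplete"))

#' @rdname ShuffleResult-class
#' @export
setGeneric("nullMoments", function(x) standardGeneric("nullMoments"))
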