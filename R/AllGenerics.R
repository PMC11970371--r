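#' @name haploScreen-generics
#' @title Accessor generics
#' @description Accessors for the core classes; slot access is never needed
#'   by user code.
#' @param x an object.
#' @param ... further arguments for methods.
#' @keywords internal
NULL

#' @rdname haploScreen-generics
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname haploScreen-generics
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname haploScreen-generics
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname haploScreen-generics
#' @export
setGeneric("markerPos", function(x) standardGeneric("markerPos"))

#' @rdname haploScreen-generics
#' @export
setGeneric("markerCm", function(x) standardGeneric("markerCm"))

#' @rdname haploScreen-generics
#' @export
setGeneric("altFreq", function(x) standardGeneric("altFreq"))

#' @rdname haploScreen-generics
#' @export
setGeneric("dcvIndex", function(x) standardGeneric("dcvIndex"))

#' @rdname haploScreen-generics
#' @export
setGeneric("dcvPos", function(x) standardGeneric("dcvPos"))

#' @rdname haploScreen-generics
#' @export
setGeneric("panelChrom", function(x) standardGeneric("panelChrom"))

#' @rdname haploScreen-generics
#' @export
setGeneric("hapA", function(x) standardGeneric("hapA"))

#' @rdname haploScreen-generics
#' @export
setGeneric("hapB", function(x) standardGeneric("hapB"))

#' @rdname haploScreen-generics
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname haploScreen-generics
#' @export
setGeneric("hapId", function(x) standardGeneric("hapId"))

#' @rdname haploScreen-generics
#' @export
setGeneric("variantId", function(x) standardGeneric("variantId"))

#' @rdname haploScreen-generics
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))
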