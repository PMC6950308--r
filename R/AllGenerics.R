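#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Accessors are the
#' supported way to reach slot data; slot access via \code{@} is internal.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @rdname accessors
#' @export
setGeneric("peakMz", function(x) standardGeneric("peakMz"))

#' @rdname accessors
#' @export
setGeneric("peakIntensity", function(x) standardGeneric("peakIntensity"))

#' @rdname accessors
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname accessors
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

#' @rdname accessors
#' @export
setGeneric("tagClasses", function(x) standardGeneric("tagClasses"))

#' @rdname accessors
#' @export
setGeneric("tagDirection", function(x) standardGeneric("tagDirection"))

#' @rdname accessors
#' @export
setGeneric("matchedPeptides", function(x) standardGeneric("matchedPeptides"))

#' @rdname accessors
#' @export
setGeneric("residueCoverage", function(x) standardGeneric("residueCoverage"))

#' @rdname accessors
#' @export
setGeneric("ki", function(x) standardGeneric("ki"))

#' @rdname accessors
#' @export
setGeneric("kiSE", function(x) standardGeneric("kiSE"))

#' @rdname accessors
#' @export
setGeneric("kiApp", function(x) standardGeneric("kiApp"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("conservationScores",
           function(x) standardGeneric("conservationScores"))

#' @rdname accessors
#' @export
setGeneric("scoreHistogram", function(x) standardGeneric("scoreHistogram"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))
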