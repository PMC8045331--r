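#' @name ctvMargins-accessors
#' @title Accessors for ctvMargins classes
#'
#' @description Accessor generics for the package's S4 classes. Slot access
#' via \code{@} is discouraged; these accessors are the supported interface.
#'
#' @param object an object of the documented class.
#' @return
#' \code{occupancy}: the logical occupancy array.
#' \code{voxelSpacing}, \code{gridOrigin}: numeric(3), mm.
#' \code{axisDirections}: 3x3 orthonormal matrix.
#' \code{directionLabel}, \code{routeClass}: character(1).
#' \code{directionVector}: numeric(3) unit vector (LPS).
#' \code{marginMm}: numeric(1) directional margin in mm.
#' \code{expansionVectors}: the [ExpansionVectorSet-class] behind a margin.
#' \code{vectorLengths}: numeric vector of expansion vector lengths, mm.
#' \code{marginCV}: numeric(1) coefficient of variation.
#' \code{perExpertMargins}: numeric(K) per-expert margins, mm.
#' \code{probabilityMap}: numeric array of STAPLE posteriors.
#' \code{consensusMask}: the thresholded consensus [BinaryVolume-class].
#' \code{sensitivities}, \code{specificities}: numeric(K).
#' \code{caseTable}: per-direction results data.frame.
#' \code{phantomTruth}: ground-truth margin data.frame.
NULL

#' @rdname ctvMargins-accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("axisDirections", function(object) standardGeneric("axisDirections"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("directionLabel", function(object) standardGeneric("directionLabel"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("directionVector", function(object) standardGeneric("directionVector"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("routeClass", function(object) standardGeneric("routeClass"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("marginMm", function(object) standardGeneric("marginMm"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("expansionVectors", function(object) standardGeneric("expansionVectors"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("vectorLengths", function(object) standardGeneric("vectorLengths"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("marginCV", function(object) standardGeneric("marginCV"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("perExpertMargins", function(object) standardGeneric("perExpertMargins"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("probabilityMap", function(object) standardGeneric("probabilityMap"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("consensusMask", function(object) standardGeneric("consensusMask"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("sensitivities", function(object) standardGeneric("sensitivities"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("specificities", function(object) standardGeneric("specificities"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("caseTable", function(object) standardGeneric("caseTable"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("phantomTruth", function(object) standardGeneric("phantomTruth"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("gtvVolume", function(object) standardGeneric("gtvVolume"))

#' @rdname ctvMargins-accessors
#' @export
setGeneric("ctvVolume", function(object) standardGeneric("ctvVolume"))
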