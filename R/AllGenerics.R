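#' @import methods
NULL

#' Accessors for coded-timeline objects
#'
#' @param x a \linkS4class{CodedTimeline}, \linkS4class{DyadTimeline},
#'   \linkS4class{SocialStateSequence} or \linkS4class{JointStateSequence}.
#' @return \code{fps}: frames per second; \code{nFrames}: number of coded
#'   frames; \code{participant}, \code{sessionId}, \code{sessionCondition}:
#'   metadata labels.
#' @name timeline-accessors
NULL

#' @rdname timeline-accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname timeline-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname timeline-accessors
#' @export
setGeneric("participant", function(x) standardGeneric("participant"))

#' @rdname timeline-accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname timeline-accessors
#' @export
setGeneric("sessionCondition", function(x) standardGeneric("sessionCondition"))

#' Extract main codes or sub-codes from a timeline
#'
#' @param x a \linkS4class{CodedTimeline}.
#' @param dimension \code{NULL} for all three dimensions (matrix), or one of
#'   \code{"SE"}, \code{"SM"}, \code{"C"} (vector).
#' @return Integer matrix (frames x dimensions) or vector.
#' @export
setGeneric("mainCodes", function(x, dimension = NULL) standardGeneric("mainCodes"))

#' @rdname mainCodes
#' @export
setGeneric("subCodes", function(x, dimension = NULL) standardGeneric("subCodes"))

#' @rdname deriveStates-methods
#' @export
setGeneric("deriveStates", function(x) standardGeneric("deriveStates"))

#' @rdname states-accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))
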