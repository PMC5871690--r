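## Accessor and show methods for the core classes.

#' @rdname timeline-accessors
setMethod("fps", "CodedTimeline", function(x) x@fps)
#' @rdname timeline-accessors
setMethod("fps", "DyadTimeline", function(x) x@infant@fps)
#' @rdname timeline-accessors
setMethod("fps", "SocialStateSequence", function(x) x@fps)
#' @rdname timeline-accessors
setMethod("fps", "JointStateSequence", function(x) x@fps)

#' @rdname timeline-accessors
setMethod("nFrames", "CodedTimeline", function(x) nrow(x@codes))
#' @rdname timeline-accessors
setMethod("nFrames", "DyadTimeline", function(x) nrow(x@infant@codes))
#' @rdname timeline-accessors
setMethod("nFrames", "SocialStateSequence", function(x) length(x@states))
#' @rdname timeline-accessors
setMethod("nFrames", "JointStateSequence", function(x) length(x@infant))

#' @rdname timeline-accessors
setMethod("participant", "CodedTimeline", function(x) x@participant)
#' @rdname timeline-accessors
setMethod("participant", "SocialStateSequence", function(x) x@participant)

#' @rdname timeline-accessors
setMethod("sessionId", "CodedTimeline", function(x) x@sessionId)
#' @rdname timeline-accessors
setMethod("sessionId", "DyadTimeline", function(x) x@infant@sessionId)

#' @rdname timeline-accessors
setMethod("sessionCondition", "CodedTimeline", function(x) x@condition)
#' @rdname timeline-accessors
setMethod("sessionCondition", "DyadTimeline", function(x) x@infant@condition)

#' @rdname mainCodes
setMethod("mainCodes", "CodedTimeline", function(x, dimension = NULL) {
  if (is.null(dimension)) {
    m <- as.matrix(x@codes[DIMENSIONS])
    storage.mode(m) <- "integer"
    return(m)
  }
  dimension <- match.arg(dimension, DIMENSIONS)
  x@codes[[dimension]]
})

#' @rdname mainCodes
setMethod("subCodes", "CodedTimeline", function(x, dimension = NULL) {
  if (is.null(dimension)) {
    m <- as.matrix(x@codes[paste0(DIMENSIONS, "_sub")])
    storage.mode(m) <- "integer"
    colnames(m) <- DIMENSIONS
    return(m)
  }
  dimension <- match.arg(dimension, DIMENSIONS)
  x@codes[[paste0(dimension, "_sub")]]
})

#' Per-frame state indices of a state sequence
#'
#' @param x a \linkS4class{SocialStateSequence} or
#'   \linkS4class{JointStateSequence}.
#' @return Integer vector of state indices (for joint sequences, a two-column
#'   matrix \code{infant}, \code{adult}).
#' @name states-accessors
#' @aliases states
setMethod("states", "SocialStateSequence", function(x) x@states)

#' @rdname states-accessors
setMethod("states", "JointStateSequence",
          function(x) cbind(infant = x@infant, adult = x@adult))

## ---- show methods ----

setMethod("show", "CodedTimeline", function(object) {
  cat(sprintf("CodedTimeline: %s%s%s\n", object@participant,
              if (nzchar(object@sessionId))
                paste0(", session ", object@sessionId) else "",
              if (nzchar(object@condition))
                paste0(" (", object@condition, ")") else ""))
  cat(sprintf("  %d frames at %g fps (%.1f s)\n", nrow(object@codes),
              object@fps, nrow(object@codes) / object@fps))
  mm <- colMeans(object@codes[DIMENSIONS])
  cat(sprintf("  mean dimensional scores: SE %.3f, SM %.3f, C %.3f\n",
              mm[1], mm[2], mm[3]))
})

setMethod("show", "DyadTimeline", function(object) {
  cat(sprintf("DyadTimeline%s%s: %d frames at %g fps\n",
              if (nzchar(sessionId(object)))
                paste0(" session ", sessionId(object)) else "",
              if (nzchar(sessionCondition(object)))
                paste0(" (", sessionCondition(object), ")") else "",
              nFrames(object), fps(object)))
})

setMethod("show", "SocialStateSequence", function(object) {
  cat(sprintf("SocialStateSequence: %d frames at %g fps\n",
              length(object@states), object@fps))
  if (length(object@states)) {
    f <- stateFrequencies(object)
    m <- modalState(f)
    cat(sprintf("  modal state: %d %s%s\n", m, stateLabels(m),
                if (isTRUE(attr(m, "tie"))) " (tie)" else ""))
  }
})

setMethod("show", "JointStateSequence", function(object) {
  cat(sprintf("JointStateSequence: %d frames at %g fps\n",
              length(object@infant), object@fps))
})
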