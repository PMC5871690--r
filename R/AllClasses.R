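#' CodedTimeline: a fixed-rate, per-frame behavioral coding of one participant
#'
#' One row per video frame, each frame holding the main code and sub-code of
#' the three behavioral dimensions (SE, SM, C). Frame \code{i} (0-based)
#' covers the half-open interval \code{[i/fps, (i+1)/fps)} seconds; a
#' boundary time belongs to the later frame. After rasterization every frame
#' is defined on all three dimensions (no gaps), and every frame's codes
#' satisfy the coding scheme's sub-code legality.
#'
#' @slot participant \code{"infant"} or \code{"adult"}.
#' @slot sessionId session label.
#' @slot condition experimental condition label.
#' @slot fps frames per second (30 fps gives the 33 ms frame resolution used
#'   for EEG-compatible coding).
#' @slot codes data.frame with integer columns \code{SE}, \code{SE_sub},
#'   \code{SM}, \code{SM_sub}, \code{C}, \code{C_sub}; sub-code columns may
#'   be \code{NA} where a sub-code is legal but unassigned.
#'
#' @exportClass CodedTimeline
setClass("CodedTimeline",
  representation(
    participant = "character",
    sessionId = "character",
    condition = "character",
    fps = "numeric",
    codes = "data.frame"
  )
)

.CODE_COLUMNS <- c("SE", "SE_sub", "SM", "SM_sub", "C", "C_sub")

setValidity("CodedTimeline", function(object) {
  msg <- character(0)
  if (length(object@fps) != 1 || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (length(object@participant) != 1 ||
      !object@participant %in% c("infant", "adult"))
    msg <- c(msg, "participant must be \"infant\" or \"adult\"")
  cd <- object@codes
  missing_cols <- setdiff(.CODE_COLUMNS, names(cd))
  if (length(missing_cols))
    return(paste("codes is missing column(s):",
                 paste(missing_cols, collapse = ", ")))
  for (d in DIMENSIONS) {
    m <- cd[[d]]
    s <- cd[[paste0(d, "_sub")]]
    if (anyNA(m) || !all(m %in% c(0L, 1L))) {
      msg <- c(msg, sprintf("%s main codes must be binary with no gaps", d))
      next
    }
    bad <- which(!isLegalCode(d, m, s))
    if (length(bad))
      msg <- c(msg, sprintf(
        "illegal %s sub-code at frame %d (main %d, sub %s)",
        d, bad[1] - 1L, m[bad[1]], as.character(s[bad[1]])))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CodedTimeline
#'
#' @param participant \code{"infant"} or \code{"adult"}.
#' @param fps frames per second.
#' @param codes data.frame with columns \code{SE}, \code{SE_sub}, \code{SM},
#'   \code{SM_sub}, \code{C}, \code{C_sub} (sub-code columns optional; filled
#'   with \code{NA} when absent).
#' @param sessionId,condition metadata labels.
#' @return A \linkS4class{CodedTimeline}.
#' @export
CodedTimeline <- function(participant, fps, codes, sessionId = "",
                          condition = "") {
  codes <- as.data.frame(codes)
  for (col in .CODE_COLUMNS)
    if (is.null(codes[[col]])) codes[[col]] <- NA_integer_
  codes <- codes[.CODE_COLUMNS]
  for (col in .CODE_COLUMNS) codes[[col]] <- as.integer(codes[[col]])
  rownames(codes) <- NULL
  new("CodedTimeline", participant = participant, sessionId = sessionId,
      condition = condition, fps = as.numeric(fps), codes = codes)
}

#' DyadTimeline: aligned infant and adult timelines of one session
#'
#' Both partners are coded against a shared session clock at the same frame
#' rate and frame count (see \code{\link{alignDyad}} for truncation of
#' unequal recordings).
#'
#' @slot infant,adult \linkS4class{CodedTimeline}s with matching fps, frame
#'   count, session and condition.
#' @exportClass DyadTimeline
setClass("DyadTimeline",
  representation(infant = "CodedTimeline", adult = "CodedTimeline")
)

setValidity("DyadTimeline", function(object) {
  msg <- character(0)
  if (object@infant@participant != "infant")
    msg <- c(msg, "infant slot must hold an infant timeline")
  if (object@adult@participant != "adult")
    msg <- c(msg, "adult slot must hold an adult timeline")
  if (object@infant@fps != object@adult@fps)
    msg <- c(msg, "fps mismatch between partners")
  if (nrow(object@infant@codes) != nrow(object@adult@codes))
    msg <- c(msg, "frame-count mismatch between partners")
  if (object@infant@sessionId != object@adult@sessionId)
    msg <- c(msg, "sessionId mismatch between partners")
  if (object@infant@condition != object@adult@condition)
    msg <- c(msg, "condition mismatch between partners")
  if (length(msg)) msg else TRUE
})

#' @rdname DyadTimeline-class
#' @param infant,adult \linkS4class{CodedTimeline}s.
#' @export
DyadTimeline <- function(infant, adult) {
  new("DyadTimeline", infant = infant, adult = adult)
}

#' SocialStateSequence: per-frame social-state indices
#'
#' The deterministic frame-wise mapping of a timeline's main-code triples to
#' the eight social states (see \code{\link{stateFromCodes}}).
#'
#' @slot fps frames per second.
#' @slot states integer vector of state indices in 1..8, one per frame.
#' @slot participant,sessionId,condition metadata carried over from the
#'   source timeline.
#' @exportClass SocialStateSequence
setClass("SocialStateSequence",
  representation(
    fps = "numeric",
    states = "integer",
    participant = "character",
    sessionId = "character",
    condition = "character"
  ),
  prototype(participant = "", sessionId = "", condition = "")
)

setValidity("SocialStateSequence", function(object) {
  if (length(object@fps) != 1 || object@fps <= 0)
    return("fps must be a single positive number")
  if (anyNA(object@states) || !all(object@states %in% 1:8))
    return("states must be integers in 1..8")
  TRUE
})

#' @rdname SocialStateSequence-class
#' @param states integer state indices in 1..8.
#' @param fps frames per second.
#' @param participant,sessionId,condition metadata labels.
#' @export
SocialStateSequence <- function(states, fps, participant = "",
                                sessionId = "", condition = "") {
  new("SocialStateSequence", fps = as.numeric(fps),
      states = as.integer(states), participant = participant,
      sessionId = sessionId, condition = condition)
}

#' JointStateSequence: per-frame (infant state, adult state) pairs
#'
#' One of the 64 ordered joint adult-infant states per frame.
#'
#' @slot fps frames per second.
#' @slot infant,adult integer state vectors of equal length.
#' @slot sessionId,condition metadata labels.
#' @exportClass JointStateSequence
setClass("JointStateSequence",
  representation(
    fps = "numeric",
    infant = "integer",
    adult = "integer",
    sessionId = "character",
    condition = "character"
  ),
  prototype(sessionId = "", condition = "")
)

setValidity("JointStateSequence", function(object) {
  if (length(object@infant) != length(object@adult))
    return("infant and adult state vectors differ in length")
  if (anyNA(object@infant) || anyNA(object@adult) ||
      !all(object@infant %in% 1:8) || !all(object@adult %in% 1:8))
    return("state indices must be integers in 1..8")
  TRUE
})
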