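## Social-state derivation and per-session summaries.

#' Derive the per-frame social-state sequence of a timeline
#'
#' Maps each frame's (SE, SM, C) main-code triple to its social-state index
#' through the canonical 8-state taxonomy (\code{\link{stateFromCodes}});
#' sub-codes are ignored. The mapping is deterministic -- no smoothing or
#' latent-state inference.
#'
#' @param x a \linkS4class{CodedTimeline}.
#' @return A \linkS4class{SocialStateSequence} of the same length.
#' @name deriveStates-methods
#' @aliases deriveStates
#' @export
setMethod("deriveStates", "CodedTimeline", function(x) {
  m <- mainCodes(x)
  SocialStateSequence(stateFromCodes(m[, "SE"], m[, "SM"], m[, "C"]),
                      fps = fps(x), participant = participant(x),
                      sessionId = sessionId(x),
                      condition = sessionCondition(x))
})

#' Segment a state sequence into maximal runs
#'
#' Run-length encodes the sequence into half-open frame segments
#' \code{[start_frame, end_frame)}. With \code{minDuration > 1}, runs shorter
#' than the minimum are absorbed into the longer adjacent run (ties go to the
#' preceding run) and adjacent equal-state runs are re-merged, repeatedly,
#' until all remaining runs meet the minimum (or a single run remains).
#'
#' @param x a \linkS4class{SocialStateSequence} or integer state vector.
#' @param minDuration minimum run length in frames (default 1 = exact
#'   run-length encoding).
#' @return data.frame with columns \code{state}, \code{start_frame}
#'   (inclusive, 0-based), \code{end_frame} (exclusive).
#' @examples
#' segmentStates(c(1, 1, 1, 2, 2))            # [1: 0-3), [2: 3-5)
#' segmentStates(c(1, 1, 2, 1, 1), minDuration = 2)  # [1: 0-5)
#' @export
segmentStates <- function(x, minDuration = 1L) {
  s <- if (is(x, "SocialStateSequence")) states(x) else as.integer(x)
  if (length(s) == 0) stop("cannot segment an empty state sequence")
  if (minDuration < 1) stop("minDuration must be >= 1")
  repeat {
    r <- rle(s)
    k <- length(r$lengths)
    if (k <= 1) break
    short <- which(r$lengths < minDuration)
    if (length(short) == 0) break
    i <- short[1]
    left <- if (i > 1) r$lengths[i - 1] else -1L
    right <- if (i < k) r$lengths[i + 1] else -1L
    donor <- if (left >= right) i - 1L else i + 1L
    r$values[i] <- r$values[donor]
    s <- inverse.rle(r)
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  data.frame(state = as.integer(r$values),
             start_frame = as.integer(ends - r$lengths),
             end_frame = as.integer(ends))
}

#' Mean dimensional scores of a session
#'
#' The session average of each dimension's binary main code: the proportion
#' of time with play-congruent activity on that dimension. A mean SM score
#' of 0.7 means active ("hands-on") possession of the object 70\% of the
#' time; the mean C score is the proportion of time attending to the object
#' or partner.
#'
#' @param x a \linkS4class{CodedTimeline} (non-empty).
#' @return Named numeric vector \code{c(SE=, SM=, C=)}, each in [0, 1].
#' @export
dimensionalMeans <- function(x) {
  stopifnot(is(x, "CodedTimeline"))
  if (nFrames(x) == 0) stop("empty timeline")
  colMeans(mainCodes(x))
}

#' State frequency distribution of a session
#'
#' @param x a \linkS4class{SocialStateSequence}, integer state vector, or
#'   \linkS4class{CodedTimeline} (states derived first).
#' @return Named numeric 8-vector of per-state frame proportions (sums to 1).
#' @export
stateFrequencies <- function(x) {
  if (is(x, "CodedTimeline")) x <- deriveStates(x)
  s <- if (is(x, "SocialStateSequence")) states(x) else as.integer(x)
  if (length(s) == 0) stop("empty state sequence")
  stats::setNames(tabulate(s, nbins = 8) / length(s), as.character(1:8))
}

#' Modal social state of a session
#'
#' The most frequently occupied state. Ties are broken toward the lowest
#' state index and flagged via the \code{"tie"} attribute.
#'
#' @param freq 8-vector of state proportions (or anything
#'   \code{\link{stateFrequencies}} accepts).
#' @return Integer state index with logical attribute \code{"tie"}.
#' @export
modalState <- function(freq) {
  if (!is.numeric(freq) || length(freq) != 8)
    freq <- stateFrequencies(freq)
  top <- which(freq == max(freq))
  structure(top[1], tie = length(top) > 1L)
}

#' Per-session state summary
#'
#' Bundles the session's dimensional means, state frequency distribution,
#' modal state (with tie flag) and metadata, ready for JSON export.
#'
#' @param x a \linkS4class{CodedTimeline}.
#' @return A list.
#' @export
stateSummary <- function(x) {
  stopifnot(is(x, "CodedTimeline"))
  seq <- deriveStates(x)
  freq <- stateFrequencies(seq)
  m <- modalState(freq)
  list(
    participant = participant(x),
    session_id = sessionId(x),
    condition = sessionCondition(x),
    fps = fps(x),
    n_frames = nFrames(x),
    dimensional_means = as.list(dimensionalMeans(x)),
    state_frequencies = as.numeric(freq),
    modal_state = as.integer(m),
    modal_state_label = stateLabels(as.integer(m)),
    modal_tie = isTRUE(attr(m, "tie"))
  )
}

#' Counts of sub-code use per (dimension, main code)
#'
#' Convenience tally of sub-code occupancy; sub-codes are stored and
#' validated but excluded from state derivation and the main summaries.
#'
#' @param x a \linkS4class{CodedTimeline}.
#' @return data.frame with columns \code{dimension}, \code{main_code},
#'   \code{sub_code}, \code{n_frames}.
#' @export
subCodeCounts <- function(x) {
  stopifnot(is(x, "CodedTimeline"))
  out <- lapply(DIMENSIONS, function(d) {
    m <- x@codes[[d]]
    s <- x@codes[[paste0(d, "_sub")]]
    tab <- table(main_code = m, sub_code = addNA(factor(s)), useNA = "no")
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    data.frame(dimension = d, main_code = as.integer(df$main_code),
               sub_code = suppressWarnings(as.integer(as.character(df$sub_code))),
               n_frames = df$Freq)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a state sequence as a per-frame TSV
#'
#' Columns \code{frame}, \code{t_onset_s}, \code{state_index}, \code{SE},
#' \code{SM}, \code{C}.
#'
#' @param x a \linkS4class{SocialStateSequence}.
#' @param path output path.
#' @export
writeStateSequence <- function(x, path) {
  stopifnot(is(x, "SocialStateSequence"))
  s <- states(x)
  m <- codesFromState(s)
  df <- data.frame(frame = seq_along(s) - 1L,
                   t_onset_s = sprintf("%.6f", (seq_along(s) - 1L) / fps(x)),
                   state_index = s, SE = m[, "SE"], SM = m[, "SM"],
                   C = m[, "C"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
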