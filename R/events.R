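## Event-table export for time-locked neural (EEG) analysis.

#' Export state segments as a BIDS-events style table
#'
#' One event per (optionally filtered) segment, with \code{onset} and
#' \code{duration} in seconds rendered at 3 decimal places plus exact
#' \code{frame_start} / \code{frame_end} columns. At 30 fps frames do not
#' fall on exact millisecond boundaries (33.3 ms), so the frame-index
#' columns carry the lossless timing that rounded seconds cannot; event
#' re-import from them is bit-exact (\code{\link{readEvents}}).
#'
#' @param segments data.frame from \code{\link{segmentStates}} (columns
#'   \code{state}, \code{start_frame}, \code{end_frame}).
#' @param fps frames per second of the source sequence.
#' @param path optional output TSV path (written with a header even when no
#'   events survive filtering).
#' @param filterStates optional subset of state indices to keep (e.g.
#'   \code{1} to extract play-congruent periods only).
#' @param participant,sessionId,condition metadata columns for the table.
#' @return data.frame with columns \code{onset}, \code{duration},
#'   \code{trial_type}, \code{frame_start}, \code{frame_end},
#'   \code{participant}, \code{session_id}, \code{condition} (invisibly when
#'   \code{path} is given).
#' @export
exportEvents <- function(segments, fps, path = NULL, filterStates = NULL,
                         participant = "", sessionId = "", condition = "") {
  stopifnot(all(c("state", "start_frame", "end_frame") %in% names(segments)))
  if (!is.null(filterStates)) {
    bad <- setdiff(filterStates, 1:8)
    if (length(bad))
      stop("unknown state(s) in filter: ", paste(bad, collapse = ", "))
    segments <- segments[segments$state %in% filterStates, , drop = FALSE]
  }
  ev <- data.frame(
    onset = segments$start_frame / fps,
    duration = (segments$end_frame - segments$start_frame) / fps,
    trial_type = sprintf("state_%d", segments$state),
    frame_start = as.integer(segments$start_frame),
    frame_end = as.integer(segments$end_frame),
    participant = if (nrow(segments)) participant else character(0),
    session_id = if (nrow(segments)) sessionId else character(0),
    condition = if (nrow(segments)) condition else character(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    out <- ev
    out$onset <- sprintf("%.3f", out$onset)
    out$duration <- sprintf("%.3f", out$duration)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(ev))
  }
  ev
}

#' Re-import an exported event table as state segments
#'
#' Reconstructs the segment list from the exact frame-index columns (the
#' rounded second columns are ignored for timing).
#'
#' @param path a TSV written by \code{\link{exportEvents}}.
#' @return data.frame with columns \code{state}, \code{start_frame},
#'   \code{end_frame}.
#' @export
readEvents <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("trial_type", "frame_start", "frame_end")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event file is missing column(s): ", paste(miss, collapse = ", "))
  data.frame(
    state = as.integer(sub("^state_", "", ev$trial_type)),
    start_frame = as.integer(ev$frame_start),
    end_frame = as.integer(ev$frame_end)
  )
}
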