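## Annotation I/O and rasterization: interval-level coder output -> gap-free
## fixed-rate coded timelines.

.ANNOTATION_COLUMNS <- c("participant", "dimension", "main_code", "sub_code",
                         "onset_s", "offset_s")

## boundary tolerance (seconds) when matching interval endpoints to frame
## times; well below one frame at any realistic rate
.TIME_EPS <- 1e-9

#' Read behavioral annotations from a delimited file
#'
#' Reads one row per coded interval (\code{participant}, \code{dimension},
#' \code{main_code}, \code{sub_code}, \code{onset_s}, \code{offset_s}),
#' validates each row against the coding scheme's sub-code legality (see
#' \code{\link{legalSubCodes}}) and returns the annotations sorted by onset
#' within (participant, dimension).
#'
#' @param path path to a CSV or TSV file (UTF-8). The delimiter defaults by
#'   extension (\code{.tsv}/\code{.tab} = tab, otherwise comma).
#' @param delim optional explicit single-character delimiter.
#' @param columns optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   \code{c(onset_s = "start", offset_s = "stop")}.
#' @return A data.frame of validated annotations with the canonical columns,
#'   sorted by (participant, dimension, onset). An empty file with a header
#'   yields a zero-row data.frame.
#' @seealso \code{\link{rasterize}}, \code{\link{writeAnnotations}}
#' @export
readAnnotations <- function(path, delim = NULL, columns = NULL) {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      pos <- match(columns[[canon]], names(df))
      if (!is.na(pos)) names(df)[pos] <- canon
    }
  }
  missing_cols <- setdiff(.ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("annotation file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[.ANNOTATION_COLUMNS]
  validateAnnotations(df)
}

#' Validate an in-memory annotation table
#'
#' @param df data.frame with the canonical annotation columns.
#' @return The validated table, sorted by (participant, dimension, onset),
#'   with typed columns. Errors cite the offending row and the legality rule
#'   violated.
#' @export
validateAnnotations <- function(df) {
  missing_cols <- setdiff(.ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("annotations are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[.ANNOTATION_COLUMNS]
  df$participant <- as.character(df$participant)
  df$dimension <- as.character(df$dimension)
  df$main_code <- as.integer(df$main_code)
  df$sub_code <- suppressWarnings(as.integer(df$sub_code))
  df$onset_s <- as.numeric(df$onset_s)
  df$offset_s <- as.numeric(df$offset_s)
  if (nrow(df) == 0) return(df)

  bad <- which(!df$participant %in% c("infant", "adult"))
  if (length(bad))
    stop(sprintf("row %d: unknown participant \"%s\" (expected infant/adult)",
                 bad[1], df$participant[bad[1]]))
  bad <- which(!df$dimension %in% DIMENSIONS)
  if (length(bad))
    stop(sprintf("row %d: unknown dimension \"%s\" (expected SE/SM/C)",
                 bad[1], df$dimension[bad[1]]))
  bad <- which(is.na(df$main_code) | !df$main_code %in% c(0L, 1L))
  if (length(bad))
    stop(sprintf("row %d: main_code must be 0 or 1", bad[1]))
  bad <- which(is.na(df$onset_s) | is.na(df$offset_s) | df$onset_s < 0 |
                 df$offset_s <= df$onset_s)
  if (length(bad))
    stop(sprintf("row %d: need 0 <= onset_s < offset_s (got %s, %s)",
                 bad[1], df$onset_s[bad[1]], df$offset_s[bad[1]]))
  for (i in seq_len(nrow(df))) {
    d <- df$dimension[i]; m <- df$main_code[i]; s <- df$sub_code[i]
    if (!isLegalCode(d, m, s)) {
      legal <- .SUBCODE_LEGAL[[d]][[as.character(m)]]
      rule <- if (length(legal))
        sprintf("%s main %d takes sub-codes {%s}", d, m,
                paste(legal, collapse = ","))
      else
        sprintf("%s main %d takes no sub-code", d, m)
      stop(sprintf("row %d: illegal sub-code %s (%s)", i, s, rule))
    }
  }
  df[order(df$participant, match(df$dimension, DIMENSIONS), df$onset_s), ,
     drop = FALSE]
}

#' Rasterize interval annotations to a fixed-rate coded timeline
#'
#' Frame \code{i} (0-based) takes the code of the interval containing time
#' \code{i/fps}; intervals are half-open \code{[onset, offset)}, so a
#' boundary time belongs to the later interval. Within each dimension the
#' intervals must be non-overlapping and, unless a fill code is configured
#' for that dimension, cover \code{[0, duration_s)} without gaps.
#'
#' @param annotations data.frame of validated annotations for \emph{one}
#'   participant (columns \code{dimension}, \code{main_code}, \code{sub_code},
#'   \code{onset_s}, \code{offset_s}; a \code{participant} column, if
#'   present, must be constant).
#' @param fps frames per second (30 fps = 33 ms frame resolution).
#' @param duration_s session duration in seconds; defaults to the latest
#'   offset. The frame count is \code{round(duration_s * fps)}.
#' @param fill optional named vector of main codes used to fill uncovered
#'   time per dimension, e.g. \code{c(SM = 0)}; dimensions without a fill
#'   entry treat gaps as errors.
#' @param participant,sessionId,condition metadata for the resulting
#'   timeline; \code{participant} defaults to the annotation table's.
#' @return A \linkS4class{CodedTimeline}.
#' @examples
#' ann <- data.frame(
#'   dimension = c("SE", "SM", "SM", "C"),
#'   main_code = c(1L, 1L, 0L, 1L),
#'   sub_code = c(1L, 2L, NA, 3L),
#'   onset_s = c(0, 0, 0.5, 0),
#'   offset_s = c(1, 0.5, 1, 1))
#' tl <- rasterize(ann, fps = 30, duration_s = 1, participant = "infant")
#' table(mainCodes(tl, "SM"))  # 15 frames of 1, 15 of 0
#' @export
rasterize <- function(annotations, fps, duration_s = NULL, fill = NULL,
                      participant = NULL, sessionId = "", condition = "") {
  if (!is.null(annotations$participant)) {
    pp <- unique(annotations$participant)
    if (length(pp) > 1)
      stop("rasterize() expects annotations of a single participant; got: ",
           paste(pp, collapse = ", "))
    if (is.null(participant) && length(pp) == 1) participant <- pp
  }
  if (is.null(participant))
    stop("participant must be given (or present in the annotations)")
  if (is.null(duration_s)) {
    if (nrow(annotations) == 0)
      stop("cannot infer duration from an empty annotation set")
    duration_s <- max(annotations$offset_s)
  }
  n <- as.integer(round(duration_s * fps))
  if (n < 1) stop("duration too short for a single frame at ", fps, " fps")
  t_frames <- (seq_len(n) - 1L) / fps

  codes <- data.frame(row.names = seq_len(n))
  for (d in DIMENSIONS) {
    iv <- annotations[annotations$dimension == d, , drop = FALSE]
    iv <- iv[order(iv$onset_s), , drop = FALSE]
    fill_code <- if (!is.null(fill) && d %in% names(fill))
      as.integer(fill[[d]]) else NULL
    ## overlap check
    if (nrow(iv) > 1) {
      ov <- which(iv$onset_s[-1] < iv$offset_s[-nrow(iv)] - .TIME_EPS)
      if (length(ov))
        stop(sprintf(
          "%s: overlapping intervals [%g, %g) and [%g, %g)", d,
          iv$onset_s[ov[1]], iv$offset_s[ov[1]],
          iv$onset_s[ov[1] + 1], iv$offset_s[ov[1] + 1]))
    }
    ## coverage / gap handling
    gaps <- .findGaps(iv, duration_s)
    if (nrow(gaps) > 0) {
      if (is.null(fill_code))
        stop(sprintf("%s: uncovered gap [%g, %g) and no fill policy",
                     d, gaps$from[1], gaps$to[1]))
      iv <- rbind(iv[c("main_code", "sub_code", "onset_s", "offset_s")],
                  data.frame(main_code = fill_code, sub_code = NA_integer_,
                             onset_s = gaps$from, offset_s = gaps$to))
      iv <- iv[order(iv$onset_s), , drop = FALSE]
    }
    idx <- findInterval(t_frames + .TIME_EPS, iv$onset_s)
    if (any(idx == 0))
      stop(sprintf("%s: frame time %g precedes the first interval",
                   d, t_frames[which(idx == 0)[1]]))
    uncovered <- t_frames >= iv$offset_s[idx] - .TIME_EPS
    if (any(uncovered))
      stop(sprintf("%s: frame time %g not covered by any interval",
                   d, t_frames[which(uncovered)[1]]))
    codes[[d]] <- iv$main_code[idx]
    codes[[paste0(d, "_sub")]] <- iv$sub_code[idx]
  }
  CodedTimeline(participant = participant, fps = fps, codes = codes,
                sessionId = sessionId, condition = condition)
}

## gaps in the union of sorted intervals relative to [0, duration_s)
.findGaps <- function(iv, duration_s) {
  eps <- .TIME_EPS
  from <- numeric(0); to <- numeric(0)
  if (nrow(iv) == 0)
    return(data.frame(from = 0, to = duration_s))
  if (iv$onset_s[1] > eps) { from <- 0; to <- iv$onset_s[1] }
  if (nrow(iv) > 1) {
    g <- which(iv$onset_s[-1] > iv$offset_s[-nrow(iv)] + eps)
    from <- c(from, iv$offset_s[g]); to <- c(to, iv$onset_s[g + 1])
  }
  if (iv$offset_s[nrow(iv)] < duration_s - eps) {
    from <- c(from, iv$offset_s[nrow(iv)]); to <- c(to, duration_s)
  }
  data.frame(from = from, to = to)
}

#' Rasterize a two-participant annotation table into an aligned dyad
#'
#' Convenience wrapper: splits the table by participant, rasterizes each
#' stream with shared settings and aligns the two timelines (see
#' \code{\link{alignDyad}}).
#'
#' @inheritParams rasterize
#' @param annotations validated annotation table containing both
#'   participants.
#' @return A \linkS4class{DyadTimeline}.
#' @export
rasterizeDyad <- function(annotations, fps, duration_s = NULL, fill = NULL,
                          sessionId = "", condition = "") {
  for (who in c("infant", "adult"))
    if (!who %in% annotations$participant)
      stop("annotations contain no rows for participant \"", who, "\"")
  tls <- lapply(c("infant", "adult"), function(who) {
    rasterize(annotations[annotations$participant == who, , drop = FALSE],
              fps = fps, duration_s = duration_s, fill = fill,
              participant = who, sessionId = sessionId,
              condition = condition)
  })
  alignDyad(tls[[1]], tls[[2]])
}

#' Align an infant and an adult timeline onto a shared session clock
#'
#' Both recordings are assumed to share a session clock (two synchronized
#' cameras); the longer timeline is truncated to the shorter frame count and
#' the truncation is reported via \code{message()}. No resampling is
#' performed: a frame-rate mismatch is an error.
#'
#' @param infant,adult \linkS4class{CodedTimeline}s at equal fps.
#' @return A \linkS4class{DyadTimeline}.
#' @export
alignDyad <- function(infant, adult) {
  if (fps(infant) != fps(adult))
    stop(sprintf("fps mismatch: infant %g vs adult %g (no resampling)",
                 fps(infant), fps(adult)))
  ni <- nFrames(infant); na <- nFrames(adult)
  n <- min(ni, na)
  if (n == 0) stop("cannot align empty timelines")
  if (ni != na) {
    message(sprintf(
      "alignDyad: truncating %s from %d to %d frames (shared clock)",
      if (ni > na) "infant" else "adult", max(ni, na), n))
    if (ni > n) infant@codes <- infant@codes[seq_len(n), , drop = FALSE]
    if (na > n) adult@codes <- adult@codes[seq_len(n), , drop = FALSE]
  }
  DyadTimeline(infant, adult)
}

#' De-rasterize a timeline back to interval annotations
#'
#' Maximal runs of identical (main code, sub-code) pairs per dimension are
#' merged back into half-open intervals on the frame grid. For annotations
#' whose boundaries lie on the frame grid this inverts
#' \code{\link{rasterize}} exactly.
#'
#' @param x a \linkS4class{CodedTimeline}.
#' @return Annotation data.frame in the canonical column layout.
#' @export
annotationsFromTimeline <- function(x) {
  stopifnot(is(x, "CodedTimeline"))
  n <- nFrames(x)
  out <- lapply(DIMENSIONS, function(d) {
    m <- x@codes[[d]]
    s <- x@codes[[paste0(d, "_sub")]]
    key <- paste(m, ifelse(is.na(s), ".", s))
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    first <- starts + 1L
    data.frame(participant = x@participant, dimension = d,
               main_code = m[first], sub_code = s[first],
               onset_s = starts / x@fps, offset_s = ends / x@fps)
  })
  do.call(rbind, out)
}

#' Write a coded timeline as a per-frame TSV
#'
#' One row per frame with columns \code{frame}, \code{t_onset_s}, \code{SE},
#' \code{SE_sub}, \code{SM}, \code{SM_sub}, \code{C}, \code{C_sub}.
#'
#' @param x a \linkS4class{CodedTimeline}.
#' @param path output file path.
#' @export
writeTimeline <- function(x, path) {
  stopifnot(is(x, "CodedTimeline"))
  n <- nFrames(x)
  df <- cbind(frame = seq_len(n) - 1L,
              t_onset_s = sprintf("%.6f", (seq_len(n) - 1L) / x@fps),
              x@codes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotations in the dialect readAnnotations() reads
#'
#' @param df annotation data.frame (canonical columns).
#' @param path output path; extension picks the delimiter
#'   (\code{.tsv}/\code{.tab} = tab, otherwise comma).
#' @export
writeAnnotations <- function(df, path) {
  df <- df[.ANNOTATION_COLUMNS]
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
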