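## Inter-rater agreement between two coders' timelines.

.overlapCodes <- function(a, b, dimension, subCodes = FALSE) {
  stopifnot(is(a, "CodedTimeline"), is(b, "CodedTimeline"))
  if (fps(a) != fps(b))
    stop(sprintf("fps mismatch between coders: %g vs %g", fps(a), fps(b)))
  n <- min(nFrames(a), nFrames(b))
  if (n == 0) stop("empty frame overlap between coders")
  dimension <- match.arg(dimension, DIMENSIONS)
  col <- if (subCodes) paste0(dimension, "_sub") else dimension
  list(a = a@codes[[col]][seq_len(n)], b = b@codes[[col]][seq_len(n)], n = n)
}

#' Percent agreement between two coders on one dimension
#'
#' Frame-wise agreement on main codes over the frames both coders coded
#' (the shorter timeline's range): \code{100 * (equal frames) / (frames
#' compared)}. Symmetric in its arguments.
#'
#' @param a,b \linkS4class{CodedTimeline}s of the same recording by two
#'   coders, at equal fps.
#' @param dimension one of \code{"SE"}, \code{"SM"}, \code{"C"}.
#' @param subCodes compare sub-codes instead of main codes (\code{NA}
#'   sub-codes agree only with \code{NA}).
#' @return Percentage in [0, 100].
#' @export
percentAgreement <- function(a, b, dimension, subCodes = FALSE) {
  ov <- .overlapCodes(a, b, dimension, subCodes)
  if (subCodes) {
    eq <- (is.na(ov$a) & is.na(ov$b)) |
      (!is.na(ov$a) & !is.na(ov$b) & ov$a == ov$b)
  } else eq <- ov$a == ov$b
  100 * mean(eq)
}

#' Cohen's kappa between two coders on one dimension
#'
#' Chance-corrected agreement from the 2x2 main-code confusion table. When
#' either coder is constant the expected agreement can equal the observed
#' agreement and kappa is undefined; the return value is then \code{NA} with
#' attribute \code{"undefined" = TRUE}.
#'
#' @inheritParams percentAgreement
#' @return Kappa coefficient in [-1, 1], or \code{NA} (flagged) when
#'   undefined.
#' @export
codersKappa <- function(a, b, dimension) {
  ov <- .overlapCodes(a, b, dimension)
  if (length(unique(ov$a)) < 2 || length(unique(ov$b)) < 2)
    return(structure(NA_real_, undefined = TRUE))
  po <- mean(ov$a == ov$b)
  pe <- mean(ov$a == 1) * mean(ov$b == 1) + mean(ov$a == 0) * mean(ov$b == 0)
  structure((po - pe) / (1 - pe), undefined = FALSE)
}

#' Full agreement report between two coders
#'
#' @inheritParams percentAgreement
#' @param kappa include Cohen's kappa per dimension.
#' @return list with per-dimension percent agreement, the number of frames
#'   compared, and (optionally) kappa coefficients.
#' @export
agreementReport <- function(a, b, kappa = TRUE, subCodes = FALSE) {
  pa <- vapply(DIMENSIONS, function(d) percentAgreement(a, b, d), numeric(1))
  out <- list(
    participant = participant(a),
    n_frames = min(nFrames(a), nFrames(b)),
    percent_agreement = as.list(pa)
  )
  if (subCodes)
    out$percent_agreement_sub <- as.list(vapply(
      DIMENSIONS, function(d) percentAgreement(a, b, d, subCodes = TRUE),
      numeric(1)))
  if (kappa) {
    kp <- lapply(DIMENSIONS, function(d) codersKappa(a, b, d))
    out$kappa <- stats::setNames(lapply(kp, function(k) {
      if (isTRUE(attr(k, "undefined"))) NA else as.numeric(k)
    }), DIMENSIONS)
  }
  out
}
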