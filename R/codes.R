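#' @title The dimensional coding scheme and social-state taxonomy
#'
#' @description
#' Behavior is coded on three dimensions -- socioemotional (\code{SE}:
#' positive/neutral vs. negative affect), sensorimotor (\code{SM}: voluntary
#' object contact vs. none/passive) and cognitive (\code{C}: attention on
#' object/partner vs. elsewhere). Each dimension carries a binary main code
#' (1 = play-congruent activity present) and, where defined, an integer
#' sub-code refining the kind of activity. The per-frame triple of main codes
#' defines one of eight social states; state 1, \code{[1 1 1]}, is the
#' play-congruent state.
#'
#' @name coding-scheme
NULL

## Dimension order is fixed throughout the package: SE, SM, C.
DIMENSIONS <- c("SE", "SM", "C")

## Legal sub-codes keyed by (dimension, main code). SM main 0 and C main 0
## take no sub-code at all.
.SUBCODE_LEGAL <- list(
  SE = list(`1` = 1:2, `0` = 1:2),
  SM = list(`1` = 1:3, `0` = integer(0)),
  C  = list(`1` = 1:5, `0` = integer(0))
)

## Canonical state numbering: row s gives the (SE, SM, C) main codes of
## social state s. State 1 is the play-congruent state [1 1 1].
.STATE_CODES <- matrix(
  c(1L, 1L, 1L,
    1L, 0L, 1L,
    0L, 1L, 1L,
    0L, 0L, 1L,
    1L, 1L, 0L,
    1L, 0L, 0L,
    0L, 1L, 0L,
    0L, 0L, 0L),
  nrow = 8, byrow = TRUE,
  dimnames = list(state = 1:8, dimension = DIMENSIONS)
)

## key = SE*4 + SM*2 + C in 0..7 -> state index
.STATE_LOOKUP <- local({
  key <- .STATE_CODES[, "SE"] * 4L + .STATE_CODES[, "SM"] * 2L +
    .STATE_CODES[, "C"]
  lut <- integer(8)
  lut[key + 1L] <- 1:8
  lut
})

#' Legal sub-codes for a (dimension, main code) pair
#'
#' @param dimension one of \code{"SE"}, \code{"SM"}, \code{"C"}.
#' @param main binary main code (0 or 1).
#' @return Integer vector of legal sub-codes; \code{integer(0)} when the pair
#'   takes no sub-code (SM main 0, C main 0).
#' @examples
#' legalSubCodes("SM", 1)  # 1 2 3
#' legalSubCodes("SM", 0)  # integer(0)
#' @export
legalSubCodes <- function(dimension, main) {
  dimension <- match.arg(dimension, DIMENSIONS)
  stopifnot(main %in% c(0, 1))
  .SUBCODE_LEGAL[[dimension]][[as.character(as.integer(main))]]
}

#' Check legality of a (dimension, main, sub) combination
#'
#' A missing (\code{NA}) sub-code is legal wherever sub-codes exist; a
#' non-missing sub-code on a pair that takes none (SM main 0, C main 0) is
#' illegal.
#'
#' @inheritParams legalSubCodes
#' @param sub integer sub-code or \code{NA}.
#' @return \code{TRUE} if legal, \code{FALSE} otherwise. Vectorized over
#'   \code{main} and \code{sub}.
#' @export
isLegalCode <- function(dimension, main, sub) {
  dimension <- match.arg(dimension, DIMENSIONS)
  main <- as.integer(main)
  sub <- as.integer(sub)
  mapply(function(m, s) {
    if (is.na(m) || !m %in% c(0L, 1L)) return(FALSE)
    legal <- .SUBCODE_LEGAL[[dimension]][[as.character(m)]]
    if (is.na(s)) return(TRUE)
    s %in% legal
  }, main, sub, USE.NAMES = FALSE)
}

#' Map main-code triples to social states and back
#'
#' The eight social states are numbered by the canonical taxonomy:
#' 1 = \code{[1 1 1]} (play-congruent), 2 = \code{[1 0 1]}, 3 = \code{[0 1 1]},
#' 4 = \code{[0 0 1]}, 5 = \code{[1 1 0]}, 6 = \code{[1 0 0]},
#' 7 = \code{[0 1 0]}, 8 = \code{[0 0 0]}. Codes are ordered (SE, SM, C).
#'
#' @param SE,SM,C binary main-code vectors of equal length.
#' @return \code{stateFromCodes}: integer state indices in 1..8.
#' @examples
#' stateFromCodes(1, 1, 1)  # 1
#' stateFromCodes(0, 0, 1)  # 4
#' codesFromState(3)        # SE=0 SM=1 C=1
#' @export
stateFromCodes <- function(SE, SM, C) {
  SE <- as.integer(SE); SM <- as.integer(SM); C <- as.integer(C)
  if (anyNA(SE) || anyNA(SM) || anyNA(C))
    stop("main codes must not contain NA")
  if (!all(SE %in% 0:1) || !all(SM %in% 0:1) || !all(C %in% 0:1))
    stop("main codes must be binary (0/1)")
  .STATE_LOOKUP[SE * 4L + SM * 2L + C + 1L]
}

#' @rdname stateFromCodes
#' @param state integer state indices in 1..8.
#' @return \code{codesFromState}: integer matrix with columns SE, SM, C.
#' @export
codesFromState <- function(state) {
  state <- as.integer(state)
  if (anyNA(state) || !all(state %in% 1:8))
    stop("state indices must be integers in 1..8")
  .STATE_CODES[state, , drop = FALSE]
}

#' @rdname stateFromCodes
#' @return \code{stateLabels}: character labels like \code{"[1 1 1]"} for the
#'   requested states.
#' @export
stateLabels <- function(state = 1:8) {
  m <- codesFromState(state)
  unname(apply(m, 1L, function(r) sprintf("[%d %d %d]", r[1], r[2], r[3])))
}

#' Size of the state taxonomy
#'
#' Counted by enumeration: the distinct main-code triples give the individual
#' social states, and ordered (infant, adult) pairs give the joint states.
#'
#' @return Integer count: 8 individual states, 64 joint states.
#' @export
nSocialStates <- function() nrow(unique(.STATE_CODES))

#' @rdname nSocialStates
#' @export
nJointStates <- function() {
  s <- seq_len(nSocialStates())
  nrow(unique(expand.grid(infant = s, adult = s)))
}
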