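## Joint adult-infant states, behavioral synchrony and condition comparison.

#' Joint (concurrent) social states of a dyad
#'
#' Pairs the two partners' derived state sequences frame by frame; each frame
#' occupies one of the 64 ordered (infant state, adult state) joint states.
#'
#' @param dyad a \linkS4class{DyadTimeline} (aligned; see
#'   \code{\link{alignDyad}}).
#' @return A \linkS4class{JointStateSequence}.
#' @export
jointStates <- function(dyad) {
  stopifnot(is(dyad, "DyadTimeline"))
  if (nFrames(dyad) == 0) stop("empty dyad timeline")
  si <- deriveStates(dyad@infant)
  sa <- deriveStates(dyad@adult)
  new("JointStateSequence", fps = fps(dyad), infant = states(si),
      adult = states(sa), sessionId = sessionId(dyad),
      condition = sessionCondition(dyad))
}

#' Joint probability distribution over the 64 dyadic states
#'
#' @param jseq a \linkS4class{JointStateSequence}.
#' @return 8x8 numeric matrix \code{p}; \code{p[i, a]} is the proportion of
#'   frames with the infant in state \code{i} and the adult in state
#'   \code{a}. Rows sum to the infant's state frequencies, columns to the
#'   adult's.
#' @export
jointDistribution <- function(jseq) {
  stopifnot(is(jseq, "JointStateSequence"))
  n <- nFrames(jseq)
  if (n == 0) stop("empty joint state sequence")
  p <- table(factor(jseq@infant, levels = 1:8),
             factor(jseq@adult, levels = 1:8)) / n
  p <- unclass(as.matrix(p))
  dimnames(p) <- list(infant = stateLabels(), adult = stateLabels())
  p
}

#' Behavioral synchrony of a dyad
#'
#' Quantifies concurrent state alignment between the partners:
#' \itemize{
#'   \item \code{p_joint_play}: proportion of frames with \emph{both}
#'     partners in the play-congruent state \code{[1 1 1]} ("synchronous
#'     play"), i.e. \code{p[1, 1]} of the joint distribution;
#'   \item \code{dimension_concordance}: per-dimension proportion of frames
#'     with equal main codes;
#'   \item \code{p_same_state}: proportion of frames with equal state index
#'     (the trace of the joint distribution).
#' }
#'
#' @param jseq a \linkS4class{JointStateSequence} (or
#'   \linkS4class{DyadTimeline}, converted first).
#' @return list with elements \code{p_joint_play},
#'   \code{dimension_concordance} (named SE/SM/C) and \code{p_same_state}.
#' @export
synchrony <- function(jseq) {
  if (is(jseq, "DyadTimeline")) jseq <- jointStates(jseq)
  stopifnot(is(jseq, "JointStateSequence"))
  n <- nFrames(jseq)
  if (n == 0) stop("empty joint state sequence")
  ci <- codesFromState(jseq@infant)
  ca <- codesFromState(jseq@adult)
  conc <- colMeans(ci == ca)
  list(
    p_joint_play = mean(jseq@infant == 1L & jseq@adult == 1L),
    dimension_concordance = conc,
    p_same_state = mean(jseq@infant == jseq@adult)
  )
}

#' Paired-design effect size (Cohen's d for paired t)
#'
#' For a paired t statistic on \code{n} pairs, \code{d = t / sqrt(n)} (the
#' standardized mean difference of the paired differences, often written
#' d_z). This is the convention consistent with reporting signed t values
#' alongside positive effect sizes of matching magnitude.
#'
#' @param t paired t statistic(s).
#' @param n number of pairs.
#' @return Effect size(s), same sign as \code{t}.
#' @examples
#' cohensDz(8.97, 5)   # 4.01
#' cohensDz(-9.85, 5)  # -4.41 (|d| = 4.41)
#' @export
cohensDz <- function(t, n) {
  if (any(n < 1)) stop("n must be >= 1")
  t / sqrt(n)
}

#' Benjamini-Hochberg FDR step-up adjustment
#'
#' Implements the step-up procedure from its definition: with the \code{m}
#' raw p-values sorted ascending, the adjusted value at rank \code{k} is
#' \code{min over j >= k of min(1, m * p_(j) / j)}; hypotheses with adjusted
#' p at or below \code{alpha} are rejected.
#'
#' @param p raw p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{p_adjusted} (in the input order) and
#'   \code{rejected} (logical).
#' @export
bhFDR <- function(p, alpha = 0.05) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  p_adj <- numeric(m)
  p_adj[o] <- adj_sorted
  list(p_adjusted = p_adj, rejected = p_adj <= alpha)
}

#' Compare per-state frequencies between two conditions (paired design)
#'
#' For each of the 8 social states, a two-sided paired t-test of the
#' condition-2 minus condition-1 state frequencies across dyads, with
#' Benjamini-Hochberg FDR correction across the 8 states (one family per
#' participant group) and the paired-design effect size
#' \code{\link{cohensDz}}. Frequencies (proportions), not raw frame counts,
#' enter the tests, so sessions of unequal length are comparable.
#'
#' @param cond1,cond2 numeric matrices of per-dyad state frequencies (dyads
#'   in rows, 8 states in columns); row names identify dyads and, when
#'   present in both, are used to pair rows.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with one row per state: \code{state}, \code{mean_diff}
#'   (condition 2 minus condition 1), \code{t}, \code{df} (= n - 1),
#'   \code{p_raw}, \code{p_fdr}, \code{d}, \code{rejected}, \code{n}; the
#'   FDR level is attached as attribute \code{"alpha"}. States with a
#'   constant zero difference across dyads report \code{t = 0}, \code{d = 0},
#'   \code{p = 1}.
#' @export
compareConditions <- function(cond1, cond2, alpha = 0.05) {
  cond1 <- as.matrix(cond1); cond2 <- as.matrix(cond2)
  if (ncol(cond1) != 8 || ncol(cond2) != 8)
    stop("frequency matrices must have 8 columns (one per state)")
  if (!is.null(rownames(cond1)) && !is.null(rownames(cond2))) {
    only1 <- setdiff(rownames(cond1), rownames(cond2))
    only2 <- setdiff(rownames(cond2), rownames(cond1))
    if (length(only1) || length(only2))
      stop("dyad(s) missing one condition: ",
           paste(unique(c(only1, only2)), collapse = ", "))
    cond2 <- cond2[rownames(cond1), , drop = FALSE]
  } else if (nrow(cond1) != nrow(cond2)) {
    stop("conditions have different numbers of dyads (",
         nrow(cond1), " vs ", nrow(cond2), ") and no dyad names to pair by")
  }
  n <- nrow(cond1)
  if (n < 2) stop("need at least 2 dyads with both conditions")
  res <- lapply(1:8, function(s) {
    diff <- cond2[, s] - cond1[, s]
    if (stats::sd(diff) == 0) {
      ## degenerate paired test: constant differences carry no variance
      tval <- if (all(diff == 0)) 0 else sign(mean(diff)) * Inf
      p <- if (all(diff == 0)) 1 else 0
    } else {
      ht <- tryCatch(stats::t.test(cond2[, s], cond1[, s], paired = TRUE),
                     error = function(e) NULL)
      if (is.null(ht)) {
        ## t.test refuses near-constant data; fall back to the definition
        tval <- mean(diff) / (stats::sd(diff) / sqrt(n))
        p <- 2 * stats::pt(-abs(tval), df = n - 1)
      } else {
        tval <- unname(ht$statistic)
        p <- ht$p.value
      }
    }
    data.frame(state = s, mean_diff = mean(diff), t = tval,
               df = n - 1L, p_raw = p)
  })
  res <- do.call(rbind, res)
  fdr <- bhFDR(res$p_raw, alpha = alpha)
  res$p_fdr <- fdr$p_adjusted
  res$d <- cohensDz(res$t, n)
  res$rejected <- fdr$rejected
  res$n <- n
  attr(res, "alpha") <- alpha
  res
}
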