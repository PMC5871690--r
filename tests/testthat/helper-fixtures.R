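## Shared fixture builders: everything is generated in code.

## Timeline from main-code vectors; sub-codes legal-or-NA.
makeTimeline <- function(SE, SM, C, fps = 30, participant = "infant",
                         sessionId = "s1", condition = "c1",
                         withSubs = FALSE) {
  n <- length(SE)
  codes <- data.frame(SE = SE, SM = SM, C = C)
  if (withSubs) {
    codes$SE_sub <- ifelse(SE == 1, 1L, 1L)
    codes$SM_sub <- ifelse(SM == 1, 2L, NA_integer_)
    codes$C_sub <- ifelse(C == 1, 3L, NA_integer_)
  }
  CodedTimeline(participant = participant, fps = fps, codes = codes,
                sessionId = sessionId, condition = condition)
}

## Random legal timeline (independent frames).
randomTimeline <- function(n, fps = 30, participant = "infant",
                           p1 = c(SE = 0.6, SM = 0.5, C = 0.7)) {
  makeTimeline(stats::rbinom(n, 1, p1["SE"]), stats::rbinom(n, 1, p1["SM"]),
               stats::rbinom(n, 1, p1["C"]), fps = fps,
               participant = participant)
}

## Frame-aligned random annotation set for one participant: per dimension, a
## partition of [0, n/fps) at frame-grid boundaries with alternating-free
## codes and legal subs.
randomAnnotations <- function(n_frames, fps = 30, participant = "infant",
                              max_run = 40) {
  out <- lapply(c("SE", "SM", "C"), function(d) {
    bounds <- 0L
    while (utils::tail(bounds, 1) < n_frames) {
      bounds <- c(bounds, min(n_frames,
                              utils::tail(bounds, 1) +
                                sample.int(max_run, 1)))
    }
    k <- length(bounds) - 1L
    main <- sample(0:1, k, replace = TRUE)
    sub <- vapply(main, function(m) {
      legal <- legalSubCodes(d, m)
      if (length(legal)) sample(legal, 1) else NA_integer_
    }, integer(1))
    data.frame(participant = participant, dimension = d, main_code = main,
               sub_code = sub, onset_s = bounds[-length(bounds)] / fps,
               offset_s = bounds[-1] / fps)
  })
  do.call(rbind, out)
}

## Annotation table covering both participants.
randomDyadAnnotations <- function(n_frames, fps = 30) {
  rbind(randomAnnotations(n_frames, fps, "infant"),
        randomAnnotations(n_frames, fps, "adult"))
}

## Brute-force BH rejection oracle: scan every candidate threshold.
bhOracle <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- which(ps <= alpha * seq_len(m) / m)
  if (length(k) == 0) return(rep(FALSE, m))
  p <= ps[max(k)]
}

## Definitional paired t.
pairedTDef <- function(x, y) {
  d <- x - y
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}
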