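makeDyadFromStates <- function(infant, adult, fps = 30) {
  ci <- codesFromState(infant)
  ca <- codesFromState(adult)
  DyadTimeline(
    makeTimeline(ci[, "SE"], ci[, "SM"], ci[, "C"], fps = fps),
    makeTimeline(ca[, "SE"], ca[, "SM"], ca[, "C"], fps = fps,
                 participant = "adult")
  )
}

test_that("joint states pair the two partners' sequences frame by frame", {
  dy <- makeDyadFromStates(rep(1, 5), rep(1, 5))
  js <- jointStates(dy)
  expect_equal(unname(states(js)), cbind(rep(1L, 5), rep(1L, 5)),
               ignore_attr = TRUE)

  ## didactic example: mother [1 0 1] while infant [0 1 1] -> pair (3, 2)
  infant <- makeTimeline(SE = 0, SM = 1, C = 1)
  mother <- makeTimeline(SE = 1, SM = 0, C = 1, participant = "adult")
  js <- jointStates(DyadTimeline(infant, mother))
  expect_equal(unname(states(js)[1, ]), c(3L, 2L))
})

test_that("joint distribution counts pairs and reproduces the marginals", {
  js <- new("JointStateSequence", fps = 30,
            infant = c(1L, 1L, 2L, 1L), adult = c(1L, 1L, 1L, 3L))
  p <- jointDistribution(js)
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[2, 1], 0.25)
  expect_equal(p[1, 3], 0.25)
  expect_equal(sum(p), 1)

  ## identical partner sequences put all mass on the diagonal
  s <- sample(1:8, 50, replace = TRUE)
  pd <- jointDistribution(new("JointStateSequence", fps = 30, infant = s,
                              adult = s))
  expect_equal(sum(diag(pd)), 1)

  set.seed(31)
  for (rep in 1:30) {
    n <- sample(5:300, 1)
    i <- sample(1:8, n, replace = TRUE)
    a <- sample(1:8, n, replace = TRUE)
    p <- jointDistribution(new("JointStateSequence", fps = 30, infant = i,
                               adult = a))
    expect_equal(unname(rowSums(p)), unname(stateFrequencies(i)),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(p)), unname(stateFrequencies(a)),
                 tolerance = 1e-12)
  }
})

test_that("synchrony measures joint play, concordance, and same-state time", {
  ## identical streams: p_same_state = 1, p_joint_play = freq[1]
  s <- rep(c(1L, 2L, 1L, 5L, 1L), each = 4)  # freq[1] = 0.6
  js <- new("JointStateSequence", fps = 30, infant = s, adult = s)
  sy <- synchrony(js)
  expect_equal(sy$p_same_state, 1)
  expect_equal(sy$p_joint_play, 0.6)
  expect_equal(unname(sy$dimension_concordance), c(1, 1, 1))

  ## disjoint states: no joint play
  js2 <- new("JointStateSequence", fps = 30, infant = rep(1L, 10),
             adult = rep(2L, 10))
  expect_equal(synchrony(js2)$p_joint_play, 0)

  ## 3 of 10 frames jointly in state 1
  js3 <- new("JointStateSequence", fps = 30,
             infant = c(rep(1L, 5), rep(4L, 5)),
             adult = c(rep(1L, 3), rep(2L, 7)))
  expect_equal(synchrony(js3)$p_joint_play, 0.3)
})

test_that("synchrony is partner-symmetric and bounded by each partner's play time", {
  set.seed(32)
  for (rep in 1:30) {
    n <- sample(10:500, 1)
    i <- sample(1:8, n, replace = TRUE, prob = c(4, rep(1, 7)))
    a <- sample(1:8, n, replace = TRUE, prob = c(4, rep(1, 7)))
    sy <- synchrony(new("JointStateSequence", fps = 30, infant = i,
                        adult = a))
    sw <- synchrony(new("JointStateSequence", fps = 30, infant = a,
                        adult = i))
    expect_equal(sy$p_joint_play, sw$p_joint_play)
    expect_equal(sy$p_same_state, sw$p_same_state)
    expect_lte(sy$p_joint_play,
               min(stateFrequencies(i)[1], stateFrequencies(a)[1]))
    expect_lte(sy$p_joint_play, sy$p_same_state)
  }
})

test_that("the paired-design effect size matches d = t / sqrt(n)", {
  expect_equal(round(cohensDz(8.97, 5), 2), 4.01)
  expect_equal(round(cohensDz(-9.85, 5), 2), -4.41)
  expect_equal(abs(round(cohensDz(-9.85, 5), 2)), 4.41)
  expect_equal(cohensDz(0, 7), 0)
})

test_that("BH-FDR step-up matches hand computation, p.adjust, and the threshold-scan oracle", {
  ## hand application: m = 8, smallest p = 0.001, rest 0.2
  p <- c(0.001, rep(0.2, 7))
  res <- bhFDR(p)
  expect_equal(res$p_adjusted[1], 0.008)
  expect_equal(res$p_adjusted[2], 0.2 * 8 / 8)

  expect_false(any(bhFDR(rep(1, 6))$rejected))
  one <- bhFDR(0.04, alpha = 0.05)
  expect_equal(one$p_adjusted, 0.04)
  expect_true(one$rejected)

  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(33)
  for (rep in 1:200) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    res <- bhFDR(p, alpha = alpha)
    expect_equal(res$p_adjusted, p.adjust(p, method = "BH"))
    expect_equal(res$rejected, bhOracle(p, alpha))
    expect_true(all(res$p_adjusted >= p - 1e-12))
  }
})

test_that("compareConditions agrees with the definitional paired t to 1e-10", {
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    f1 <- t(sapply(seq_len(n), function(i) stateFrequencies(
      sample(1:8, 100, replace = TRUE))))
    f2 <- t(sapply(seq_len(n), function(i) stateFrequencies(
      sample(1:8, 100, replace = TRUE, prob = c(5, rep(1, 7))))))
    cmp <- compareConditions(f1, f2)
    for (s in 1:8) {
      if (sd(f2[, s] - f1[, s]) == 0) next  # t undefined; handled separately
      tt <- pairedTDef(f2[, s], f1[, s])
      expect_equal(cmp$t[s], tt, tolerance = 1e-10)
      expect_equal(cmp$d[s], tt / sqrt(n), tolerance = 1e-10)
      expect_equal(cmp$df[s], n - 1)
      expect_equal(cmp$mean_diff[s], mean(f2[, s] - f1[, s]),
                   tolerance = 1e-12)
    }
    expect_true(all(cmp$p_fdr >= cmp$p_raw))
    expect_equal(sign(cmp$d), sign(cmp$t))
  }
})

test_that("compareConditions handles degenerate and invalid designs", {
  f <- matrix(rep(1 / 8, 16), nrow = 2)
  cmp <- compareConditions(f, f)
  expect_equal(cmp$t, rep(0, 8))
  expect_equal(cmp$d, rep(0, 8))
  expect_equal(cmp$p_raw, rep(1, 8))

  expect_error(compareConditions(f[1, , drop = FALSE],
                                 f[1, , drop = FALSE]),
               "at least 2 dyads")

  a <- matrix(runif(24), 3, 8, dimnames = list(c("d1", "d2", "d3"), NULL))
  b <- matrix(runif(24), 3, 8, dimnames = list(c("d1", "d2", "d4"), NULL))
  expect_error(compareConditions(a, b), "d3")
})
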