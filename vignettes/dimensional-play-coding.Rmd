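---
title: "Dimensional coding and state analysis of dyadic play: methods"
author: "dyadplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensional coding and state analysis of dyadic play: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadplay)
```

## The model

`dyadplay` analyzes dyadic (adult--infant) object play coded frame by frame
on three behavioral dimensions, each tied to a neural circuit family that
animal work implicates in play:

* **SE** (socioemotional): positive or neutral affect (1) vs. negative
  affect (0);
* **SM** (sensorimotor): voluntary physical contact with the object (1) vs.
  no or passive contact (0);
* **C** (cognitive): visual attention on the object or partner (1) vs.
  elsewhere (0).

Each dimension carries a binary *main code* and, where defined, an integer
*sub-code* refining the kind of activity (e.g. C sub-code 3 =
object-specific exploration). The legal sub-code sets are fixed: SE takes
sub-codes {1, 2} under either main code, SM takes {1, 2, 3} under main 1 and
none under main 0, and C takes {1..5} under main 1 and none under main 0 --
twelve sub-coded combinations in all. Sub-codes are stored and validated but
never enter state derivation; `subCodeCounts()` tallies them.

The per-frame triple of main codes defines one of $2^3 = 8$ **social
states**, numbered canonically: 1 = [1 1 1] (the *play-congruent* state),
2 = [1 0 1], 3 = [0 1 1], 4 = [0 0 1], 5 = [1 1 0], 6 = [1 0 0],
7 = [0 1 0], 8 = [0 0 0] (codes ordered SE, SM, C). A dyad's concurrent
pair (infant state, adult state) is one of 64 **joint states**;
*synchronous play* is joint state (1, 1). The mapping is a deterministic
bijection -- no smoothing or latent-state inference is performed, so every
derived quantity is an exact function of the codes.

Session-level summaries are the **dimensional mean scores** (per-dimension
mean of the main code: the proportion of time play-congruent on that
dimension), the 8-vector of **state frequencies**, and the **modal state**.
These obey exact marginal identities -- e.g. the mean SE score equals the
summed frequency of states {1, 2, 5, 6} -- which the test suite asserts on
randomized timelines.

## Time base and rasterization

Coders produce interval annotations (participant, dimension, main code,
sub-code, onset, offset in seconds). `rasterize()` converts them to a
gap-free per-frame timeline at a fixed frame rate, 30 fps by default (one
frame = 33 ms, the resolution needed to time-lock behavioral states to EEG).
Conventions, chosen for unambiguous arithmetic:

* frames are 0-based and half-open: frame $i$ covers $[i/f, (i+1)/f)$
  seconds, and a boundary time belongs to the *later* frame;
* interval endpoints are matched to frame times with a $10^{-9}$ s
  tolerance, well below one frame at any realistic rate;
* within a dimension, overlapping intervals are a hard error, and uncovered
  gaps are errors unless an explicit per-dimension fill code is configured
  (`fill = c(SM = 0)`) -- silent filling would hide coder error;
* the two partners share a session clock (two synchronized cameras), so
  `alignDyad()` only truncates the longer recording; it never resamples,
  and a frame-rate mismatch is an error.

De-rasterization (`annotationsFromTimeline()`) inverts rasterization
exactly when annotation boundaries lie on the frame grid; boundaries off
the grid are quantized to it, which is the expected and documented loss.

## Condition comparison

Per-state frequencies -- proportions, never raw frame counts, so sessions of
unequal length are comparable -- are compared between two conditions with
two-sided paired t-tests across dyads (`compareConditions()`), one test per
state, with Benjamini--Hochberg FDR control across the 8 states within a
participant group ($\alpha = 0.05$ by default) and the paired-design effect
size $d_z = t/\sqrt{n}$. Two-sided tests are used because directional
language in a report does not by itself justify a one-sided procedure. The
$d_z$ convention is validated in the tests against worked examples: with
$n = 5$, $t = 8.97 \mapsto d = 4.01$ and $t = -9.85 \mapsto |d| = 4.41$
(2 d.p.), and likewise for three further $(t, d)$ pairs.

The BH step-up adjustment is implemented from its definition (sorted
ascending, $\tilde p_{(k)} = \min_{j \ge k} \min(1, m\,p_{(j)}/j)$) and is
cross-checked in the tests against both `stats::p.adjust(method = "BH")`
and an exhaustive threshold-scan oracle for $m \le 8$. Degenerate designs
are handled explicitly: a state with identically zero frequency differences
reports $t = 0$, $p = 1$; constant non-zero differences report an infinite
t with $p = 0$ rather than an error.

## Inter-rater agreement

`percentAgreement()` is frame-wise percent agreement on main codes over the
frames both coders coded (the coding unit is the frame, so frame-wise
comparison is the natural default; sub-code agreement is available behind a
flag). `codersKappa()` supplements it with Cohen's kappa from the 2x2
main-code confusion table; when either coder is constant, kappa's
denominator can vanish, so the value is returned as `NA` with an explicit
`undefined` flag rather than a silent number.

## The synthetic dyad generator

No coded session videos are distributed, so the package carries a seedable
generator (`simulateDyad()`) used throughout the tests and examples. The
adult's state evolves as a first-order Markov chain over the 8 states; at
each frame the infant copies the adult's current state with probability
$\kappa$ (the coupling, or synchrony dial) and otherwise steps from its own
previous state by its own kernel. This per-frame copy mechanism is the
simplest that makes expected same-state time monotone in $\kappa$, with
$\kappa = 0$ giving independent partners and $\kappa = 1$ a perfect mirror.
States are decoded to main codes through the canonical bijection; sub-codes
are drawn uniformly from the legal set of each (dimension, main code) pair,
since no empirical sub-code distribution is available to emulate. A single
seed governs all draws; identical parameters give byte-identical output.

Transition kernels are built as sticky mixtures
$P = s\,I + (1 - s)\,\mathbf{1}\pi^\top$, whose stationary distribution is
exactly $\pi$ for any persistence $s < 1$. The default $s = 0.96$ gives
mean dwell times of roughly 1--2 s at 30 fps, a plausible scale for infant
behavioral states. One subtlety matters when choosing $\kappa$: a copied
state persists through the infant's own sticky kernel, so the infant's
effective marginal is approximately
$(\kappa\,\pi_A + (1-\kappa)(1-s)\,\pi_I) / (\kappa + (1-\kappa)(1-s))$ --
coupling must stay comparable to the escape rate $1 - s$ for the infant's
own repertoire to remain visible.

`conditionPreset()` bundles two regimes:

* **teaching-like** (didactic, non-conducive to play): infant stationary
  target peaked on state 2 ([1 0 1], attentive but hands-off, ~35%), with
  appreciable negative-affect observation (state 4); adult peaked on
  state 1 with frequent instructed negative-affect demonstration
  (state 3); $\kappa = 0.01$. Long-run infant modal state: [1 0 1].
* **play-like** (conducive): both partners peaked on the play-congruent
  state (infant ~52%, adult ~60%); $\kappa = 0.02$, elevated relative to
  teaching. Long-run infant modal state: [1 1 1].

These targets were set once, from the qualitative regime the framework is
meant to discriminate (play-congruent modal state and clearly higher
synchrony under the conducive condition; hands-off attentive modal state
under the didactic condition). Ten-minute simulations land at roughly
19--21% infant play-state time and ~10--12% synchronous play under
teaching-like, versus ~55% and ~38% under play-like. The generator emulates
the *state structure* of real sessions -- frequencies, first-order
transitions, tunable coupling -- and not their semi-Markov dwell-time
distributions, coder noise, or any lagged (turn-taking) contingency;
passing tests therefore demonstrate correctness of the analysis machinery
on Markovian data, not fidelity of any particular behavioral claim about
real dyads.

`estimateTransition()` inverts the generator (row-normalized bigram counts,
with never-visited source states flagged rather than silently zeroed); on
uncoupled simulations of 100,000 frames it recovers the generating kernel
to within 0.02 element-wise.

## Event export for neural time-locking

`segmentStates()` run-length encodes a state sequence into maximal
half-open frame segments; with a minimum duration, shorter runs are
absorbed into the longer adjacent run (ties to the preceding run) and
re-merged, which keeps the output a partition. `exportEvents()` writes
segments as a BIDS-events style TSV (`onset`, `duration`, `trial_type`)
with seconds rendered at 3 decimals. Because 30 fps frames do not fall on
millisecond boundaries, the table also carries exact `frame_start` /
`frame_end` columns; `readEvents()` reconstructs segments from those
bit-exactly. The BIDS-like layout is a portability choice, not a
requirement of any downstream tool.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to give tight Monte Carlo
bounds while staying quick: exact identities on 1,000 randomized short
timelines; a 50,000-frame uncoupled uniform simulation for the 1/64
joint-play closed form (3 binomial SEs); 100,000 frames for transition
recovery; a 5-point $\kappa$ grid averaged over 50 seeds (30 s sessions)
for monotonicity; and 10-minute sessions for the preset regime checks. The
acceptance script analyzes a freshly simulated 5-dyad, two-condition corpus
of 10-minute sessions (180,000 frames in all).

## Known limitations

* States are deterministic functions of codes; there is no model of coder
  noise or of latent behavioral states.
* Synchrony is strictly concurrent; lagged contingencies such as
  turn-taking are out of scope.
* Exactly two participants per session; no clock-drift correction beyond
  truncation to the shared clock.
* The comparison machinery assumes a paired two-condition design; with
  fewer than two complete dyads the pipeline skips that stage and says so.
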