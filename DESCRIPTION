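Package: dyadplay
Title: Dimensional Coding and State Analysis of Adult-Infant Play Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for frame-level dimensional coding of dyadic (adult-infant)
    object play. Behavioral annotations on three dimensions (socioemotional,
    sensorimotor, cognitive) are rasterized to fixed-rate coded timelines,
    mapped to an 8-state social-state taxonomy, and summarized as dimensional
    mean scores, state frequency distributions and modal states. Dyad-level
    analyses cover the 64 joint adult-infant states, behavioral synchrony
    (synchronous play), and paired condition comparisons with
    Benjamini-Hochberg false-discovery-rate control and paired-design effect
    sizes. Includes inter-rater agreement statistics, a seedable
    coupled-Markov simulator of dyadic state sequences, and a BIDS-events
    style exporter of state segments for time-locked neural (EEG) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
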