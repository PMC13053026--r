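Package: refgame
Title: Simulation and Analysis of Dyadic Referential Communication Games
    with Graded Iconicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how iconicity affects the bootstrapping of
    communication systems in dyadic referential games played in a novel
    signaling medium. Implements the trackpad-to-CIELAB colorspace mapping
    and its dot-signal counterpart, a game engine enforcing round timing and
    a sliding-window winning condition over six referents, parametric
    sender/receiver agents (iconic anchoring, drifting arbitrary
    conventions, exemplar memory with an iconic prior) for generating
    synthetic cohorts, the success-index and signal-stability metrics, and
    the condition-level linear and mixed-effects summaries. Game logs
    round-trip through JSON Lines and CSV, and a column-mapping adapter
    ingests externally deposited logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmmTMB,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
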