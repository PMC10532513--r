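Package: antivea
Title: Schedules, Simulation, and Scoring for the ANTI-Vea Attention and
    Vigilance Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ANTI-Vea task, which measures the three
    attentional networks (phasic alerting, orienting, executive control)
    together with executive and arousal vigilance in a single session.
    Builds deterministic, seeded trial schedules for the standard task and
    its sub-task versions; simulates raw trial-level response data from a
    generative cognitive model whose parameters are the quantities the
    scorer estimates; reads and writes a documented trial-level CSV
    dialect; scores raw data into the task's core attentional-network and
    vigilance indexes (plus signal-detection extensions) with the standard
    preprocessing rules; and estimates split-half reliability with the
    Spearman-Brown correction. Reference cohort presets calibrated to
    published normative results support parameter-recovery testing of the
    whole task-to-index chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
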