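Package: lickometry
Title: Drinking Microstructure Analysis for Home-Cage Lickometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of capacitance-based lickometer
    recordings from limited-access drinking sessions in mice. Converts raw
    sensor readings to touch/release events with a per-sample delta rule,
    pairs events into licks with contact durations, segments licks into
    bouts using initiation (at least 3 licks with inter-lick intervals of
    at most 1 s) and termination (quiet gap longer than 3 s) criteria, and
    derives per-session microstructure summaries, cumulative-lick curves
    and frontloading splits. Includes intake conversion from bottle masses,
    per-group blood-ethanol accumulation slopes with bootstrap slope-ratio
    intervals, two-sample Kolmogorov-Smirnov comparison of pooled lick-time
    distributions, rank/t location tests, linear mixed-effects models of
    intake against drinking behaviors, and a seeded synthetic-cohort
    generator with genotype presets emulating wild-type and ADH1-deficient
    drinking phenotypes so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
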