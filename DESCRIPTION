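Package: ciliascreen
Title: Hit Calling for Arrayed RNAi Ciliation Screens
Version: 1.0.0
Authors@R:
    person("Alex", "Moran", email = "alex.moran@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for arrayed RNA-interference screens that score
    formation of the primary cilium by immunofluorescence counting. Computes
    percent ciliation from ciliated/total cell counts, normalizes each
    condition to the same-experiment scrambled control, calibrates loss and
    gain thresholds from negative-control dispersion against a
    positive-control anchor, and applies a two-round decision automaton with
    per-duplex knockdown concordance (qRT-PCR delta-delta-Ct or precomputed
    percent RNA remaining) to call gene-level hits. Includes cilium-length
    two-sample testing for the gain arm, a seeded synthetic-screen generator
    with a hierarchical binomial count model, and an operating-characteristics
    harness (false-positive rate, power, effect recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
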