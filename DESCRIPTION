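Package: avidity
Title: Multivalent Adaptor-Scaffold Binding Equilibria from Polymer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative modelling of multivalent binding between a
    bivalent adaptor protein (two SH3 domains, e.g. Grb2) and a scaffold
    carrying several polyproline motifs in a disordered region (e.g. the
    Sos1 C-terminal tail). Detects class I/II polyproline motifs and
    linker architecture in protein sequences, computes effective local
    concentrations of tethered motifs from worm-like-chain end-to-end
    statistics combined with empirical inter-site distance distributions,
    assembles effective equilibrium constants for all 1:1 and 2:1
    adaptor-scaffold complexes, and solves the mass-action speciation of
    the resulting species at cellular concentrations. Ships the measured
    single-site dissociation constants and effective concentrations for
    the Grb2-Sos1 system as packaged fixtures, plus generators for
    synthetic distance traces, motif-bearing sequences and alignments
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
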