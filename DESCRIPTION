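Package: phosphowalk
Title: Phosphoproteome-Transcriptome Network Integration via Random Walks
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates phospho-antibody array readouts with expression
    signatures on a directed signaling network. Computes sign-adjusted
    phosphosite fold changes, layered functional annotation (self, kinases,
    regulated partners), random-walk-with-return proximity from signaling
    proteins to transcription factors, regulon-based transcription-factor
    activity estimation, and the selection rules that combine them, together
    with a fully synthetic data generator with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    ape
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
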