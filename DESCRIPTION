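Package: unskit
Title: Modular DNA Circuit Assembly with Unique Nucleotide Sequence Addressing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and in-silico verification toolkit for hierarchical,
    one-pot construction of multi-transcription-unit DNA circuits addressed
    by orthogonal 40-bp unique nucleotide sequences (UNSs). Provides
    restriction-site finding and digestion simulation on linear and circular
    DNA, nearest-neighbor melting temperatures, hairpin and cross-annealing
    scores, rejection-sampling design of orthogonal UNS sets, sequence-level
    models of position, carrier and adaptor vectors, assembly planning with
    marker-alternating adaptors and bench protocol arithmetic, simulation of
    isothermal (Gibson) one-pot assembly with junction and ambiguity
    analysis, diagnostic restriction-map prediction with a gel
    distinguishability model, and colony-screening statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
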