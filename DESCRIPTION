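Package: duoprobe
Title: Dual-Genome Oligonucleotide Probe Design and One-Channel
    Microarray Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing 60-mer expression probes that work
    across two divergent genomes (e.g. the japonica and indica rice
    subspecies) and for analysing the resulting one-channel microarray
    data. Covers candidate enumeration in the transcript 3' window with
    GC, low-complexity and self-complementarity filters; a seed-and-extend
    genome matcher with a seven-group cross-genome specificity
    classification; median-scaling normalization, technical-replicate QC,
    error-weighted log2 ratios with Welch tests, differential-expression
    and tissue-specificity calling; Fisher-exact term enrichment tables;
    and 2^-ddCt qPCR concordance. A synthetic-data module generates
    divergent genome pairs and replicate intensity data with known ground
    truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
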