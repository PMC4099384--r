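Package: talenarch
Title: Design and Analysis of TALE-FokI Nuclease Architectures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and characterising paired TALE-FokI nucleases
    in three scaffold geometries: the classical Tail-to-Tail (TtT) pair, the
    Head-to-Head (HtH) pair, and the asymmetric single-strand Tail-to-Head
    (TtH) pair. Provides RVD array design under the canonical code, paired
    target-site discovery and genome targetability scanning with
    target-devoid region reporting, off-target enumeration under Hamming
    mismatch tolerance, amplicon deep-sequencing indel classification with
    deletion-size and deletion-center statistics, and a synthetic-data
    generator (genomes with planted repeat expansions, reads under a
    parametric NHEJ indel model) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
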