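Package: prophager
Title: Prophage Activity Estimation from Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decides whether an integrated prophage is in the lytic (active)
    or lysogenic (dormant) stage of infection by statistical comparison of
    per-nucleotide read coverage over the prophage region versus the
    prophage-excluded flanking host region of the same scaffold. Reads are
    filtered by alignment percent identity, scaffold-end coverage is masked,
    and each prophage is scored by the prophage/host mean coverage ratio and
    the Cohen's d effect size of the coverage difference, gated by minimum
    coverage and breadth requirements. Includes parsers for manual and
    VIBRANT-style prophage coordinate tables, an orchestration layer for
    short-read aligners, a seeded synthetic read simulator for ground-truth
    benchmarking, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
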