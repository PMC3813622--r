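Package: scanmut
Title: Primer Design and Sequencing Verification for Scanning Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Batch design of mutagenic primer pairs for whole-plasmid
    overlapping PCR, covering codon selection, a GC-fraction melting
    temperature rule, GC-clamp quality scoring and exhaustive enumeration
    of primer geometries under length, temperature and overlap
    constraints.  Includes a gapless offset-scan aligner for
    semi-automatic verification of mutant sequencing reads with
    codon-level mutation calls, primer design for seamless
    (ligation-independent) cloning with three overhang-placement
    strategies, an in-silico mutagenesis and assembly simulator, and a
    seeded synthetic fixture generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
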