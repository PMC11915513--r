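Package: searchschemes
Title: Search Schemes for Lossless Approximate String Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Construction, validation and evaluation of search schemes for
    lossless approximate string matching in bidirectional FM-indices. Provides
    generators for classical filtration strategies recast as search schemes
    (backtracking, pigeonhole and optimized pigeonhole, suffix filter, 01*0
    seeds and their merged variant) together with a matrix-based construction
    heuristic; completeness, validity and redundancy checking by error
    configuration enumeration; node count and weighted node count performance
    metrics for Hamming and edit distance; and a reference bidirectional
    FM-index over small texts that executes schemes, with a brute-force
    dynamic-programming oracle for verification. Includes a deterministic
    simulator for random texts and reads carrying an exact number of errors,
    a canonical JSON scheme format, FASTA input and output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
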