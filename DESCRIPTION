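Package: psimeth
Title: Stress-Methylome Analysis: Permutation-Based Differential
    Methylation from Whole-Genome Bisulfite Sequencing Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from
    per-cytosine bisulfite sequencing count tables using a root-mean-square
    goodness-of-fit test calibrated by multinomial permutation with early
    stopping, selects the largest p-value cutoff controlling the false
    discovery rate, merges significant cytosines into regions with
    replicate-consistency filtering, and annotates regions against gene and
    transposable-element features.  Includes spike-in non-conversion
    correction of weighted methylation levels, persistence classification
    of regions across stress and recovery timepoints, and a synthetic-data
    generator emulating a phosphate-starvation study design for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
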