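Package: tandemloc
Title: Simulation and Inference for Tandemly Duplicated Herbicide-Resistance Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing tandem gene-duplication loci of the kind
    that confer glyphosate resistance through EPSPS amplification: a synthetic
    locus generator with a known truth channel (repeat arrays, mobile-element
    spacers, short reads, BAC-scale long fragments, qPCR Ct tables), read-depth
    CNV boundary detection and masked flank-normalized per-unit copy-number
    estimation, comparative-Ct qPCR quantification with junction-marker and
    primer-constraint logic, repeat-structure reconstruction from long
    fragments (anchoring, unit typing, insertion detection, overlap merging,
    junction microhomology), and a population simulator of array evolution by
    unequal crossing over with microhomology-mediated truncation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
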