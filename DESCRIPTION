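Package: barcodeEval
Title: Evaluation of DNA Barcode Loci by Distance, Gap, Identification
    and Monophyly Criteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate candidate DNA barcode loci and their
    multilocus combinations from species-labelled, pre-aligned nucleotide
    sequences. Computes Kimura 2-parameter pairwise distances with
    pairwise deletion, partitions them into intra- and inter-specific
    sets, tests for a barcoding gap, scores leave-one-out identification
    success under the best match, best close match and all species
    barcodes criteria, builds neighbor-joining trees with bootstrap
    support and per-species monophyly (discrimination) rates, and
    concatenates loci across shared individuals. A Kimura-process
    sequence simulator with controlled intra- and inter-specific
    divergence supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
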