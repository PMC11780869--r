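Package: endomap
Title: Mapping and Attribution of Endoribonuclease Cleavage Sites from
    Stabilized RNA End-Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls endoribonuclease cleavage sites in bacterial
    transcriptomes from paired 5'- and 3'-end sequencing of
    exoribonuclease-deficient strains, where cleavage products accumulate
    and their termini mark the cleaved phosphodiester bond. Sites are
    detected as abutting 3'/5' peak pairs using winsorized
    signal-to-background ratios, attributed to specific enzymes (RNase Y,
    RNase III, EndoA and others) through expression-normalized knockout
    sensitivity scores thresholded by a two-component Gaussian mixture,
    and characterized by RNA-duplex geometry (overhang and duplex length
    from minimum-free-energy folds), local sequence and structure
    context, and motif-anchored metagene profiles. Also quantifies
    massively parallel reporter assay (MPRA) libraries of cleavage-region
    variants via barcoded RNA-to-gDNA ratios, and ships a seeded
    synthetic-data generator emulating strain-genotype-dependent end
    tracks and MPRA read sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
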