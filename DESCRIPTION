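Package: mekit
Title: Discovery and Homology-Based Modeling of Plant Microexons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the smallest (1-15 nt) internal microexons in plant
    genomes. Detects microexon-spanning reads from spliced alignments (CIGAR
    N-gap patterns), calls microexons from multi-sample junction tables with
    percent spliced-in (PSI) estimation and annotation comparison, extracts
    in-frame 108-nt microexon-tags from coding transcripts and clusters them
    by BLOSUM62 peptide similarity, builds split position-weight matrices and
    scans genomes for microexon-tag loci across intron gaps with canonical
    splice sites, computes intron-retention (PIR) and detained-intron
    statistics with U-rich/G-rich intronic-enhancer window counting, and
    assembles concatenated consensus supermatrices for phylogenetics. Ships a
    seeded synthetic-fixture generator (genomes with planted microexons,
    exact-CIGAR spliced reads, mutated cross-species tag families) used to
    exercise every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
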