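Package: AmpliScreen
Title: Multi-Locus Amplicon Screening of Individual Mosquitoes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled multi-locus amplicon sequencing of
    individual wild-caught Anopheles mosquitoes. Routes multiplexed paired-end
    reads to samples and loci by barcode and primer, merges pairs into
    consensus amplicons, dereplicates them into unique-sequence count tables,
    and derives per-mosquito biology: kdr (L1014F) insecticide-resistance
    genotypes from the Seq2/(Seq1+Seq2) allele-ratio statistic, Anopheles
    species from the S200X6.1 marker with a cox1 fallback and F1-hybrid
    detection, mammalian blood-meal composition, and eukaryotic parasite or
    arbovirus detections against a packaged reference panel. Bacterial 16S
    communities are summarised with Bray-Curtis and weighted UniFrac
    dissimilarities, principal coordinates analysis, and a sequential
    distance-based PERMANOVA that partitions microbiota variance among
    collection site, species, genotype, blood-meal and infection status. A
    synthetic-data module simulates complete multiplexed runs with known
    ground truth, including extraction controls with low-level
    cross-contamination and a site-structured bacterial community with a
    controllable effect size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    ape,
    vegan,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phyloseq,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, Metagenomics, Microbiome, AmpliconVariants
RoxygenNote: 7.3.3
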