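Package: DivergeScan
Title: Demographic Inference and Genome Scans for RAD-Like SNP Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Population-genomic inference for diploid biallelic SNP panels
    from structured population samples, such as RAD-seq data from paired
    habitat populations in two geographic regions. Provides VCF import with
    a post-genotyping filter chain; Weir-Cockerham FST (per SNP, pairwise
    with locus bootstrap, and in sliding windows); diversity summaries
    (observed heterozygosity, minor-allele-frequency spectra, linkage
    disequilibrium decay, LD-based recent effective population size, runs
    of homozygosity, genomic relatedness); a structured-coalescent
    simulator for twenty two-population divergence models (panmixia,
    equilibrium migration, strict isolation, isolation-with-migration,
    ancient migration, secondary contact, each with optional beta-distributed
    heterogeneity in effective size and migration) feeding approximate
    Bayesian computation model choice and parameter estimation; redundancy
    analysis scans for environment-associated loci with permutation tests
    and loading-based outlier calls; and chromosomal inversion detection by
    windowed PCA and local PCA/MDS, karyotype assignment, arrangement-level
    statistics, and net-divergence dating. A synthetic study generator
    produces VCF, metadata, and ground-truth fixtures so that the complete
    pipeline is testable without access to any particular empirical data
    set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    vegan,
    ape,
    nnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
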