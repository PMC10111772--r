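Package: CaptivePopGen
Title: Population Genomics of Captive and Founder-Derived Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of small, captive or
    founder-derived populations from multi-sample SNP data: hard site
    filtering of VCF genotypes, outgroup polarization, windowed nucleotide
    diversity and Watterson's theta, Weir-Cockerham FST, identity-by-state
    and method-of-moments identity-by-descent relatedness, genotype PCA,
    neighbor-joining phylogenies with bootstrap support, sliding-window
    run-of-homozygosity detection with F_ROH and excess-homozygosity F_H
    inbreeding coefficients, Patterson's D (ABBA-BABA) and f4-ratio
    introgression tests with block-jackknife errors, impact-stratified
    deleterious-mutation load accounting with the Rxy purging statistic,
    k-mer genome-size estimation, and a forward Wright-Fisher simulator of
    founder/captive demography (selection, pedigrees, introgression pulses)
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, Genetics, Coverage, Simulation
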