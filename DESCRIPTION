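Package: introscan
Title: Detection and Characterization of Small Interspecies Introgression Tracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting small (10 kb to 500 kb) interspecies
    introgression tracts in whole-genome resequencing data of diploid
    populations. Discovers species-diagnostic alleles fixed between two
    species panels and polarized against an outgroup, classifies each
    individual's genotype at those sites, runs sliding-window statistics
    (average heterozygosity, heterozygous-site proportion, genotype-class
    proportions), calls tract borders with a two-stage 500-kb screen and
    1-kb refinement, assesses whether reduced-representation designs (RAD,
    ddRAD) would capture the diagnostic variation, fits linkage
    disequilibrium decay against a Loess-smoothed recombination map, and
    computes interallelic Ka/Ks by the Nei-Gojobori method. Includes a
    synthetic two-species genome simulator with a machine-readable truth
    set so every stage is testable without real sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    minpack.lm,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
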