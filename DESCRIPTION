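Package: popsweep
Title: Population Diversity, Linkage Disequilibrium and Selective-Sweep Scans
    from Multi-Sample VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for resequencing-based population genetics of
    structured cohorts: post-calling SNP filtering (hard INFO thresholds, SNP
    cluster and indel-proximity rules, per-genotype GQ masking), per-population
    diversity statistics (proportion of polymorphic markers, expected and
    observed heterozygosity, nucleotide diversity, polymorphism information
    content), linkage-disequilibrium decay from unphased genotypes via
    EM haplotype-frequency estimation, population structure (genotype PCA,
    identity-by-state distances, neighbor-joining trees), and selective-sweep
    detection by intersecting the top quantiles of sliding-window
    Weir-Cockerham FST and the theta-pi diversity ratio, with region merging
    and gene-overlap annotation. Includes a Balding-Nichols cohort simulator
    with injected sweeps and truth tables for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
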