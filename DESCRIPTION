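Package: twinmeth
Title: Twin-Cohort Analysis of Imprinted-Region DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of CpG-unit DNA methylation in
    monozygotic and dizygotic twin cohorts, with a focus on imprinting
    control regions. Provides an ACE-structured twin cohort simulator with
    allele-resolved (parent-of-origin) methylation and SNP haplotypes; an
    in-silico MassCleave (T-cleavage) forward model for bisulfite amplicons,
    including fragmentation, fragment masses, CpG-unit maps, SNP-dependent
    spectral peaks and methylation/genotype estimation from spectra;
    cohort-level quality filtering, summaries and Spearman correlation
    matrices; intra-pair discordance statistics with non-related null pairs,
    loss/gain-of-methylation calling and concordance tabulation with
    MZ-vs-DZ chi-square tests; genotype- and haplotype-stratified
    methylation analysis with parent-of-origin grouping; and position
    weight matrix scanning with variant substitution and enrichment
    meta-profiles around motif hits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
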