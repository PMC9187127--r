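Package: sdmafx
Title: Sex Differences in Allele Frequency on the X Chromosome
Version: 0.1.0
Authors@R:
    person("sdmafx", "maintainers", email = "maintainers@sdmafx.org",
           role = c("aut", "cre"))
Description: Region-aware testing for sex differences in minor allele
    frequency (sdMAF) on the human X chromosome. Tallies sex-stratified
    genotype counts from VCF or aggregated count tables, assigns variants
    to the pseudoautosomal regions (PAR1, PAR2), the X-transposed region
    (PAR3/XTR) or the non-pseudoautosomal region (NPR), and applies
    Hardy-Weinberg-disequilibrium-adjusted Wald chi-square tests that
    respect male ploidy in each region. Includes chi-square and exact
    Hardy-Weinberg tests (within sex, and jointly over hemizygous males
    and diploid females), population-stratified analysis with
    sample-size-weighted Z-score meta-analysis, minor-allele flip
    detection, Bland-Altman summaries, sliding-window smoothing of
    -log10 p-values, and a seeded synthetic genotype generator for
    validation and operating-characteristic studies. P-values are carried
    in log space so that values far below double precision (e.g. 1e-300)
    remain exact to representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
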