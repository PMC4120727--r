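Package: hapdiff
Title: Genome Scans for Allele-Frequency and Haplotype Differentiation
    Between Two Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic regions that are differentiated between two
    closely related populations from phased haplotype panels. Implements
    per-SNP two-population Wright's F_ST with genome-wide empirical
    p-values and a windowed exact-binomial enrichment scan, the iHS and
    XP-EHH extended-haplotype-homozygosity selection statistics with
    derived-allele-frequency-bin and genome-wide normalization, a
    tiered discovery plus cross-metric validation rule for reporting
    candidate regions, and a windowed haplotype similarity score for
    three-population comparisons. Ships a seeded phased-haplotype
    simulator (drift, linkage disequilibrium, admixture, hard selective
    sweeps) used as the test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
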