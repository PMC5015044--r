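Package: proxyreg
Title: LD Proxy Expansion and Regulatory Evidence Scoring for GWAS Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes potential regulatory variants downstream of a
    genome-wide association study. Index SNPs are expanded to proxy sets by
    computing pairwise linkage disequilibrium (r-squared, D') from phased
    haplotype panels, every variant is intersected with regulatory evidence
    tracks (transcription-factor ChIP-seq peaks, DNase peaks and footprints,
    motif instances, eQTL associations, histone marks), and each variant is
    assigned an ordered evidence category (1a-6, or no-data) by an explicit
    evidence-combination decision table. Includes allele-differential
    position-weight-matrix scoring for motif disruption, merging of
    annotations from a scoring and a secondary source, report tables, and a
    synthetic-data module that simulates haplotype panels with block LD
    structure and plants evidence tracks realizing any target category.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
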