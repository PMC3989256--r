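Package: sweepscan
Title: Selection Footprint Scanning with Haplotype and Allele-Frequency Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects footprints of recent selection on a chromosome from phased
    SNP-chip genotypes of one or more populations. Implements five complementary
    scan statistics -- extended haplotype homozygosity based XPEHH and iHS, a
    two-step Bayesian Fst with Beta posterior sampling, windowed Tajima's D, and
    a cross-population composite likelihood ratio (XPCLR-style) sweep scan --
    together with two empirical significance procedures (autosomal top-fraction
    cutoffs and permutation nulls), region building with extension and merging,
    cross-method overlap summaries, and a forward Wright-Fisher two-population
    sweep simulator for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
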