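Package: mitofam
Title: Mitochondrial DNA Heteroplasmy, Content and Transmission Analysis for Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mitochondrial DNA (mtDNA) variation in
    family-based disease cohorts from ultradeep sequencing data. Calls
    low-fraction heteroplasmies from per-site allele-count pileups with
    quality, strand-concordance and depth filters; estimates mtDNA content
    from mtDNA/autosome depth ratios or targeted consensus-read counts and
    standardizes it to a family-adjusted z-score (mtCNz); classifies variants
    as predicted pathogenic from external predictor score tables and assigns
    rank-based inverse-normal pathogenicity z-scores; classifies heteroplasmy
    origin (inherited versus de novo) via a read-count sharing test and tests
    germline purifying selection with one-sample t and stratified resampling
    tests; and fits the matched case-control association layer (conditional
    logistic regression, fixed-effect meta-analysis, population-attributable
    risk). A synthetic family-data generator with full truth tables supports
    calibration and power studies without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
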