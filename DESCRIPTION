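Package: stardiplo
Title: Star-Allele Diplotype Calling for CYP2D6 and CYP2C19 from
    Multi-Platform SNV and CNV Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls star-allele diplotypes for the pharmacogenes CYP2D6 and
    CYP2C19 from genotyping-platform observations: site genotype categories
    (WT/HET/MUT), copy-number probe calls at intragenic regions, and raw
    allelic signal ratios. Models CYP2D6 structural variation (the *5 whole
    gene deletion, xN duplications and multiplications, CYP2D7-2D6 and
    CYP2D6-2D7 hybrid genes and hybrid tandems) through a forward copy-number
    model and an inverse structural classifier, enumerates diplotypes
    consistent with unphased genotype categories, phases duplications from
    replicate allelic signal ratios, collapses calls to each platform's
    coverage, derives cross-platform consensus genotypes with concordance
    tables, computes activity scores and metabolizer phenotypes, and drives a
    clinical workflow state machine that recommends the next assay. A forward
    simulator of platform observations makes every component testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
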