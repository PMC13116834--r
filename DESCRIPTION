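Package: rvburden
Title: Rare-Variant Collapsing Burden Tests for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control rare-variant burden analysis for annotated cohort
    VCFs: qualifying-variant filtering by population allele frequency, site
    quality, depth and consequence class; per-gene collapsing of genotypes
    into heterozygous, compound-heterozygous and homozygous carrier
    categories under dominant and recessive inheritance models; exact
    Fisher burden tests on 2x2 carrier tables with Benjamini-Hochberg false
    discovery rate control; panel-level gene-set burden tests; and a
    synthetic cohort generator with Hardy-Weinberg genotype sampling so the
    whole pipeline can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    methods,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
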