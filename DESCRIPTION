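Package: steelheadAssoc
Title: Genotype-Phenotype Association for Steelhead Migration Timing and
    Age-at-Maturity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-usable pipeline linking two candidate genomic
    regions (the GREB1L/ROCK1 region of chromosome 28 and the SIX6 region
    of chromosome 25) to adult migration timing and age/size at maturity
    in Columbia River steelhead (Oncorhynchus mykiss).  PIT-tag detection
    histories are filtered into migration-timing phenotypes; genotypes are
    screened for linkage disequilibrium, pruned, and summarised into EM
    haplotype frequencies with per-individual posterior pairs;
    associations are tested with kinship-aware mixed linear models,
    sequential-covariate variance partitioning, haplotype score statistics
    with permutation nulls, and nonparametric per-group tests.  A
    synthetic-data module generates genotypes, phenotypes, and detection
    histories with the study system's assumed structure so that every
    stage is testable without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
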