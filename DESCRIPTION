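Package: triadcascade
Title: Sequential Multi-Omic Association Cascade for Drug-Sensitivity Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrative multi-omic discovery analysis linking cellular
    drug-sensitivity phenotypes, SNP genotypes, mRNA expression and miRNA
    expression into jointly associated (SNP, miRNA, gene) triads via a
    six-step sequential filtering cascade. Provides a synthetic-cohort
    generator with planted SNP -> miRNA -> gene -> phenotype effects for
    desk-scale validation, viability phenotyping utilities, a vectorised
    univariate regression/correlation engine with additive genotype coding,
    cross-cohort replication and allele-frequency screening, and a
    reproducible pipeline with manifest-based provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
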