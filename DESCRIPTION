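Package: tenderqtl
Title: GBLUP Association and Haplotype Fine-Mapping for Beef Tenderness QTL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis for Warner-Bratzler shear force
    in multi-breed beef cattle cohorts. Implements genotype quality control,
    window-based EM phasing and imputation, a genomic relationship matrix with
    X-linked male coding (VanRaden method 1), REML variance components under a
    single-trait animal model, GBLUP back-solving of SNP allele substitution
    effects with t-like normalization, rank-based across-breed QTL-region
    concordance, and sliding nine-SNP haplotype-window fine-mapping with
    percent-of-phenotypic-variance statistics. Includes a half-sib cohort
    simulator with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
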