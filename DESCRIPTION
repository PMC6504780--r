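Package: gwepi
Title: Genome-Wide SNP-SNP Interaction and Pathway Association Analysis
Version: 0.1.0
Authors@R: person("gwepi", "maintainers", email = "gwepi@example.org",
    role = c("aut", "cre"))
Description: Case/control genome-wide interaction (epistasis) screening with
    the allele-based odds-ratio Z statistic and allele-dosage logistic
    refinement, gene/locus mapping with interaction-cluster filtering, EM
    haplotype frequency estimation and per-haplotype association tests,
    permutation-based gene-set enrichment (GSEA) pathway association with
    FDR/FWER, a precomputed-P pathway method, PLINK text/binary genotype
    input/output with MAF/HWE/missingness quality control, and seeded
    synthetic-cohort generators with planted interaction, haplotype and
    pathway signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
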