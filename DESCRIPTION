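Package: cyp2cphase
Title: CYP2C19 Star-Allele Phasing and Metabolic Phenotype Assignment in the CYP2C Cluster
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers CYP2C haplotypes and CYP2C19 star-allele diplotypes from
    unphased SNP genotypes at six CYP2C-cluster loci by expectation-maximization,
    with per-individual diplotype posterior probabilities and a posterior-based
    inclusion threshold. Translates diplotypes into CYP2C19 metabolizer
    phenotypes (PM/IM/NM/RM/UM) under two schemes: the CPIC-style star-allele
    scheme and a combined CYP2C19-CYP2C scheme that credits the CYP2C:TG
    haplotype with increased activity. Includes Hardy-Weinberg goodness-of-fit
    and chi-square cohort comparisons, a seeded random-mating cohort simulator
    with frequency presets for four Native American cohorts, and a pipeline
    that renders cohort reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
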