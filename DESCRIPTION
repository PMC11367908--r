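Package: dsdscreen
Title: Recessive Variant Screening and Validation for SRY-Negative XX DSD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the variant-discovery and validation workflow used to
    study SRY-negative XX differences of sex development (DSD) in pigs: a
    four-criterion autosomal-recessive screen of nonsynonymous SNPs across a
    control/affected genome trio, a two-step structural-variant concordance
    screen with cohort burden summaries, candidate-gene panel prioritisation,
    cohort genotype and allele-frequency validation, ligation-probe relative
    copy-number quantification and classification, in-silico PCR amplicon
    prediction (including the WWOX intron-5 deletion assay and duplex SRY
    typing), and delta-delta-Ct expression analysis. Seeded synthetic-data
    generators with planted ground truth provide every input the pipeline
    consumes, so all stages are testable without access to raw genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
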