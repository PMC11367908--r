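#!/usr/bin/env Rscript
# Stage 6: the PCR assays and expression analysis — in-silico products of
# the WWOX deletion assay on both alleles, duplex SRY typing, and
# delta-delta-Ct fold changes against the normal-female calibrator.

suppressPackageStartupMessages(library(dsdscreen))
in_dir <- "results/simulated"

templates <- read_templates(file.path(in_dir, "wwox_assay_templates.fasta"))
primers <- wwox_assay_primers()
wt <- predict_amplicons(templates[["wildtype"]], primers)
del <- predict_amplicons(templates[["deletion"]], primers)
cat(sprintf("WWOX assay: wild-type band %d bp, deletion band %d bp (difference %d bp)\n",
            wt, del, wt - del))
cat(sprintf("  genotype banding: hom wild type -> {%d}; het -> {%d, %d}; hom deletion -> {%d}\n",
            wt, del, wt, del))

# duplex SRY typing of the trio as the screen would see it
lanes <- list(NF = list(GAPDH = TRUE, SRY = FALSE),
              D1 = list(GAPDH = TRUE, SRY = FALSE),
              D2 = list(GAPDH = TRUE, SRY = FALSE),
              reference_male = list(GAPDH = TRUE, SRY = TRUE),
              failed_lane = list(GAPDH = FALSE, SRY = FALSE))
for (id in names(lanes)) {
  cat(sprintf("  %-15s -> %s\n", id, sry_status(lanes[[id]])))
}

records <- read_expression_table(file.path(in_dir, "qpcr_ct.tsv"))
res <- ddct(records, "IFITM1", calibrator_group = "normal_female")
cat("delta-delta-Ct (IFITM1, calibrator normal_female):\n")
for (i in seq_len(nrow(res$per_group))) {
  g <- res$per_group[i, ]
  cat(sprintf("  %-13s n=%d  mean fold %.2f  (Welch p vs calibrator: %s)\n",
              g$group, g$n, g$mean_fold,
              ifelse(is.na(g$p_welch_vs_calibrator), "-",
                     sprintf("%.3g", g$p_welch_vs_calibrator))))
}
utils::write.table(res$per_individual, "results/ddct_folds.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/ddct_folds.tsv\n")
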