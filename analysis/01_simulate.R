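#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume.
# A trio variant table with planted screen classes, an SV table with planted
# concordance classes, a 32+32 validation cohort, ligation-probe signals
# with planted copy classes, triplicate qPCR records, and the deletion-assay
# template pair. All seeded; rerunning reproduces the files byte-for-byte.

suppressPackageStartupMessages(library(dsdscreen))
seed <- 20240901L
out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

trio <- generate_trio_snvs(trio_sim_config(
  kA = 50, kB = 30, kC = 20, kD = 10,
  k_shared_hom = 100, k_single_affected = 50,
  k_synonymous = 40, k_intronic = 200, seed = seed
))
write_snv_table(trio$variants, file.path(out_dir, "trio_snvs.tsv"), "tsv")
utils::write.table(trio$truth, file.path(out_dir, "trio_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("trio: %d variants (%d planted across criteria A-D)\n",
            nrow(trio$variants), sum(trio$truth$class %in% c("A", "B", "C", "D"))))

svs <- generate_sv_sets(sv_sim_config(
  n_concordant = 20, n_primary_only = 15, n_control_shared = 10, seed = seed
))
write_sv_table(svs$svs, file.path(out_dir, "trio_svs.tsv"), "tsv")
utils::write.table(svs$truth, file.path(out_dir, "sv_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("svs: %d records (%d concordant pairs planted)\n",
            nrow(svs$svs), sum(svs$truth$label == "concordant") / 2))

cohort <- generate_cohort(cohort_sim_config(
  loci = list(
    list(locus_id = "IFITM1_c218", alleles = c("T", "C"),
         affected = c(TT = 28, TC = 4), control = c(CC = 32)),
    list(locus_id = "NOBOX_c1043", alleles = c("C", "G"),
         affected = c(CC = 26, CG = 6), control = c(GG = 32))
  ),
  n_affected = 32, n_control = 32, mode = "exact", seed = seed
))
utils::write.table(cohort$table, file.path(out_dir, "cohort_genotypes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cohort: %d genotype rows at %d loci\n",
            nrow(cohort$table), length(unique(cohort$table$locus_id))))

# copy-number design: 32 diploid controls; affected cohort mixing classes
copies <- data.frame(
  sample_id = c(sprintf("ctl%02d", 1:32), sprintf("aff%02d", 1:32)),
  group = rep(c("control", "affected"), each = 32),
  copies = c(rep(2, 32), rep(c(0, 1, 1, 2), 8))
)
cnv <- generate_cnvplex(signal_sim_config(copies, probe = "wwox_del",
                                          cv = 0.1, seed = seed))
utils::write.table(cnv$signals, file.path(out_dir, "probe_signals.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cnv$truth, file.path(out_dir, "copy_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cnvplex: %d peak signals for %d samples\n",
            nrow(cnv$signals), length(unique(cnv$signals$sample_id))))

qpcr <- generate_qpcr(qpcr_sim_config(
  offsets = c(normal_female = 0, xx_dsd = -2, normal_male = 0.5),
  replicate_sd = 0.1, n_per_group = 3, gene = "IFITM1", seed = seed
))
utils::write.table(qpcr$records, file.path(out_dir, "qpcr_ct.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("qpcr: %d Ct rows, groups: %s\n", nrow(qpcr$records),
            paste(unique(qpcr$records$group), collapse = ", ")))

fixture <- generate_amplicon_fixture(seed = seed)
write_amplicon_fasta(fixture, file.path(out_dir, "wwox_assay_templates.fasta"))
cat(sprintf("amplicon templates: wild type %d bp, deletion allele %d bp\n",
            nchar(fixture$wildtype), nchar(fixture$deletion)))
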