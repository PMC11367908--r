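#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
dsd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dsdscreen", mustWork = FALSE)
  if (!nzchar(path)) abort("no packaged data file '%s'", file)
  path
}

#' Candidate-gene panel for the SNP screen
#'
#' The 11-gene panel used to prioritise screened SNPs (genes implicated in
#' sex development, germ-cell biology or steroidogenesis by public databases
#' and the literature).
#'
#' @return A [gene_panel()].
#' @export
candidate_gene_panel <- function() {
  read_gene_panel(dsd_extdata("candidate_snp_genes.tsv"))
}

#' The 14 candidate structural variants
#'
#' The curated candidate SV list taken into cohort validation (type,
#' coordinates 1-based inclusive, gene content; e.g. the 70 bp WWOX
#' intron-5 deletion at 6:9669113-9669182). Presence flags mark the two
#' affected genomes. The CCDC85C row's published coordinates omit the
#' chromosome; chromosome 7 (the pig CCDC85C locus) is used here.
#'
#' @return An [sv_table()].
#' @export
candidate_sv_table <- function() {
  read_sv_table(dsd_extdata("candidate_svs.tsv"), dialect = "tsv")
}

#' Synthetic cohort carrier table for candidate SVs
#'
#' A reconstructed 32-animal affected cohort whose per-SV carrier counts and
#' per-individual burden match the reported validation marginals (20 WWOX
#' deletion carriers of whom 14 carry only that SV; 4 PITX1-only, 2
#' SHC1-only and 2 chromosome-3-only carriers; 10 animals with two or more
#' candidate SVs). Individual-level assignments beyond those marginals are
#' synthetic. Includes each animal's intact-copy genotype at the WWOX
#' deletion locus (0/1/2 intact copies).
#'
#' @param path carrier TSV; defaults to the packaged synthetic cohort.
#' @return A list: `carriers` (named list individual -> SV ids, the
#'   [sv_burden()] input), `groups` (named character vector),
#'   `wwox_intact_copies` (named integer vector).
#' @export
read_sv_carriers <- function(path = dsd_extdata("sv_carriers_synthetic.tsv")) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("individual_id", "group", "sv_ids")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort("%s: missing columns: %s", path, paste(missing_cols, collapse = ", "))
  }
  carriers <- lapply(strsplit(df$sv_ids, ";", fixed = TRUE),
                     function(x) x[nzchar(x)])
  names(carriers) <- df$individual_id
  out <- list(carriers = carriers,
              groups = stats::setNames(df$group, df$individual_id))
  if ("wwox_intact_copies" %in% names(df)) {
    out$wwox_intact_copies <- stats::setNames(as.integer(df$wwox_intact_copies),
                                              df$individual_id)
  }
  out
}
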