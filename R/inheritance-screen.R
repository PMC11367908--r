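#' Per-sample zygosity sets of nonsynonymous variants
#'
#' For every sample, collects the variant keys of nonsynonymous variants the
#' sample carries: `all_ns` (het or hom), `hom_ns` (hom only) and `het_ns`
#' (het only). These sets are the substrate of the four-criterion recessive
#' screen. `no_call` genotypes are treated as unevaluable and enter no set;
#' the number of excluded no-calls is recorded in the `n_no_call` attribute.
#'
#' @param variants an [snv_table()].
#' @param roles a [sample_roles()] data.frame with exactly one
#'   `control_female` and at least two `affected` samples, all present as
#'   genotype columns of `variants`.
#' @param effects coding-effect classes admitted to the screen; defaults to
#'   `"nonsynonymous"` (the study's criterion). Widen to e.g.
#'   `c("nonsynonymous", "stopgain", "stoploss")` to include truncating
#'   variants.
#' @return An object of class `zygosity_sets`: a named list (one element per
#'   sample) of lists with character-vector members `all_ns`, `hom_ns`,
#'   `het_ns`, carrying the `roles` and `n_no_call` attributes.
#' @export
build_zygosity_sets <- function(variants, roles,
                                effects = "nonsynonymous") {
  stopifnot(inherits(variants, "snv_table"), is.data.frame(roles))
  if (sum(roles$role == "control_female") != 1L) {
    abort("exactly one control_female sample is required")
  }
  if (sum(roles$role == "affected") < 2L) {
    abort("at least two affected samples are required")
  }
  missing_samples <- setdiff(roles$sample_id, table_samples(variants))
  if (length(missing_samples)) {
    abort("samples not in variant table: %s", paste(missing_samples, collapse = ", "))
  }
  keep <- variants$effect %in% effects
  keys <- variant_key(variants)
  n_no_call <- 0L
  sets <- lapply(roles$sample_id, function(s) {
    gt <- variants[[s]]
    n_no_call <<- n_no_call + sum(keep & gt == "no_call")
    list(
      all_ns = keys[keep & gt %in% c("het", "hom")],
      hom_ns = keys[keep & gt == "hom"],
      het_ns = keys[keep & gt == "het"]
    )
  })
  names(sets) <- roles$sample_id
  attr(sets, "roles") <- roles
  attr(sets, "n_no_call") <- n_no_call
  class(sets) <- "zygosity_sets"
  sets
}

#' One criterion of the autosomal-recessive screen
#'
#' The four zygosity-pattern criteria over the control (NF) and affected
#' (D1, D2, ...) genomes:
#' \describe{
#'   \item{A}{homozygous nonsynonymous in every affected genome, absent from
#'     the control: `intersect(affected hom) \ control all`.}
#'   \item{B}{homozygous nonsynonymous only in the control:
#'     `control hom \ union(affected all)`.}
#'   \item{C}{homozygous in every affected genome and heterozygous in the
#'     control: `intersect(affected hom) ∩ control het`.}
#'   \item{D}{heterozygous nonsynonymous only in the control:
#'     `control het \ union(affected all)`.}
#' }
#' With more than two affected samples the intersections/unions extend over
#' all of them; the trio is the special case.
#'
#' @param sets a [build_zygosity_sets()] result.
#' @param criterion one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return Character vector of variant keys selected by the criterion.
#' @export
screen_criterion <- function(sets, criterion = c("A", "B", "C", "D")) {
  criterion <- match.arg(criterion)
  roles <- attr(sets, "roles")
  ctrl <- sets[[roles$sample_id[roles$role == "control_female"]]]
  aff <- sets[roles$sample_id[roles$role == "affected"]]
  aff_hom <- Reduce(intersect, lapply(aff, `[[`, "hom_ns"))
  aff_all <- Reduce(union, lapply(aff, `[[`, "all_ns"))
  switch(criterion,
    A = setdiff(aff_hom, ctrl$all_ns),
    B = setdiff(ctrl$hom_ns, aff_all),
    C = intersect(aff_hom, ctrl$het_ns),
    D = setdiff(ctrl$het_ns, aff_all)
  )
}

#' Run the full four-criterion recessive screen
#'
#' Builds the zygosity sets and evaluates criteria A-D. The four result sets
#' are pairwise disjoint by construction (hom/het are disjoint within a
#' sample and presence/absence in the control partition A/C from B/D), so
#' the screen total is the sum of the four set sizes.
#'
#' @inheritParams build_zygosity_sets
#' @return A list of class `screen_result`: `criteria` (named list of key
#'   vectors for A-D), `counts` (named integer vector), `total`
#'   (`|A| + |B| + |C| + |D|`), and `union` (all selected keys).
#' @export
screen_all <- function(variants, roles, effects = "nonsynonymous") {
  sets <- build_zygosity_sets(variants, roles, effects = effects)
  criteria <- lapply(c(A = "A", B = "B", C = "C", D = "D"),
                     function(cr) screen_criterion(sets, cr))
  counts <- vapply(criteria, length, integer(1))
  structure(
    list(criteria = criteria, counts = counts,
         total = sum(counts), union = unlist(criteria, use.names = FALSE)),
    class = "screen_result"
  )
}

#' @exportS3Method base::print
print.screen_result <- function(x, ...) {
  cat("Recessive screen:",
      sprintf("A=%d B=%d C=%d D=%d", x$counts[["A"]], x$counts[["B"]],
              x$counts[["C"]], x$counts[["D"]]),
      sprintf("(total %d)\n", x$total))
  invisible(x)
}

#' Restrict screened variants to a candidate-gene panel
#'
#' Keeps the variants whose key is among `keys` and whose gene symbol is in
#' the panel, mirroring the study's prioritisation of screened SNPs against
#' genes implicated in sex development by databases and literature.
#'
#' @param keys character vector of variant keys (e.g. a criterion's output).
#' @param variants the [snv_table()] the keys were screened from.
#' @param panel a [gene_panel()].
#' @return The matching rows of `variants`, sorted by `(chrom, pos)`.
#' @export
filter_by_panel <- function(keys, variants, panel) {
  stopifnot(inherits(variants, "snv_table"), inherits(panel, "gene_panel"))
  hit <- variant_key(variants) %in% keys & variants$gene %in% panel$gene
  out <- variants[hit, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- table_samples(variants)
  class(out) <- c("snv_table", "data.frame")
  out
}
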