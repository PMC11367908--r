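#' Construct a cohort genotype table
#'
#' Long format, one row per individual and locus: the two observed alleles
#' (both empty for a missing genotype) plus an `affected`/`control` group
#' label. Genotype labels are unordered allele multisets, written with the
#' alleles in lexicographic order (so `TC` and `CT` are the same genotype,
#' displayed `CT`... see `genotype_label`).
#'
#' @param df data.frame with columns
#'   `individual_id, group, locus_id, allele1, allele2`.
#' @return A validated data.frame of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(df) {
  need <- c("individual_id", "group", "locus_id", "allele1", "allele2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  for (col in need) df[[col]] <- as.character(df[[col]])
  bad_group <- setdiff(unique(df$group), c("affected", "control"))
  if (length(bad_group)) abort("unknown group: %s", paste(bad_group, collapse = ", "))
  if (anyDuplicated(df[, c("individual_id", "locus_id")])) {
    abort("(individual_id, locus_id) pairs must be unique")
  }
  half <- xor(nzchar(df$allele1), nzchar(df$allele2))
  if (any(half)) abort("half-missing genotype for individual %s",
                       df$individual_id[which(half)[1]])
  rownames(df) <- NULL
  class(df) <- c("cohort_genotypes", "data.frame")
  df
}

#' Read a cohort genotype table from TSV
#'
#' @param path TSV with the [cohort_genotypes()] columns; empty allele cells
#'   encode missing genotypes.
#' @return A [cohort_genotypes()] table.
#' @export
read_cohort_genotypes <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  df$allele1[is.na(df$allele1)] <- ""
  df$allele2[is.na(df$allele2)] <- ""
  cohort_genotypes(df)
}

# canonical unordered genotype label: alleles sorted lexicographically
genotype_label <- function(a1, a2) {
  mapply(function(x, y) paste(sort(c(x, y)), collapse = ""), a1, a2,
         USE.NAMES = FALSE)
}

# all alleles seen at a locus across both groups (declared allele set)
locus_alleles <- function(table, locus) {
  rows <- table[table$locus_id == locus & nzchar(table$allele1), , drop = FALSE]
  sort(unique(c(rows$allele1, rows$allele2)))
}

# all genotype labels over an allele set, lexicographic
all_genotype_labels <- function(alleles) {
  if (!length(alleles)) return(character(0))
  combos <- expand.grid(a = alleles, b = alleles, stringsAsFactors = FALSE)
  sort(unique(genotype_label(combos$a, combos$b)))
}

#' Genotype counts and frequencies for one locus and group
#'
#' Tallies the typed individuals of a group at a locus into unordered
#' genotype classes over the locus's observed allele set (so genotypes seen
#' only in the other group are reported at frequency 0, as in a
#' case/control validation table). Missing genotypes are excluded from
#' `n_typed` and counted in `n_missing`.
#'
#' @param table a [cohort_genotypes()] table.
#' @param locus locus id.
#' @param group `"affected"` or `"control"`.
#' @return A list of class `freq_entry`: `locus`, `group`, `n_typed`,
#'   `n_missing`, `genotype_counts`, `genotype_freq` (named numeric vectors
#'   over all genotype labels, lexicographic), `allele_counts`,
#'   `allele_freq`.
#' @examples
#' # 28 TT + 4 TC among 32 affected -> TT 0.875, TC 0.125, CC 0
#' @export
genotype_frequencies <- function(table, locus, group = c("affected", "control")) {
  group <- match.arg(group)
  stopifnot(inherits(table, "cohort_genotypes"))
  if (!locus %in% table$locus_id) abort("unknown locus: %s", locus)
  alleles <- locus_alleles(table, locus)
  rows <- table[table$locus_id == locus & table$group == group, , drop = FALSE]
  typed <- rows[nzchar(rows$allele1), , drop = FALSE]
  if (!nrow(typed)) abort("no typed individuals for locus %s in group %s", locus, group)
  labels <- all_genotype_labels(alleles)
  obs <- genotype_label(typed$allele1, typed$allele2)
  bad <- setdiff(unique(c(typed$allele1, typed$allele2)), alleles)
  if (length(bad)) abort("allele outside locus allele set: %s", paste(bad, collapse = ", "))
  counts <- vapply(labels, function(l) sum(obs == l), integer(1))
  n_typed <- nrow(typed)
  allele_counts <- vapply(alleles, function(a) {
    sum((typed$allele1 == a) + (typed$allele2 == a))
  }, integer(1))
  entry <- list(
    locus = locus, group = group,
    n_typed = n_typed, n_missing = nrow(rows) - n_typed,
    genotype_counts = counts,
    genotype_freq = counts / n_typed,
    allele_counts = allele_counts,
    allele_freq = allele_counts / (2 * n_typed)
  )
  class(entry) <- "freq_entry"
  entry
}

#' Allele frequencies from a genotype-frequency entry
#'
#' `freq(x) = (2 * hom_x + het_containing_x) / (2 * n_typed)`. Computation
#' carries full precision; use [display_freq()] for the 3-decimal
#' round-half-even display convention.
#'
#' @param entry a [genotype_frequencies()] result.
#' @return Named numeric vector of allele frequencies.
#' @export
allele_frequencies <- function(entry) {
  stopifnot(inherits(entry, "freq_entry"))
  entry$allele_freq
}

#' Display rounding for reported frequencies
#'
#' Round-half-even at 3 decimals (base R's `round`), the convention used for
#' reported genotype and allele frequencies; computations elsewhere keep
#' full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3).
#' @return Rounded numeric vector.
#' @export
display_freq <- function(x, digits = 3) round(x, digits)

#' Which genotypes are exclusive to one group at a locus
#'
#' Partitions the genotype labels observed at a locus into those seen only
#' in affected individuals, only in controls, or in both — the comparison
#' behind calling a genotype "exclusively found" in the affected cohort.
#'
#' @param table a [cohort_genotypes()] table.
#' @param locus locus id; both groups must have typed individuals there.
#' @return List with character vectors `affected_only_genotypes`,
#'   `control_only_genotypes`, `shared`.
#' @export
exclusivity_check <- function(table, locus) {
  stopifnot(inherits(table, "cohort_genotypes"))
  observed <- function(group) {
    rows <- table[table$locus_id == locus & table$group == group &
                    nzchar(table$allele1), , drop = FALSE]
    if (!nrow(rows)) abort("group %s has no typed individuals at locus %s", group, locus)
    unique(genotype_label(rows$allele1, rows$allele2))
  }
  aff <- observed("affected")
  ctl <- observed("control")
  list(
    affected_only_genotypes = sort(setdiff(aff, ctl)),
    control_only_genotypes = sort(setdiff(ctl, aff)),
    shared = sort(intersect(aff, ctl))
  )
}

#' Carrier prevalence from intact-copy genotypes
#'
#' For a deletion locus typed as copies of the intact segment (0, 1 or 2), an
#' individual with at most one intact copy carries at least one
#' deletion-bearing allele. Returns the carrier fraction with its
#' numerator/denominator.
#'
#' @param cn_genotypes named integer vector: individual id -> intact copies
#'   (0, 1 or 2).
#' @param groups optional named character vector of group labels parallel to
#'   `cn_genotypes`; with `group` set, only that group's individuals count.
#' @param group optional group label filter.
#' @return List of class `carrier_prevalence`: `fraction`, `n_carriers`,
#'   `n_total`.
#' @examples
#' carrier_prevalence(c(a = 0, b = 1, c = 2, d = 2))  # 2/4 carriers
#' @export
carrier_prevalence <- function(cn_genotypes, groups = NULL, group = NULL) {
  if (!is.null(group)) {
    if (is.null(groups)) abort("group filter given without group labels")
    cn_genotypes <- cn_genotypes[groups == group]
  }
  if (!length(cn_genotypes)) abort("empty group")
  if (any(!cn_genotypes %in% 0:2)) abort("intact-copy genotypes must be 0, 1 or 2")
  n_car <- sum(cn_genotypes <= 1)
  structure(list(fraction = n_car / length(cn_genotypes),
                 n_carriers = n_car, n_total = length(cn_genotypes)),
            class = "carrier_prevalence")
}

#' Allele-count association test at a biallelic locus
#'
#' An extension beyond the motivating study (which reports frequencies
#' only): a Fisher exact test on the 2x2 allele-count table
#' (group x allele), with the Haldane-Anscombe 0.5 correction applied to the
#' odds ratio when any cell is zero so the estimate stays finite and
#' positive. The p-value is the exact (uncorrected) Fisher probability.
#'
#' @param table a [cohort_genotypes()] table.
#' @param locus a biallelic locus typed in both groups.
#' @return List: `odds_ratio`, `p_value`, `counts` (2x2 matrix,
#'   rows affected/control, columns the two alleles).
#' @export
association_test <- function(table, locus) {
  aff <- genotype_frequencies(table, locus, "affected")
  ctl <- genotype_frequencies(table, locus, "control")
  alleles <- union(names(aff$allele_counts), names(ctl$allele_counts))
  if (length(alleles) != 2L) {
    abort("association_test requires exactly two alleles (locus %s has %d)",
          locus, length(alleles))
  }
  m <- rbind(
    affected = aff$allele_counts[alleles],
    control = ctl$allele_counts[alleles]
  )
  m[is.na(m)] <- 0L
  colnames(m) <- alleles
  if (any(colSums(m) == 0L)) abort("degenerate table: an allele is absent everywhere")
  p <- stats::fisher.test(m)$p.value
  mc <- if (any(m == 0L)) m + 0.5 else m
  or <- (mc[1, 1] * mc[2, 2]) / (mc[1, 2] * mc[2, 1])
  list(odds_ratio = unname(or), p_value = p, counts = m)
}
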