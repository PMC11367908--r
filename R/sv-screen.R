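#' Structural-variant matching policy
#'
#' Controls when two SV records from different genomes are considered the
#' same event. `gene_and_type` (the default) follows the study's criterion —
#' same variant type and shared gene content at compatible positions;
#' `reciprocal_overlap` is the common positional alternative for gene-sparse
#' regions.
#'
#' @param mode `"gene_and_type"` or `"reciprocal_overlap"`.
#' @param min_reciprocal_overlap fraction in (0, 1]; both records must be
#'   covered by the overlap to at least this fraction (ignored in
#'   `gene_and_type` mode). Default 0.5.
#' @param breakpoint_tolerance positive integer bp; how far apart breakpoints
#'   may sit and still be treated as the same position. Default 1000.
#' @return A list of class `sv_match_policy`.
#' @export
sv_match_policy <- function(mode = c("gene_and_type", "reciprocal_overlap"),
                            min_reciprocal_overlap = 0.5,
                            breakpoint_tolerance = 1000L) {
  mode <- match.arg(mode)
  if (!(min_reciprocal_overlap > 0 && min_reciprocal_overlap <= 1)) {
    abort("min_reciprocal_overlap must be in (0, 1]")
  }
  if (breakpoint_tolerance <= 0) abort("breakpoint_tolerance must be positive")
  structure(list(mode = mode,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 breakpoint_tolerance = as.integer(breakpoint_tolerance)),
            class = "sv_match_policy")
}

# 1-based inclusive overlap length; 0 if disjoint or different chromosomes
sv_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start) + 1L)
}

# smallest distance between any breakpoint of a and any breakpoint of b
sv_breakpoint_dist <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  min(abs(outer(c(a$start, a$end), c(b$start, b$end), "-")))
}

as_sv_record <- function(x) {
  if (inherits(x, "sv_table") || is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(as.data.frame(x))
  }
  x$gene_set <- toupper(sv_genes(x$genes %||% "")[[1]])
  x
}

#' Do two SV records describe the same event?
#'
#' In `gene_and_type` mode, `TRUE` iff the types are equal, the gene sets
#' intersect, and the intervals either overlap by at least 1 bp or have
#' nearest breakpoints within the tolerance. Records with empty gene sets
#' (intergenic events, for which a gene criterion is undefined) are instead
#' matched on type plus breakpoint proximity. In `reciprocal_overlap` mode,
#' `TRUE` iff the types and chromosome are equal and the overlap covers at
#' least `min_reciprocal_overlap` of both records — except inversions, which
#' are balanced events and are matched on both breakpoints lying within the
#' tolerance.
#'
#' The predicate is symmetric in its two records in both modes.
#'
#' @param a,b single SV records (one-row [sv_table()] slices or lists with
#'   fields `sv_type, chrom, start, end, genes`).
#' @param policy an [sv_match_policy()].
#' @return Logical scalar.
#' @export
sv_match <- function(a, b, policy = sv_match_policy()) {
  a <- as_sv_record(a); b <- as_sv_record(b)
  if (a$sv_type != b$sv_type) return(FALSE)
  tol <- policy$breakpoint_tolerance
  both_ends_close <- a$chrom == b$chrom &&
    abs(a$start - b$start) <= tol && abs(a$end - b$end) <= tol
  if (policy$mode == "gene_and_type") {
    near <- sv_overlap_bp(a, b) >= 1L || sv_breakpoint_dist(a, b) <= tol
    if (length(a$gene_set) == 0L && length(b$gene_set) == 0L) {
      return(near)
    }
    length(intersect(a$gene_set, b$gene_set)) > 0L && near
  } else {
    if (a$chrom != b$chrom) return(FALSE)
    if (a$sv_type == "inversion") return(both_ends_close)
    ov <- sv_overlap_bp(a, b)
    ov / (a$end - a$start + 1) >= policy$min_reciprocal_overlap &&
      ov / (b$end - b$start + 1) >= policy$min_reciprocal_overlap
  }
}

sv_rows_present <- function(svs, sample) {
  if (!sample %in% table_samples(svs)) abort("unknown sample: %s", sample)
  subset_sv_table(svs, svs[[sample]])
}

# list of per-row record lists for fast pairwise matching
sv_record_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as_sv_record(df[i, , drop = FALSE]))
}

subset_sv_table <- function(svs, idx) {
  out <- svs[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- table_samples(svs)
  class(out) <- c("sv_table", "data.frame")
  out
}

#' Screen step A: SVs specific to an affected genome
#'
#' Returns the SVs carried by the primary affected genome that have no
#' matching event (under the policy) among the SVs carried by the control
#' genome.
#'
#' @param svs an [sv_table()] with presence columns for both samples.
#' @param control,affected sample ids.
#' @param policy an [sv_match_policy()].
#' @return The selected rows as an [sv_table()].
#' @export
screen_step_a <- function(svs, control, affected, policy = sv_match_policy()) {
  stopifnot(inherits(svs, "sv_table"))
  aff <- sv_rows_present(svs, affected)
  ctl <- sv_record_list(sv_rows_present(svs, control))
  keep <- vapply(sv_record_list(aff), function(a) {
    !any(vapply(ctl, function(c) sv_match(a, c, policy), logical(1)))
  }, logical(1))
  subset_sv_table(aff, keep)
}

#' Screen step B: concordance with the second affected genome
#'
#' Keeps the step-A survivors that match (under the policy) at least one SV
#' carried by the other affected genome — the study's requirement that both
#' affected genomes show the same variant gene positions and types.
#'
#' @param step_a an [sv_table()] produced by [screen_step_a()].
#' @param other_affected an [sv_table()] of (or containing) the second
#'   affected genome's SVs; if it has a presence column named
#'   `other_sample`, only rows present in that sample are used.
#' @param policy an [sv_match_policy()].
#' @param other_sample optional sample id selecting rows of `other_affected`.
#' @return The concordant rows of `step_a` as an [sv_table()].
#' @export
screen_step_b <- function(step_a, other_affected, policy = sv_match_policy(),
                          other_sample = NULL) {
  stopifnot(inherits(step_a, "sv_table"))
  other <- if (!is.null(other_sample)) {
    sv_rows_present(other_affected, other_sample)
  } else other_affected
  other <- sv_record_list(other)
  keep <- vapply(sv_record_list(step_a), function(a) {
    any(vapply(other, function(b) sv_match(a, b, policy), logical(1)))
  }, logical(1))
  subset_sv_table(step_a, keep)
}

#' Per-individual candidate-SV burden in a cohort
#'
#' Counts, for each cohort member, how many candidate SVs it carries, and
#' summarises the cohort into individuals carrying exactly one, two or more,
#' or zero candidate SVs. Also reports, per SV, how many individuals carry
#' only that SV (exclusive carriers).
#'
#' @param carriers named list: individual id -> character vector of carried
#'   candidate-SV ids (individuals absent from the list carry none).
#' @param cohort_size total number of individuals in the cohort (>= number
#'   of listed carriers).
#' @return A list of class `sv_burden`: `per_individual` (named integer
#'   vector over the listed carriers), `summary` (list with `exactly_one`,
#'   `two_or_more`, `zero`), and `exclusive_carriers` (named integer vector
#'   per SV id).
#' @export
sv_burden <- function(carriers, cohort_size) {
  ids <- names(carriers) %||% character(0)
  if (anyDuplicated(ids)) abort("individual ids must be unique")
  carriers <- lapply(carriers, unique)
  n_per <- vapply(carriers, length, integer(1))
  carriers <- carriers[n_per > 0L]
  n_per <- n_per[n_per > 0L]
  if (cohort_size < length(n_per)) {
    abort("cohort_size (%d) smaller than number of carriers (%d)",
          cohort_size, length(n_per))
  }
  singles <- unlist(carriers[n_per == 1L], use.names = FALSE)
  all_svs <- unique(unlist(carriers, use.names = FALSE))
  exclusive <- vapply(all_svs, function(sv) sum(singles == sv), integer(1))
  structure(
    list(
      per_individual = n_per,
      summary = list(
        exactly_one = sum(n_per == 1L),
        two_or_more = sum(n_per >= 2L),
        zero = cohort_size - length(n_per)
      ),
      exclusive_carriers = exclusive
    ),
    class = "sv_burden"
  )
}
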