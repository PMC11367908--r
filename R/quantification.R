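DEFAULT_REFERENCE_PROBES <- c("ACTB", "COL10A1", "GCG")

#' Construct a ligation-probe signal table
#'
#' Long format: one fluorescent peak signal per sample and probe. Each
#' sample must carry all three reference probes (defaults `ACTB`,
#' `COL10A1`, `GCG` — the internal reference controls of the multiplex
#' ligation assay) alongside its target probes.
#'
#' @param df data.frame with columns `sample_id, group, probe_id,
#'   peak_signal` (peak signals strictly positive).
#' @param reference_probes character vector of the three reference probe ids.
#' @return A validated data.frame of class `probe_signals` with a
#'   `reference_probes` attribute.
#' @export
probe_signals <- function(df, reference_probes = DEFAULT_REFERENCE_PROBES) {
  need <- c("sample_id", "group", "probe_id", "peak_signal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (length(reference_probes) != 3L) abort("exactly three reference probes are required")
  df <- df[, need, drop = FALSE]
  df$peak_signal <- as.numeric(df$peak_signal)
  if (any(!is.finite(df$peak_signal)) || any(df$peak_signal <= 0)) {
    abort("peak_signal must be positive")
  }
  if (anyDuplicated(df[, c("sample_id", "probe_id")])) {
    abort("(sample_id, probe_id) pairs must be unique")
  }
  for (s in unique(df$sample_id)) {
    have <- df$probe_id[df$sample_id == s]
    lack <- setdiff(reference_probes, have)
    if (length(lack)) abort("sample %s lacks reference probe %s", s, lack[1])
  }
  rownames(df) <- NULL
  attr(df, "reference_probes") <- reference_probes
  class(df) <- c("probe_signals", "data.frame")
  df
}

#' Read a probe signal table from TSV
#'
#' @param path TSV with the [probe_signals()] columns.
#' @param reference_probes reference probe ids (default `ACTB`, `COL10A1`,
#'   `GCG`).
#' @return A [probe_signals()] table.
#' @export
read_probe_signals <- function(path, reference_probes = DEFAULT_REFERENCE_PROBES) {
  probe_signals(utils::read.delim(path, check.names = FALSE), reference_probes)
}

peak_of <- function(table, sample, probe) {
  v <- table$peak_signal[table$sample_id == sample & table$probe_id == probe]
  if (!length(v)) return(NA_real_)
  v[1]
}

#' Reference-normalised probe signal
#'
#' The target probe's peak divided by the arithmetic mean of the sample's
#' three reference-probe peaks — the within-sample normalisation of the
#' ligation assay. Scale-invariant: multiplying all of a sample's peaks by a
#' constant leaves it unchanged.
#'
#' @param table a [probe_signals()] table.
#' @param sample sample id.
#' @param probe target probe id.
#' @return Numeric scalar.
#' @export
normalize_signal <- function(table, sample, probe) {
  stopifnot(inherits(table, "probe_signals"))
  refs <- attr(table, "reference_probes")
  target <- peak_of(table, sample, probe)
  if (is.na(target)) abort("sample %s has no probe %s", sample, probe)
  ref_peaks <- vapply(refs, function(r) peak_of(table, sample, r), numeric(1))
  if (anyNA(ref_peaks)) {
    abort("sample %s lacks reference probe %s", sample, refs[which(is.na(ref_peaks))[1]])
  }
  target / mean(ref_peaks)
}

#' Relative copy number of a target segment across samples
#'
#' Normalised signals are scaled so that the control samples' median sits at
#' 2 copies (diploid): `relative_cn(s) = 2 * norm(s) / median(norm(control))`.
#' The median baseline is robust to a contaminating deletion carrier among
#' the controls.
#'
#' @param table a [probe_signals()] table.
#' @param probe target probe id.
#' @param controls character vector of control sample ids (non-empty, all
#'   carrying the probe).
#' @param samples samples to call; defaults to every sample carrying the
#'   probe.
#' @param thresholds copy-class thresholds passed to
#'   [classify_copy_class()].
#' @return A data.frame of class `cn_calls`: `sample_id`,
#'   `normalized_signal`, `relative_cn`, `copy_class`.
#' @export
relative_copy_number <- function(table, probe, controls, samples = NULL,
                                 thresholds = c(0.5, 1.5, 2.5)) {
  stopifnot(inherits(table, "probe_signals"))
  if (!length(controls)) abort("empty control set")
  if (is.null(samples)) {
    samples <- unique(table$sample_id[table$probe_id == probe])
  }
  norm <- vapply(samples, function(s) normalize_signal(table, s, probe), numeric(1))
  ctrl_norm <- vapply(controls, function(s) normalize_signal(table, s, probe), numeric(1))
  baseline <- stats::median(ctrl_norm)
  rel <- 2 * norm / baseline
  out <- data.frame(
    sample_id = samples,
    normalized_signal = unname(norm),
    relative_cn = unname(rel),
    copy_class = vapply(unname(rel), classify_copy_class, character(1),
                        thresholds = thresholds),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cn_calls", "data.frame")
  out
}

#' Classify a relative copy number into a copy class
#'
#' Default thresholds in copy units: below 0.5 -> `"0"` (homozygous loss),
#' 0.5 to 1.5 -> `"1"` (heterozygous loss), 1.5 to 2.5 -> `"2"` (diploid),
#' 2.5 and above -> `"gain"`.
#'
#' @param relative_cn non-negative copy-number estimate (diploid = 2).
#' @param thresholds increasing numeric vector of the three class
#'   boundaries.
#' @return One of `"0"`, `"1"`, `"2"`, `"gain"`.
#' @export
classify_copy_class <- function(relative_cn, thresholds = c(0.5, 1.5, 2.5)) {
  if (!is.finite(relative_cn) || relative_cn < 0) {
    abort("relative_cn must be non-negative")
  }
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  if (relative_cn < thresholds[1]) "0"
  else if (relative_cn < thresholds[2]) "1"
  else if (relative_cn < thresholds[3]) "2"
  else "gain"
}

#' A PCR primer pair
#'
#' @param forward,reverse primer sequences, non-empty strings over
#'   `{A,C,G,T}` (degenerate bases unsupported; assay primers are exact).
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (!is_dna(forward) || !is_dna(reverse)) {
    abort("primers must be non-empty strings over {A,C,G,T}")
  }
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' Primer pair of the WWOX intron-5 deletion assay
#'
#' The published assay amplifies 298 bp from the wild-type allele and
#' 228 bp from the allele carrying the 70 bp intron-5 deletion.
#'
#' @return A [primer_pair()].
#' @export
wwox_assay_primers <- function() {
  primer_pair("ATCCTCGCAGGACACAGGAG", "TGTGTAGCGGCCTCCAGAAG")
}

#' In-silico PCR: predicted amplicon lengths
#'
#' Finds every exact occurrence of the forward primer on the given strand
#' and of the reverse-complemented reverse primer downstream of it; each
#' forward/reverse pairing with the forward site first yields a product of
#' length `end(reverse site) - start(forward site) + 1` (1-based inclusive).
#' No product is not an error — the template simply does not amplify.
#'
#' @param template DNA string (or `Biostrings::DNAString`).
#' @param primers a [primer_pair()].
#' @return Integer vector of product lengths in bp, sorted ascending (empty
#'   if no product).
#' @export
predict_amplicons <- function(template, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- Biostrings::DNAString(toupper(as.character(template)))
  fwd_sites <- Biostrings::matchPattern(primers$forward, template)
  rev_sites <- Biostrings::matchPattern(revcomp(primers$reverse), template)
  if (!length(fwd_sites) || !length(rev_sites)) return(integer(0))
  fstart <- Biostrings::start(fwd_sites)
  fend <- Biostrings::end(fwd_sites)
  rstart <- Biostrings::start(rev_sites)
  rend <- Biostrings::end(rev_sites)
  lens <- integer(0)
  for (i in seq_along(fstart)) {
    downstream <- rstart > fstart[i] & rend > fend[i]
    lens <- c(lens, rend[downstream] - fstart[i] + 1L)
  }
  sort(lens)
}

#' Interpret a duplex SRY/GAPDH typing assay
#'
#' The duplex PCR types SRY presence with GAPDH as the internal control:
#' a failed GAPDH band voids the assay regardless of the SRY band.
#'
#' @param bands named logical vector or list with elements `GAPDH` and
#'   `SRY` (band observed or not).
#' @return `"sry_positive"`, `"sry_negative"`, or `"assay_failure"`.
#' @export
sry_status <- function(bands) {
  gapdh <- isTRUE(as.logical(bands[["GAPDH"]]))
  sry <- isTRUE(as.logical(bands[["SRY"]]))
  if (!gapdh) "assay_failure" else if (sry) "sry_positive" else "sry_negative"
}

#' Construct a qPCR expression table
#'
#' Long format, one row per individual and replicate: triplicate Ct values
#' for the target gene and the reference gene (GAPDH in the motivating
#' assay), with a group label. Exactly three replicates per individual is
#' part of the assay contract and is enforced.
#'
#' @param df data.frame with columns `individual_id, group, gene, replicate,
#'   ct_target, ct_reference`.
#' @return A validated data.frame of class `expression_table`.
#' @export
expression_table <- function(df) {
  need <- c("individual_id", "group", "gene", "replicate", "ct_target", "ct_reference")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need, drop = FALSE]
  df$ct_target <- as.numeric(df$ct_target)
  df$ct_reference <- as.numeric(df$ct_reference)
  if (any(!is.finite(df$ct_target)) || any(!is.finite(df$ct_reference)) ||
      any(df$ct_target <= 0) || any(df$ct_reference <= 0)) {
    abort("Ct values must be positive")
  }
  reps <- table(paste(df$individual_id, df$gene))
  if (any(reps != 3L)) {
    abort("every individual needs exactly 3 replicates (got %d for %s)",
          reps[which(reps != 3L)[1]], names(reps)[which(reps != 3L)[1]])
  }
  rownames(df) <- NULL
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Read a qPCR Ct table from TSV
#'
#' @param path TSV with the [expression_table()] columns.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path) {
  expression_table(utils::read.delim(path, check.names = FALSE))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per individual, `dCt = mean(Ct_target) - mean(Ct_reference)` over the
#' triplicates; `ddCt = dCt - mean(dCt over the calibrator group)`;
#' `fold = 2^(-ddCt)`. The calibrator group's mean ddCt is 0 by
#' construction. A two-sided Welch t-test on dCt between each group and the
#' calibrator is reported as an analysis convenience (the choice of test is
#' this package's, not part of the assay).
#'
#' @param records an [expression_table()].
#' @param gene gene to analyse (rows with other genes are ignored).
#' @param calibrator_group group whose mean dCt anchors the comparison
#'   (default `"normal_female"`).
#' @return A list of class `ddct_result`: `per_individual` (data.frame with
#'   `individual_id, group, d_ct, dd_ct, fold`), `per_group` (data.frame
#'   with `group, mean_fold, mean_dd_ct, n, p_welch_vs_calibrator`),
#'   `calibrator_group`.
#' @export
ddct <- function(records, gene, calibrator_group = "normal_female") {
  stopifnot(inherits(records, "expression_table"))
  rec <- records[records$gene == gene, , drop = FALSE]
  if (!nrow(rec)) abort("no records for gene %s", gene)
  ids <- unique(rec$individual_id)
  per <- do.call(rbind, lapply(ids, function(i) {
    r <- rec[rec$individual_id == i, , drop = FALSE]
    data.frame(individual_id = i, group = r$group[1],
               d_ct = mean(r$ct_target) - mean(r$ct_reference),
               stringsAsFactors = FALSE)
  }))
  if (!any(per$group == calibrator_group)) {
    abort("calibrator group %s is empty", calibrator_group)
  }
  cal_mean <- mean(per$d_ct[per$group == calibrator_group])
  per$dd_ct <- per$d_ct - cal_mean
  per$fold <- 2^(-per$dd_ct)
  groups <- unique(per$group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    dct_g <- per$d_ct[per$group == g]
    dct_cal <- per$d_ct[per$group == calibrator_group]
    p <- if (g == calibrator_group || length(dct_g) < 2L || length(dct_cal) < 2L ||
             (stats::sd(dct_g) == 0 && stats::sd(dct_cal) == 0)) {
      NA_real_
    } else {
      stats::t.test(dct_g, dct_cal)$p.value
    }
    data.frame(group = g, mean_fold = mean(per$fold[per$group == g]),
               mean_dd_ct = mean(per$dd_ct[per$group == g]),
               n = length(dct_g), p_welch_vs_calibrator = p,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_individual = per, per_group = per_group,
                 calibrator_group = calibrator_group),
            class = "ddct_result")
}
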