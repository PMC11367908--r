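#' Sample roles for the trio screen
#'
#' The recessive screen runs over one unaffected control female genome and at
#' least two affected genomes (in the motivating study: normal female NF and
#' the two XX DSD animals D1, D2).
#'
#' @param control sample id of the control female (length 1).
#' @param affected character vector of affected sample ids (at least 2).
#' @return A data.frame with columns `sample_id` and `role`
#'   (`"control_female"` or `"affected"`).
#' @examples
#' sample_roles("NF", c("D1", "D2"))
#' @export
sample_roles <- function(control, affected) {
  stopifnot(is.character(control), length(control) == 1L)
  stopifnot(is.character(affected))
  if (length(affected) < 2L) {
    abort("at least two affected samples are required (got %d)", length(affected))
  }
  ids <- c(control, affected)
  if (anyDuplicated(ids)) abort("sample ids must be unique")
  data.frame(
    sample_id = ids,
    role = c("control_female", rep("affected", length(affected))),
    stringsAsFactors = FALSE
  )
}

CORE_SNV_COLS <- c("chrom", "pos", "ref", "alt", "gene", "region", "effect")

#' Construct an annotated SNV table
#'
#' One row per site-allele: chromosome, 1-based position, ref/alt alleles,
#' gene symbol (may be empty), genomic region, predicted coding effect, and
#' one genotype column per sample with codes `absent`, `het`, `hom`,
#' `no_call`. `absent` means no non-reference allele was recorded for that
#' sample at the site; `no_call` means the site could not be evaluated and is
#' distinct from `absent`.
#'
#' @param df data.frame carrying at least the columns
#'   `chrom, pos, ref, alt, gene, region, effect` plus one column per sample.
#' @param samples character vector naming the genotype columns; defaults to
#'   every non-core column of `df`.
#' @return A validated data.frame of class `snv_table` with a `samples`
#'   attribute.
#' @export
snv_table <- function(df, samples = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CORE_SNV_COLS, names(df))
  if (length(missing_cols)) {
    abort("missing SNV columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(samples)) samples <- setdiff(names(df), CORE_SNV_COLS)
  df <- df[, c(CORE_SNV_COLS, samples), drop = FALSE]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$gene <- toupper(as.character(df$gene))
  df$region <- as.character(df$region)
  df$effect <- as.character(df$effect)
  if (nrow(df)) {
    if (any(df$pos < 1L, na.rm = TRUE)) abort("pos must be >= 1")
    if (any(!is_dna(df$ref)) || any(!is_dna(df$alt))) {
      abort("ref/alt must be non-empty strings over {A,C,G,T}")
    }
    if (any(df$ref == df$alt)) abort("ref and alt must differ")
    bad_region <- setdiff(unique(df$region), REGION_LEVELS)
    if (length(bad_region)) abort("unknown region: %s", paste(bad_region, collapse = ", "))
    bad_effect <- setdiff(unique(df$effect), EFFECT_LEVELS)
    if (length(bad_effect)) abort("unknown effect: %s", paste(bad_effect, collapse = ", "))
    for (s in samples) {
      df[[s]] <- as.character(df[[s]])
      bad <- setdiff(unique(df[[s]]), GENOTYPE_LEVELS)
      if (length(bad)) abort("sample %s has invalid genotype codes: %s", s, paste(bad, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  class(df) <- c("snv_table", "data.frame")
  df
}

#' Samples carried by a variant or probe table
#'
#' @param x an `snv_table` or `sv_table`.
#' @return Character vector of sample ids.
#' @export
table_samples <- function(x) attr(x, "samples")

#' Canonical variant identity key
#'
#' Two records with equal keys are the same site-allele regardless of their
#' per-sample genotype content. Alleles are upper-cased before keying.
#'
#' @param chrom chromosome, or an `snv_table` (then remaining args are ignored
#'   and keys are computed row-wise).
#' @param pos 1-based position.
#' @param ref,alt alleles.
#' @return Character vector of keys of the form `"chrom:pos:REF:ALT"`.
#' @examples
#' variant_key("2", 153536, "t", "c")
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(variant_key(df$chrom, df$pos, df$ref, df$alt))
  }
  if (length(chrom) == 0L) return(character(0))
  paste(as.character(chrom), as.integer(pos), toupper(ref), toupper(alt), sep = ":")
}

# --- genotype parsing -------------------------------------------------------

# map a VCF GT string to a genotype code for alt-allele index `alt_idx`
gt_to_code <- function(gt, alt_idx) {
  gt[is.na(gt)] <- "./."   # some VCF readers surface missing genotypes as NA
  vapply(strsplit(sub(":.*", "", gt), "[/|]"), function(al) {
    if (length(al) == 0L || any(is.na(al) | al == "." | al == "")) return("no_call")
    hits <- sum(al == as.character(alt_idx))
    if (hits == 0L) "absent" else if (hits == length(al)) "hom" else "het"
  }, character(1))
}

TSV_GT_CODES <- c("." = "absent", "het" = "het", "hom" = "hom", "nc" = "no_call")
GT_TSV_CODES <- c(absent = ".", het = "het", hom = "hom", no_call = "nc")

# --- SNV table I/O ----------------------------------------------------------

#' Read an annotated multi-sample SNV table
#'
#' Two dialects are supported. `tsv`: a header line with columns
#' `chrom,pos,ref,alt,gene,region,effect` followed by one column per sample
#' holding the codes `.` (absent), `het`, `hom`, `nc` (no call). `vcf`: a
#' VCF v4.x file with per-sample GT fields and the annotation carried in the
#' INFO keys `GENE`, `REGION`, `EFFECT`. Multi-allelic VCF rows are split
#' into one record per alternate allele; each split record inherits the row's
#' annotation. VCF genotype `0/0` maps to `absent`, `./.` to `no_call`, any
#' mix of the alt with another allele to `het`, and all-alt to `hom`.
#'
#' Unknown `EFFECT` strings are downgraded to `"unknown"` with a warning;
#' structurally malformed rows raise an error naming the offending line.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return An [snv_table()].
#' @export
read_snv_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("no such file: %s", path)
  if (dialect == "tsv") read_snv_tsv(path) else read_snv_vcf(path)
}

read_snv_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(CORE_SNV_COLS, names(df))
  if (length(missing_cols)) {
    abort("%s: missing columns: %s", path, paste(missing_cols, collapse = ", "))
  }
  samples <- setdiff(names(df), CORE_SNV_COLS)
  if (!nrow(df)) {
    empty <- df
    empty$pos <- integer(0)
    return(snv_table(empty, samples))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) {
    abort("%s: malformed pos at line %d", path, which(is.na(pos))[1] + 1L)
  }
  df$pos <- pos
  unknown_eff <- !(df$effect %in% EFFECT_LEVELS)
  if (any(unknown_eff)) {
    warning(sprintf("%s: %d unknown effect string(s) set to 'unknown'",
                    path, sum(unknown_eff)), call. = FALSE)
    df$effect[unknown_eff] <- "unknown"
  }
  for (s in samples) {
    code <- TSV_GT_CODES[df[[s]]]
    if (anyNA(code)) {
      abort("%s: invalid genotype code '%s' for sample %s at line %d",
            path, df[[s]][which(is.na(code))[1]], s, which(is.na(code))[1] + 1L)
    }
    df[[s]] <- unname(code)
  }
  snv_table(df, samples)
}

read_snv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1] %||% character(0)
  if (nrow(fix) == 0L) {
    empty <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                        alt = character(0), gene = character(0), region = character(0),
                        effect = character(0), stringsAsFactors = FALSE)
    for (s in samples) empty[[s]] <- character(0)
    return(snv_table(empty, samples))
  }
  info <- vcf@fix[, "INFO"]
  info_get <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info))
    out <- rep("", length(info))
    hit <- nchar(m) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m[hit])
    out
  }
  gene <- info_get("GENE")
  region <- info_get("REGION")
  effect <- info_get("EFFECT")
  gene[gene == "."] <- ""
  region[region == "" | region == "."] <- "other"
  effect[effect == "" | effect == "."] <- "unknown"
  unknown_eff <- !(effect %in% EFFECT_LEVELS)
  if (any(unknown_eff)) {
    warning(sprintf("%s: %d unknown effect string(s) set to 'unknown'",
                    path, sum(unknown_eff)), call. = FALSE)
    effect[unknown_eff] <- "unknown"
  }
  gt <- vcf@gt[, samples, drop = FALSE]
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    do.call(rbind, lapply(seq_along(alts), function(a) {
      rec <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a],
        gene = gene[i], region = region[i], effect = effect[i],
        stringsAsFactors = FALSE
      )
      for (s in samples) rec[[s]] <- gt_to_code(gt[i, s], a)
      rec
    }))
  })
  snv_table(do.call(rbind, rows), samples)
}

#' Write an annotated SNV table
#'
#' Inverse of [read_snv_table()]: `read_snv_table(write_snv_table(x))`
#' reproduces `x` field-by-field in either dialect. The VCF writer emits one
#' plain-text VCF 4.2 row per record (records are already one alt per row)
#' with annotation in the `GENE`/`REGION`/`EFFECT` INFO keys and genotypes
#' `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param x an [snv_table()].
#' @param path output file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_snv_table <- function(x, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "snv_table"))
  samples <- table_samples(x)
  if (dialect == "tsv") {
    out <- as.data.frame(x)
    for (s in samples) out[[s]] <- unname(GT_TSV_CODES[out[[s]]])
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Genomic region\">",
      "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t")
    )
    gt_vcf <- c(absent = "0/0", het = "0/1", hom = "1/1", no_call = "./.")
    body <- vapply(seq_len(nrow(x)), function(i) {
      info <- sprintf("GENE=%s;REGION=%s;EFFECT=%s",
                      ifelse(nzchar(x$gene[i]), x$gene[i], "."),
                      x$region[i], x$effect[i])
      gts <- vapply(samples, function(s) gt_vcf[[x[[s]][i]]], character(1))
      paste(c(x$chrom[i], x$pos[i], ".", x$ref[i], x$alt[i], ".", "PASS",
              info, "GT", gts), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

# --- SV table I/O -----------------------------------------------------------

CORE_SV_COLS <- c("sv_id", "sv_type", "chrom", "start", "end", "size", "genes")

#' Construct a structural-variant table
#'
#' One row per SV: identifier, type (`deletion`, `duplication`, `inversion`),
#' chromosome, 1-based inclusive start/end, size in bp (`end - start + 1`),
#' semicolon-separated gene symbols (possibly empty for intergenic events),
#' and one logical presence column per sample.
#'
#' @param df data.frame with columns `sv_id, sv_type, chrom, start, end`
#'   and `genes`, plus per-sample presence columns (logical or 0/1); `size`
#'   is recomputed.
#' @param samples character vector naming the presence columns; defaults to
#'   all non-core columns.
#' @return A validated data.frame of class `sv_table`.
#' @export
sv_table <- function(df, samples = NULL) {
  stopifnot(is.data.frame(df))
  need <- setdiff(CORE_SV_COLS, c(names(df), "size"))
  if (length(need)) abort("missing SV columns: %s", paste(need, collapse = ", "))
  if (is.null(samples)) samples <- setdiff(names(df), CORE_SV_COLS)
  df$sv_id <- as.character(df$sv_id)
  df$sv_type <- as.character(df$sv_type)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$genes <- toupper(as.character(df$genes))
  if (nrow(df)) {
    bad_type <- setdiff(unique(df$sv_type), SV_TYPES)
    if (length(bad_type)) abort("unknown SV type: %s", paste(bad_type, collapse = ", "))
    if (any(df$end < df$start)) {
      abort("end < start for SV %s", df$sv_id[which(df$end < df$start)[1]])
    }
    if (anyDuplicated(df$sv_id)) abort("sv_id must be unique")
  }
  df$size <- df$end - df$start + 1L
  for (s in samples) {
    v <- df[[s]]
    df[[s]] <- if (is.character(v)) v %in% c("1", "TRUE", "true") else as.logical(v)
  }
  df <- df[, c(CORE_SV_COLS, samples), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  class(df) <- c("sv_table", "data.frame")
  df
}

# split a semicolon-joined gene field into a (possibly empty) symbol vector
sv_genes <- function(genes) {
  g <- strsplit(genes, ";", fixed = TRUE)
  lapply(g, function(x) x[nzchar(x)])
}

#' Read a structural-variant table
#'
#' `tsv`: header columns `sv_id, type, chrom, start, end, genes` (1-based
#' inclusive coordinates, genes semicolon-separated) plus one 0/1 presence
#' column per sample. `bedpe`: the two breakpoints as 0-based half-open
#' intervals (`chrom1 start1 end1 chrom2 start2 end2 name score strand1
#' strand2`) followed by `type, genes` and the presence columns; the record
#' interval is reconstructed as `[end1, end2]` 1-based inclusive.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"bedpe"`.
#' @return An [sv_table()]; `size` is recomputed as `end - start + 1`.
#' @export
read_sv_table <- function(path, dialect = c("tsv", "bedpe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("no such file: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (dialect == "tsv") {
    need <- c("sv_id", "type", "chrom", "start", "end", "genes")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      abort("%s: missing columns: %s", path, paste(missing_cols, collapse = ", "))
    }
    samples <- setdiff(names(df), need)
    out <- data.frame(
      sv_id = df$sv_id, sv_type = df$type, chrom = df$chrom,
      start = suppressWarnings(as.integer(df$start)),
      end = suppressWarnings(as.integer(df$end)),
      genes = df$genes, stringsAsFactors = FALSE
    )
  } else {
    need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
              "name", "score", "strand1", "strand2", "type", "genes")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      abort("%s: missing columns: %s", path, paste(missing_cols, collapse = ", "))
    }
    samples <- setdiff(names(df), need)
    out <- data.frame(
      sv_id = df$name, sv_type = df$type, chrom = df$chrom1,
      start = suppressWarnings(as.integer(df$end1)),
      end = suppressWarnings(as.integer(df$end2)),
      genes = df$genes, stringsAsFactors = FALSE
    )
  }
  if (nrow(out) && (anyNA(out$start) || anyNA(out$end))) {
    abort("%s: malformed coordinates at line %d", path,
          which(is.na(out$start) | is.na(out$end))[1] + 1L)
  }
  for (s in samples) out[[s]] <- df[[s]] %in% c("1", "TRUE", "true")
  sv_table(out, samples)
}

#' Write a structural-variant table
#'
#' Inverse of [read_sv_table()] for both dialects (BEDPE coordinates are
#' converted back to 0-based half-open breakpoints on write).
#'
#' @param x an [sv_table()].
#' @param path output file.
#' @param dialect `"tsv"` or `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(x, path, dialect = c("tsv", "bedpe")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "sv_table"))
  samples <- table_samples(x)
  pres <- as.data.frame(lapply(x[samples], as.integer))
  names(pres) <- samples
  if (dialect == "tsv") {
    out <- data.frame(sv_id = x$sv_id, type = x$sv_type, chrom = x$chrom,
                      start = x$start, end = x$end, genes = x$genes,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    out <- data.frame(
      chrom1 = x$chrom, start1 = x$start - 1L, end1 = x$start,
      chrom2 = x$chrom, start2 = x$end - 1L, end2 = x$end,
      name = x$sv_id, score = ".", strand1 = ".", strand2 = ".",
      type = x$sv_type, genes = x$genes,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  out <- cbind(out, pres)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- gene panels ------------------------------------------------------------

#' Construct a candidate-gene panel
#'
#' Panels hold the literature/database-curated genes used to prioritise
#' screened variants. Symbols are upper-cased and must be unique.
#'
#' @param genes character vector of gene symbols.
#' @param notes optional character vector of free-text annotations.
#' @return A data.frame of class `gene_panel` with columns `gene`, `note`.
#' @export
gene_panel <- function(genes, notes = NULL) {
  genes <- toupper(as.character(genes))
  if (anyDuplicated(genes)) abort("panel gene symbols must be unique")
  out <- data.frame(gene = genes,
                    note = if (is.null(notes)) rep("", length(genes)) else as.character(notes),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_panel", "data.frame")
  out
}

#' Read a candidate-gene panel from TSV
#'
#' @param path TSV with columns `gene` and optionally `note`.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!"gene" %in% names(df)) abort("%s: missing column 'gene'", path)
  gene_panel(df$gene, df$note %||% NULL)
}

# --- assembly statistics ----------------------------------------------------

#' N50 of a set of contig or scaffold lengths
#'
#' The largest length L such that pieces of length >= L together cover at
#' least half of the total assembly span; computed by sorting descending and
#' accumulating.
#'
#' @param lengths non-empty vector of positive integer lengths (bp).
#' @return The N50 length in bp (integer-valued numeric).
#' @examples
#' assembly_n50(c(80, 70, 50, 40, 30, 20)) # 70
#' @export
assembly_n50 <- function(lengths) {
  if (length(lengths) == 0L) abort("assembly_n50: empty length list")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("assembly_n50: lengths must be positive")
  }
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  srt[which(cumsum(srt) >= sum(srt) / 2)[1]]
}
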