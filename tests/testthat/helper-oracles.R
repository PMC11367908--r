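# Independent brute-force oracles, coded directly from the definitions and
# kept separate from the implementation paths they check.

# per-variant boolean evaluation of the four screen criteria (trio case)
oracle_screen <- function(variants, control, affected) {
  stopifnot(length(affected) == 2L)
  carries <- function(g) g %in% c("het", "hom")
  keys <- variant_key(variants)
  out <- list(A = character(0), B = character(0), C = character(0), D = character(0))
  for (i in seq_len(nrow(variants))) {
    if (variants$effect[i] != "nonsynonymous") next
    gNF <- variants[[control]][i]
    g1 <- variants[[affected[1]]][i]
    g2 <- variants[[affected[2]]][i]
    if (g1 == "hom" && g2 == "hom" && !carries(gNF)) out$A <- c(out$A, keys[i])
    if (gNF == "hom" && !carries(g1) && !carries(g2)) out$B <- c(out$B, keys[i])
    if (g1 == "hom" && g2 == "hom" && gNF == "het") out$C <- c(out$C, keys[i])
    if (gNF == "het" && !carries(g1) && !carries(g2)) out$D <- c(out$D, keys[i])
  }
  out
}

# a random trio SNV table with unique keys and arbitrary genotypes
random_trio_table <- function(n, samples = c("NF", "D1", "D2")) {
  pos <- sample.int(10 * n + 10, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  df <- data.frame(
    chrom = sample(as.character(1:5), n, replace = TRUE),
    pos = pos, ref = ref, alt = unname(alt),
    gene = sample(sprintf("G%03d", 1:50), n, replace = TRUE),
    region = sample(c("exonic", "intronic", "utr"), n, replace = TRUE),
    effect = sample(c("nonsynonymous", "synonymous", "stopgain", "unknown"),
                    n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (s in samples) {
    df[[s]] <- sample(c("absent", "het", "hom", "no_call"), n, replace = TRUE)
  }
  snv_table(df, samples)
}

# direct evaluation of the SV match predicate, re-derived from its definition
oracle_sv_match <- function(a, b, mode = "gene_and_type", frac = 0.5, tol = 1000) {
  ga <- setdiff(strsplit(a$genes, ";")[[1]], "")
  gb <- setdiff(strsplit(b$genes, ";")[[1]], "")
  same_chrom <- a$chrom == b$chrom
  ov <- if (same_chrom) max(0, min(a$end, b$end) - max(a$start, b$start) + 1) else 0
  bp <- if (same_chrom) {
    min(abs(c(a$start - b$start, a$start - b$end, a$end - b$start, a$end - b$end)))
  } else Inf
  if (a$sv_type != b$sv_type) return(FALSE)
  if (mode == "gene_and_type") {
    near <- ov >= 1 || bp <= tol
    if (length(ga) == 0 && length(gb) == 0) return(near)
    return(length(intersect(ga, gb)) > 0 && near)
  }
  if (!same_chrom) return(FALSE)
  if (a$sv_type == "inversion") {
    return(abs(a$start - b$start) <= tol && abs(a$end - b$end) <= tol)
  }
  ov / (a$end - a$start + 1) >= frac && ov / (b$end - b$start + 1) >= frac
}

random_sv_record <- function() {
  start <- sample.int(10000, 1)
  list(sv_type = sample(c("deletion", "duplication", "inversion"), 1),
       chrom = sample(as.character(1:3), 1),
       start = start, end = start + sample.int(3000, 1) - 1L,
       genes = sample(c("", "GA", "GB", "GA;GB"), 1))
}

# per-individual counting of candidate-SV burden
oracle_burden <- function(carriers, cohort_size) {
  n <- vapply(carriers, function(x) length(unique(x)), integer(1))
  n <- n[n > 0]
  list(exactly_one = sum(n == 1), two_or_more = sum(n >= 2),
       zero = cohort_size - length(n))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# quadratic brute-force amplicon scan over all substring positions
oracle_amplicons <- function(template, fwd, rev) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(rev, "")[[1]]), collapse = ""))
  find_all <- function(pat) {
    hits <- integer(0)
    for (i in seq_len(nchar(template) - nchar(pat) + 1)) {
      if (substr(template, i, i + nchar(pat) - 1) == pat) hits <- c(hits, i)
    }
    hits
  }
  fs <- find_all(fwd)
  rs <- find_all(rc)
  lens <- integer(0)
  for (f in fs) {
    for (r in rs) {
      if (r > f && (r + nchar(rc) - 1) > (f + nchar(fwd) - 1)) {
        lens <- c(lens, as.integer((r + nchar(rc) - 1) - f + 1))
      }
    }
  }
  sort(lens)
}
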