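# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state, so generators are pure functions of
#' their configuration and callers' random streams are undisturbed.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with sprintf formatting; call. = FALSE everywhere for clean messages
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# valid genotype codes used throughout
GENOTYPE_LEVELS <- c("absent", "het", "hom", "no_call")

REGION_LEVELS <- c("exonic", "intronic", "intergenic", "utr", "splicing", "other")
EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stopgain", "stoploss", "unknown")
SV_TYPES      <- c("deletion", "duplication", "inversion")

is_dna <- function(x) {
  is.character(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

# random DNA of length n from the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
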