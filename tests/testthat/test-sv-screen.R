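wwox_rec <- function(start = 9669113L, end = 9669182L, type = "deletion",
                     genes = "WWOX", chrom = "6") {
  list(sv_id = "x", sv_type = type, chrom = chrom,
       start = start, end = end, genes = genes)
}

test_that("sv_match follows the gene-and-type criterion", {
  pol <- sv_match_policy("gene_and_type")
  a <- wwox_rec()
  expect_true(sv_match(a, a, pol))                       # reflexive
  expect_false(sv_match(a, wwox_rec(type = "duplication"), pol))
  expect_true(sv_match(a, wwox_rec(9669100L, 9669190L), pol))
  # same gene but far beyond the breakpoint tolerance
  expect_false(sv_match(a, wwox_rec(9769113L, 9769182L), pol))
  # nearby but disjoint: within default 1 kb tolerance
  expect_true(sv_match(a, wwox_rec(9669500L, 9669600L), pol))
  # intergenic records are matched on breakpoints alone
  expect_true(sv_match(wwox_rec(genes = ""), wwox_rec(9669200L, 9669300L, genes = ""), pol))
  expect_false(sv_match(wwox_rec(genes = ""), wwox_rec(genes = "", chrom = "7"), pol))
})

test_that("reciprocal-overlap mode requires mutual coverage; inversions use breakpoints", {
  pol <- sv_match_policy("reciprocal_overlap", min_reciprocal_overlap = 0.5)
  a <- wwox_rec(1000L, 1999L)
  expect_true(sv_match(a, wwox_rec(1500L, 2499L), pol))   # 50% both ways
  expect_false(sv_match(a, wwox_rec(1900L, 2899L), pol))  # 10% overlap
  # a short deletion nested in a long one fails the long record's fraction
  expect_false(sv_match(a, wwox_rec(1000L, 9999L), pol))
  inv_a <- wwox_rec(1000L, 5000L, type = "inversion")
  inv_b <- wwox_rec(1400L, 5400L, type = "inversion")
  expect_true(sv_match(inv_a, inv_b, pol))
  expect_false(sv_match(inv_a, wwox_rec(3000L, 9000L, type = "inversion"), pol))
})

test_that("sv_match is symmetric and agrees with a direct predicate evaluation", {
  set.seed(91)
  pols <- list(sv_match_policy("gene_and_type"),
               sv_match_policy("reciprocal_overlap"))
  for (i in 1:200) {
    a <- random_sv_record(); b <- random_sv_record()
    for (pol in pols) {
      m_ab <- sv_match(a, b, pol)
      expect_identical(m_ab, sv_match(b, a, pol))
      expect_identical(m_ab, oracle_sv_match(a, b, mode = pol$mode))
    }
  }
})

test_that("step A keeps affected-specific SVs, step B keeps concordant ones", {
  svs <- sv_table(data.frame(
    sv_id = sprintf("s%d", 1:6),
    sv_type = c("deletion", "deletion", "duplication", "deletion", "inversion", "deletion"),
    chrom = c("1", "1", "2", "3", "4", "5"),
    start = c(100L, 450L, 5000L, 100L, 200L, 300L),
    end = c(400L, 800L, 9000L, 900L, 900L, 900L),
    genes = c("GA", "GA", "GB", "GC", "GD", "GE"),
    NF = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    D1 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    D2 = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ), c("NF", "D1", "D2"))
  # s1 is shifted < tolerance from NF-carried s2 (shared); s3 carried by NF too
  a <- screen_step_a(svs, "NF", "D2")
  expect_setequal(a$sv_id, c("s4", "s5", "s6"))
  b <- screen_step_b(a, svs, other_sample = "D1")
  expect_setequal(b$sv_id, "s4")
  # identical control/affected lists -> nothing survives step A
  same <- svs; same$NF <- same$D2
  expect_identical(nrow(screen_step_a(sv_table(as.data.frame(same), c("NF", "D1", "D2")),
                                      "NF", "D2")), 0L)
  # empty other-affected set -> step B empty
  expect_identical(nrow(screen_step_b(a, a[0, , drop = FALSE])), 0L)
  expect_error(screen_step_a(svs, "NF", "D9"), "unknown sample")
})

test_that("screening is monotone: step B within step A within the affected set", {
  sg <- generate_sv_sets(sv_sim_config(12, 9, 6, seed = 5))
  aff <- sg$svs$sv_id[sg$svs$D2]
  a <- screen_step_a(sg$svs, "NF", "D2")
  b <- screen_step_b(a, sg$svs, other_sample = "D1")
  expect_true(all(a$sv_id %in% aff))
  expect_true(all(b$sv_id %in% a$sv_id))
})

test_that("planted SV classes are recovered exactly", {
  sg <- generate_sv_sets(sv_sim_config(20, 15, 10, seed = 3))
  a <- screen_step_a(sg$svs, "NF", "D2")
  expect_identical(nrow(a), 35L)
  b <- screen_step_b(a, sg$svs, other_sample = "D1")
  expect_identical(nrow(b), 20L)
  lab <- sg$truth$label[match(b$sv_id, sg$truth$sv_id)]
  expect_true(all(lab == "concordant"))
  # zero concordant -> step B empty
  sg0 <- generate_sv_sets(sv_sim_config(0, 8, 4, seed = 3))
  a0 <- screen_step_a(sg0$svs, "NF", "D2")
  expect_identical(nrow(screen_step_b(a0, sg0$svs, other_sample = "D1")), 0L)
})

test_that("burden summaries match brute-force per-individual counting", {
  expect_identical(sv_burden(list(), 32)$summary,
                   list(exactly_one = 0L, two_or_more = 0L, zero = 32))
  set.seed(17)
  for (rep in 1:20) {
    n_ind <- sample(5:30, 1)
    carriers <- stats::setNames(
      lapply(seq_len(n_ind), function(i) {
        sample(sprintf("sv%d", 1:6), sample(0:3, 1))
      }),
      sprintf("ind%02d", seq_len(n_ind))
    )
    got <- sv_burden(carriers, 32)$summary
    want <- oracle_burden(carriers, 32)
    expect_identical(got$exactly_one, want$exactly_one)
    expect_identical(got$two_or_more, want$two_or_more)
    expect_identical(as.integer(got$zero), as.integer(want$zero))
  }
  expect_error(sv_burden(list(a = "sv1", b = "sv2"), 1), "cohort_size")
})

test_that("the synthetic cohort carrier table reproduces the reported marginals", {
  carr <- read_sv_carriers()
  bu <- sv_burden(carr$carriers, 32)
  expect_identical(bu$summary$exactly_one, 22L)
  expect_identical(bu$summary$two_or_more, 10L)
  expect_identical(as.integer(bu$summary$zero), 0L)
  expect_identical(unname(bu$exclusive_carriers["wwox_del"]), 14L)
  expect_identical(unname(bu$exclusive_carriers["pitx1_del"]), 4L)
  expect_identical(unname(bu$exclusive_carriers["shc1_dup"]), 2L)
  expect_identical(unname(bu$exclusive_carriers["chr3_del"]), 2L)
})

test_that("the shipped candidate SV list parses completely", {
  svs <- candidate_sv_table()
  expect_identical(nrow(svs), 14L)
  expect_identical(svs$size[svs$sv_id == "wwox_del"], 70L)
  expect_setequal(unique(svs$sv_type), c("deletion", "duplication", "inversion"))
  expect_true(all(svs$D1 & svs$D2) && !any(svs$NF))
})
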