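toy_signals <- function(target = 500, refs = c(1000, 1000, 1000),
                        sample = "s1", group = "affected", probe = "wwox_del") {
  probe_signals(data.frame(
    sample_id = sample, group = group,
    probe_id = c(probe, "ACTB", "COL10A1", "GCG"),
    peak_signal = c(target, refs), stringsAsFactors = FALSE
  ))
}

test_that("signal normalisation is the target over the reference mean", {
  expect_equal(normalize_signal(toy_signals(1000), "s1", "wwox_del"), 1)
  expect_equal(normalize_signal(toy_signals(500), "s1", "wwox_del"), 0.5)
  set.seed(3)
  for (rep in 1:20) {
    t <- stats::runif(1, 10, 5000); r <- stats::runif(3, 10, 5000)
    expect_equal(normalize_signal(toy_signals(t, r), "s1", "wwox_del"),
                 t / mean(r))   # one-line oracle
    # scale invariance: multiplying all of the sample's peaks by k
    k <- stats::runif(1, 0.1, 10)
    expect_equal(normalize_signal(toy_signals(k * t, k * r), "s1", "wwox_del"),
                 normalize_signal(toy_signals(t, r), "s1", "wwox_del"))
  }
  missing_ref <- data.frame(
    sample_id = "s1", group = "g", probe_id = c("wwox_del", "ACTB", "COL10A1", "GCG"),
    peak_signal = c(1, 1, 1, 1), stringsAsFactors = FALSE
  )[1:3, ]
  expect_error(probe_signals(missing_ref), "GCG")
})

test_that("relative copy number centres controls at two copies", {
  cp <- data.frame(sample_id = sprintf("s%02d", 1:8),
                   group = c(rep("control", 4), rep("affected", 4)),
                   copies = c(2, 2, 2, 2, 2, 1, 1, 0))
  sim <- generate_cnvplex(signal_sim_config(cp, cv = 0, seed = 1))
  calls <- relative_copy_number(sim$signals, "wwox_del",
                                controls = cp$sample_id[cp$group == "control"])
  expect_equal(calls$relative_cn[calls$sample_id == "s01"], 2)
  expect_equal(calls$relative_cn[calls$sample_id == "s06"], 1)
  expect_equal(stats::median(calls$relative_cn[1:4]), 2)
  expect_error(relative_copy_number(sim$signals, "wwox_del", character(0)),
               "empty control")
})

test_that("copy classes follow the 0.5/1.5/2.5 thresholds", {
  expect_identical(classify_copy_class(2.0), "2")
  expect_identical(classify_copy_class(0.97), "1")
  expect_identical(classify_copy_class(0.49), "0")
  expect_identical(classify_copy_class(0.5), "1")
  expect_identical(classify_copy_class(1.5), "2")
  expect_identical(classify_copy_class(2.5), "gain")
  expect_error(classify_copy_class(-0.1), "non-negative")
})

test_that("planted copy classes are recovered from noisy signals", {
  cp <- data.frame(
    sample_id = sprintf("s%02d", 1:64),
    group = rep(c("control", "affected"), each = 32),
    copies = c(rep(2, 32), rep(c(0, 1, 2, 3), 8))
  )
  sim <- generate_cnvplex(signal_sim_config(cp, cv = 0.1, seed = 11))
  calls <- relative_copy_number(sim$signals, "wwox_del",
                                controls = cp$sample_id[cp$group == "control"])
  planted <- ifelse(cp$copies >= 3, "gain", as.character(cp$copies))
  expect_gte(mean(calls$copy_class == planted), 0.99)
  ctrl_cn <- calls$relative_cn[match(cp$sample_id[cp$group == "control"],
                                     calls$sample_id)]
  expect_identical(stats::median(ctrl_cn), 2)
})

test_that("amplicon prediction finds exact primer placements", {
  pr <- primer_pair(paste(rep("A", 20), collapse = ""),
                    paste(rep("T", 20), collapse = ""))
  expect_identical(predict_amplicons("GGGG", pr), integer(0))
  # forward + 10 spacer + revcomp(reverse): 20 + 10 + 20 = 50
  pr2 <- primer_pair("ACGTACGTACGTACGTACGT", "TTGGCCAATTGGCCAATTGG")
  tmpl2 <- paste0("GGC", pr2$forward, "CATCATCATG", revcomp(pr2$reverse), "TTC")
  expect_identical(predict_amplicons(tmpl2, pr2), 50L)
  expect_error(primer_pair("ACGTN", "ACGT"), "A,C,G,T")
})

test_that("the generated assay fixture yields the wild-type and deletion bands", {
  fx <- generate_amplicon_fixture(seed = 1)
  expect_identical(predict_amplicons(fx$wildtype, fx$primers), 298L)
  expect_identical(predict_amplicons(fx$deletion, fx$primers), 228L)
  expect_identical(diff(fx$deletion_interval)[[1]] + 1L, 70L)
})

test_that("multiple forward sites give one product each, as in a brute scan", {
  set.seed(21)
  pr <- primer_pair("ACGGTCAGTC", "TGACCTGGAT")
  rc <- revcomp(pr$reverse)
  tmpl <- paste0(random_dna(15), pr$forward, random_dna(8), pr$forward,
                 random_dna(12), rc, random_dna(15))
  got <- predict_amplicons(tmpl, pr)
  expect_length(got, 2L)
  expect_identical(got, oracle_amplicons(tmpl, pr$forward, pr$reverse))
  for (rep in 1:10) {
    t_r <- paste0(random_dna(10), pr$forward, random_dna(sample(5:40, 1)),
                  rc, random_dna(10))
    expect_identical(predict_amplicons(t_r, pr),
                     oracle_amplicons(t_r, pr$forward, pr$reverse))
  }
})

test_that("excising an internal interval shortens spanning products by its length", {
  set.seed(9)
  fx <- generate_amplicon_fixture(seed = 4)
  before <- predict_amplicons(fx$wildtype, fx$primers)
  for (d in c(1L, 7L, 33L, 70L, 150L)) {
    start <- fx$deletion_interval[["start"]]
    cut <- excise_interval(fx$wildtype, start, start + d - 1L)
    expect_identical(predict_amplicons(cut, fx$primers), before - d)
  }
})

test_that("duplex SRY typing honours the internal control", {
  expect_identical(sry_status(list(GAPDH = TRUE, SRY = FALSE)), "sry_negative")
  expect_identical(sry_status(list(GAPDH = TRUE, SRY = TRUE)), "sry_positive")
  expect_identical(sry_status(list(GAPDH = FALSE, SRY = TRUE)), "assay_failure")
  expect_identical(sry_status(list(GAPDH = FALSE, SRY = FALSE)), "assay_failure")
})

test_that("delta-delta-Ct folds follow their closed form", {
  q <- generate_qpcr(qpcr_sim_config(
    offsets = c(normal_female = 0, xx_dsd = -3), replicate_sd = 0, seed = 2))
  d <- ddct(q$records, "IFITM1", calibrator_group = "normal_female")
  pg <- d$per_group
  expect_equal(pg$mean_fold[pg$group == "normal_female"], 1)   # fold 1 at sd 0
  expect_equal(pg$mean_fold[pg$group == "xx_dsd"], 8)          # ddCt -3 -> 2^3
  expect_equal(mean(d$per_individual$dd_ct[
    d$per_individual$group == "normal_female"]), 0)
  expect_true(all(d$per_individual$fold > 0))
})

test_that("estimated fold change stays in the noise-model interval at sd 0.1", {
  q <- generate_qpcr(qpcr_sim_config(
    offsets = c(normal_female = 0, xx_dsd = -2, normal_male = 0),
    replicate_sd = 0.1, n_per_group = 3, seed = 5))
  d <- ddct(q$records, "IFITM1")
  mf <- d$per_group$mean_fold[d$per_group$group == "xx_dsd"]
  expect_gte(mf, 3.2)
  expect_lte(mf, 5.0)
})

test_that("the triplicate contract is enforced", {
  df <- data.frame(individual_id = "i1", group = "g", gene = "X",
                   replicate = 1:2, ct_target = c(20, 20),
                   ct_reference = c(18, 18), stringsAsFactors = FALSE)
  expect_error(expression_table(df), "exactly 3 replicates")
  bad <- data.frame(individual_id = "i1", group = "g", gene = "X",
                    replicate = 1:3, ct_target = c(20, 20, -1),
                    ct_reference = 18, stringsAsFactors = FALSE)
  expect_error(expression_table(bad), "positive")
})
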