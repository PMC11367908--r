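# Seeded generators with planted ground truth for every pipeline input.
# Each generator is a pure function of its config (including the seed):
# rerunning with the same config reproduces the output exactly.

#' Configuration for the synthetic trio SNV generator
#'
#' Counts of variants planted into the four screen-criterion zygosity
#' classes plus four background classes that no criterion may select:
#' `shared_hom` (homozygous in all three genomes), `single_affected`
#' (homozygous in exactly one affected genome, absent from the control),
#' `synonymous` (criterion-A zygosity pattern but a synonymous effect) and
#' `intronic` (criterion-A pattern, intronic region, no coding effect).
#'
#' @param kA,kB,kC,kD planted counts per screen criterion.
#' @param k_shared_hom,k_single_affected,k_synonymous,k_intronic background
#'   counts.
#' @param chroms chromosome name pool.
#' @param control,affected sample ids (one control, >= 2 affected).
#' @param pos_pool_size positions are drawn without replacement from
#'   `1..pos_pool_size`; exhaustion is an error.
#' @param seed integer seed.
#' @return A list of class `trio_sim_config`.
#' @export
trio_sim_config <- function(kA = 50, kB = 30, kC = 20, kD = 10,
                            k_shared_hom = 100, k_single_affected = 50,
                            k_synonymous = 40, k_intronic = 200,
                            chroms = as.character(1:18),
                            control = "NF", affected = c("D1", "D2"),
                            pos_pool_size = 1e6, seed = 1L) {
  counts <- c(kA = kA, kB = kB, kC = kC, kD = kD,
              k_shared_hom = k_shared_hom, k_single_affected = k_single_affected,
              k_synonymous = k_synonymous, k_intronic = k_intronic)
  if (any(counts < 0)) abort("planted counts must be >= 0")
  structure(c(as.list(counts),
              list(chroms = chroms, control = control, affected = affected,
                   pos_pool_size = pos_pool_size, seed = seed)),
            class = "trio_sim_config")
}

rand_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = unname(ref), alt = unname(alt))
}

#' Generate a trio SNV table with planted screen classes
#'
#' Every emitted variant carries exactly one truth label; variants planted
#' for a criterion satisfy exactly that criterion's zygosity pattern and the
#' background classes satisfy none, so [screen_all()] must recover the
#' planted per-criterion counts exactly.
#'
#' @param config a [trio_sim_config()].
#' @return List: `variants` (an [snv_table()]), `truth` (data.frame
#'   `key, class`), `roles` (a [sample_roles()] data.frame).
#' @export
generate_trio_snvs <- function(config) {
  stopifnot(inherits(config, "trio_sim_config"))
  classes0 <- c(rep("A", config$kA), rep("B", config$kB),
                rep("C", config$kC), rep("D", config$kD),
                rep("shared_hom", config$k_shared_hom),
                rep("single_affected", config$k_single_affected),
                rep("synonymous", config$k_synonymous),
                rep("intronic", config$k_intronic))
  aff <- config$affected
  samples <- c(config$control, aff)
  if (length(classes0) == 0L) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        gene = character(0), region = character(0),
                        effect = character(0), stringsAsFactors = FALSE)
    for (s in samples) empty[[s]] <- character(0)
    return(list(variants = snv_table(empty, samples),
                truth = data.frame(key = character(0), class = character(0),
                                   stringsAsFactors = FALSE),
                roles = sample_roles(config$control, aff)))
  }
  if (length(classes0) > config$pos_pool_size) {
    abort("position pool exhausted (%d > %g)", length(classes0), config$pos_pool_size)
  }
  with_seed(config$seed, {
    n <- length(classes0)
    classes <- classes0
    pos <- sample.int(config$pos_pool_size, n)   # unique positions
    chrom <- sample(config$chroms, n, replace = TRUE)
    alleles <- rand_ref_alt(n)
    classes <- sample(classes)                   # shuffle row order
    gt <- matrix("absent", nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
    region <- rep("exonic", n)
    effect <- rep("nonsynonymous", n)
    for (i in seq_len(n)) {
      gt[i, ] <- switch(classes[i],
        A = c("absent", rep("hom", length(aff))),
        B = c("hom", rep("absent", length(aff))),
        C = c("het", rep("hom", length(aff))),
        D = c("het", rep("absent", length(aff))),
        shared_hom = rep("hom", length(samples)),
        single_affected = {
          g <- c("absent", sample(c("absent", "het"), length(aff), replace = TRUE))
          g[1L + sample.int(length(aff), 1L)] <- "hom"
          g
        },
        synonymous = c("absent", rep("hom", length(aff))),
        intronic = c("absent", rep("hom", length(aff)))
      )
      if (classes[i] == "synonymous") effect[i] <- "synonymous"
      if (classes[i] == "intronic") { region[i] <- "intronic"; effect[i] <- "unknown" }
    }
    df <- data.frame(chrom = chrom, pos = pos, ref = alleles$ref,
                     alt = alleles$alt,
                     gene = sprintf("GENE%05d", seq_len(n)),
                     region = region, effect = effect,
                     stringsAsFactors = FALSE)
    for (j in seq_along(samples)) df[[samples[j]]] <- gt[, j]
    variants <- snv_table(df, samples)
    list(variants = variants,
         truth = data.frame(key = variant_key(variants), class = classes,
                            stringsAsFactors = FALSE),
         roles = sample_roles(config$control, aff))
  })
}

#' Configuration for the synthetic SV generator
#'
#' @param n_concordant SVs carried by both affected genomes (planted as two
#'   records with breakpoints jittered within `jitter` bp of each other, so
#'   the concordance step exercises real matching) and absent from the
#'   control.
#' @param n_primary_only SVs carried by the primary affected genome alone.
#' @param n_control_shared SVs carried by both the primary affected genome
#'   and the control.
#' @param chroms chromosome name pool.
#' @param control,affected_primary,affected_secondary sample ids.
#' @param jitter maximum breakpoint displacement between the two records of
#'   a concordant pair (must stay within the match policy's tolerance).
#' @param seed integer seed.
#' @return A list of class `sv_sim_config`.
#' @export
sv_sim_config <- function(n_concordant = 20, n_primary_only = 15,
                          n_control_shared = 10,
                          chroms = as.character(1:18),
                          control = "NF", affected_primary = "D2",
                          affected_secondary = "D1",
                          jitter = 200L, seed = 1L) {
  if (any(c(n_concordant, n_primary_only, n_control_shared) < 0)) {
    abort("planted counts must be >= 0")
  }
  structure(list(n_concordant = n_concordant, n_primary_only = n_primary_only,
                 n_control_shared = n_control_shared, chroms = chroms,
                 control = control, affected_primary = affected_primary,
                 affected_secondary = affected_secondary,
                 jitter = as.integer(jitter), seed = seed),
            class = "sv_sim_config")
}

#' Generate an SV table with planted concordance classes
#'
#' Each planted event gets a unique gene symbol so distinct events never
#' match under the gene-based policy. Concordant events appear as a
#' primary-genome record plus a secondary-genome partner with jittered
#' breakpoints; control-shared events are present in both the control and
#' the primary affected genome.
#'
#' @param config an [sv_sim_config()].
#' @return List: `svs` (an [sv_table()] with presence columns for the three
#'   genomes) and `truth` (data.frame `sv_id, label` with labels
#'   `concordant`, `affected_primary_only`, `control_shared`; the secondary
#'   partner of a concordant pair is labelled `concordant` too).
#' @export
generate_sv_sets <- function(config) {
  stopifnot(inherits(config, "sv_sim_config"))
  n_events <- config$n_concordant + config$n_primary_only + config$n_control_shared
  samples <- c(config$control, config$affected_secondary, config$affected_primary)
  if (n_events == 0L) {
    empty <- data.frame(sv_id = character(0), sv_type = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), genes = character(0),
                        stringsAsFactors = FALSE)
    for (s in samples) empty[[s]] <- logical(0)
    return(list(svs = sv_table(empty, samples),
                truth = data.frame(sv_id = character(0), label = character(0),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(config$seed, {
    labels <- c(rep("concordant", config$n_concordant),
                rep("affected_primary_only", config$n_primary_only),
                rep("control_shared", config$n_control_shared))
    rows <- list(); truth <- list(); k <- 0L
    for (i in seq_len(n_events)) {
      chrom <- sample(config$chroms, 1L)
      start <- sample.int(1e8, 1L)
      size <- sample(100:50000, 1L)
      type <- sample(SV_TYPES, 1L)
      gene <- sprintf("SVGENE%04d", i)
      presence <- stats::setNames(as.list(rep(FALSE, 3L)), samples)
      presence[[config$affected_primary]] <- TRUE
      if (labels[i] == "control_shared") presence[[config$control]] <- TRUE
      k <- k + 1L
      rows[[k]] <- data.frame(sv_id = sprintf("sv%04d", k), sv_type = type,
                              chrom = chrom, start = start, end = start + size - 1L,
                              genes = gene, stringsAsFactors = FALSE)
      rows[[k]] <- cbind(rows[[k]], as.data.frame(presence, check.names = FALSE))
      truth[[k]] <- data.frame(sv_id = rows[[k]]$sv_id, label = labels[i],
                               stringsAsFactors = FALSE)
      if (labels[i] == "concordant") {
        # jittered partner carried by the secondary affected genome
        js <- start + sample(-config$jitter:config$jitter, 1L)
        je <- start + size - 1L + sample(-config$jitter:config$jitter, 1L)
        if (je < js) je <- js
        presence2 <- stats::setNames(as.list(rep(FALSE, 3L)), samples)
        presence2[[config$affected_secondary]] <- TRUE
        k <- k + 1L
        rows[[k]] <- data.frame(sv_id = sprintf("sv%04d", k), sv_type = type,
                                chrom = chrom, start = max(1L, js), end = je,
                                genes = gene, stringsAsFactors = FALSE)
        rows[[k]] <- cbind(rows[[k]], as.data.frame(presence2, check.names = FALSE))
        truth[[k]] <- data.frame(sv_id = rows[[k]]$sv_id, label = "concordant",
                                 stringsAsFactors = FALSE)
      }
    }
    list(svs = sv_table(do.call(rbind, rows), samples),
         truth = do.call(rbind, truth))
  })
}

#' Configuration for the synthetic cohort genotype generator
#'
#' @param loci list of locus definitions, each a list with `locus_id`,
#'   `alleles` (two single-character alleles) and per-group specs
#'   `affected` / `control`: in `exact` mode named integer genotype counts
#'   summing to the group size; in `sampling` mode named genotype
#'   frequencies summing to 1. Genotype names use the locus alleles in any
#'   order (`TC` and `CT` are the same genotype).
#' @param n_affected,n_control group sizes (default 32 + 32, the validation
#'   cohort design).
#' @param mode `"exact"` (deterministic layout matching the counts) or
#'   `"sampling"` (genotypes drawn from the frequencies).
#' @param seed integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(loci, n_affected = 32L, n_control = 32L,
                              mode = c("exact", "sampling"), seed = 1L) {
  mode <- match.arg(mode)
  for (l in loci) {
    stopifnot(!is.null(l$locus_id), length(l$alleles) == 2L,
              all(nchar(l$alleles) == 1L))
  }
  structure(list(loci = loci, n_affected = as.integer(n_affected),
                 n_control = as.integer(n_control), mode = mode, seed = seed),
            class = "cohort_sim_config")
}

canonical_genotype_names <- function(x, alleles) {
  labs <- vapply(strsplit(names(x), ""), function(ch) {
    if (length(ch) != 2L || !all(ch %in% alleles)) {
      abort("invalid genotype label '%s'", paste(ch, collapse = ""))
    }
    paste(sort(ch), collapse = "")
  }, character(1))
  stats::setNames(as.numeric(x), labs)
}

#' Generate a cohort genotype table with known frequencies
#'
#' @param config a [cohort_sim_config()].
#' @return List: `table` (a [cohort_genotypes()] table) and `truth`
#'   (list per locus and group of the configured genotype counts or
#'   frequencies, genotype names canonicalised).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    rows <- list(); truth <- list()
    group_n <- c(affected = config$n_affected, control = config$n_control)
    for (l in config$loci) {
      truth[[l$locus_id]] <- list()
      for (grp in c("affected", "control")) {
        spec <- canonical_genotype_names(l[[grp]], l$alleles)
        n <- group_n[[grp]]
        if (config$mode == "exact") {
          if (any(spec != round(spec)) || sum(spec) > n) {
            abort("exact-mode counts for locus %s/%s must be integers summing to <= %d",
                  l$locus_id, grp, n)
          }
          gts <- rep(names(spec), times = spec)
          gts <- c(gts, rep("", n - length(gts)))  # remainder untyped
        } else {
          if (abs(sum(spec) - 1) > 1e-8) {
            abort("sampling-mode frequencies for locus %s/%s must sum to 1",
                  l$locus_id, grp)
          }
          gts <- sample(names(spec), n, replace = TRUE, prob = spec)
        }
        a1 <- substr(gts, 1, 1); a2 <- substr(gts, 2, 2)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("%s_%03d", grp, seq_len(n)),
          group = grp, locus_id = l$locus_id,
          allele1 = a1, allele2 = a2, stringsAsFactors = FALSE
        )
        truth[[l$locus_id]][[grp]] <- spec
      }
    }
    list(table = cohort_genotypes(do.call(rbind, rows)), truth = truth)
  })
}

#' Configuration for the synthetic ligation-probe signal generator
#'
#' The noise model is multiplicative log-normal with unit mean and the given
#' coefficient of variation, applied independently to every peak. A sample
#' with zero copies of the target emits a small positive floor (2% of
#' baseline) before noise, keeping peak signals strictly positive while
#' preserving class separation.
#'
#' @param copies data.frame with columns `sample_id, group, copies`
#'   (copies of the target segment, 0-3).
#' @param probe target probe id.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param baseline reference peak scale in fluorescence units.
#' @param reference_probes three reference probe ids.
#' @param seed integer seed.
#' @return A list of class `signal_sim_config`.
#' @export
signal_sim_config <- function(copies, probe = "wwox_del", cv = 0.1,
                              baseline = 1000,
                              reference_probes = DEFAULT_REFERENCE_PROBES,
                              seed = 1L) {
  stopifnot(is.data.frame(copies),
            all(c("sample_id", "group", "copies") %in% names(copies)))
  if (any(!copies$copies %in% 0:3)) abort("copies must be in 0..3")
  if (cv < 0) abort("cv must be >= 0")
  structure(list(copies = copies, probe = probe, cv = cv, baseline = baseline,
                 reference_probes = reference_probes, seed = seed),
            class = "signal_sim_config")
}

# unit-mean lognormal draws with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a probe signal table with planted copy classes
#'
#' Target peaks scale with `copies / 2` times the baseline (floor 0.02x
#' baseline at zero copies); reference peaks sit at the baseline. All peaks
#' carry independent multiplicative log-normal noise.
#'
#' @param config a [signal_sim_config()].
#' @return List: `signals` (a [probe_signals()] table) and `truth`
#'   (data.frame `sample_id, group, copies`).
#' @export
generate_cnvplex <- function(config) {
  stopifnot(inherits(config, "signal_sim_config"))
  with_seed(config$seed, {
    cp <- config$copies
    n <- nrow(cp)
    target_scale <- ifelse(cp$copies == 0, 0.02, cp$copies / 2)
    target <- target_scale * config$baseline * rlnorm_cv(n, config$cv)
    rows <- data.frame(sample_id = cp$sample_id, group = cp$group,
                       probe_id = config$probe, peak_signal = target,
                       stringsAsFactors = FALSE)
    for (ref in config$reference_probes) {
      rows <- rbind(rows, data.frame(
        sample_id = cp$sample_id, group = cp$group, probe_id = ref,
        peak_signal = config$baseline * rlnorm_cv(n, config$cv),
        stringsAsFactors = FALSE
      ))
    }
    list(signals = probe_signals(rows, config$reference_probes),
         truth = cp)
  })
}

#' Configuration for the synthetic qPCR generator
#'
#' Group structure enters through additive offsets on the target-gene Ct
#' (reference Ct is group-independent), so a group with offset `-k` has a
#' true fold change of `2^k` against the zero-offset calibrator.
#'
#' @param offsets named numeric vector of per-group target-Ct offsets.
#' @param replicate_sd Gaussian sd of replicate Ct noise (cycles).
#' @param n_per_group individuals per group (default 3, the assay design).
#' @param gene target gene name.
#' @param base_ct_target,base_ct_reference baseline Ct values (cycles).
#' @param seed integer seed.
#' @return A list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(offsets = c(normal_female = 0, xx_dsd = -2,
                                        normal_male = 0),
                            replicate_sd = 0.1, n_per_group = 3L,
                            gene = "IFITM1", base_ct_target = 25,
                            base_ct_reference = 20, seed = 1L) {
  if (is.null(names(offsets))) abort("offsets must be named by group")
  if (replicate_sd < 0) abort("replicate_sd must be >= 0")
  structure(list(offsets = offsets, replicate_sd = replicate_sd,
                 n_per_group = as.integer(n_per_group), gene = gene,
                 base_ct_target = base_ct_target,
                 base_ct_reference = base_ct_reference, seed = seed),
            class = "qpcr_sim_config")
}

#' Generate triplicate qPCR Ct records with known fold changes
#'
#' @param config a [qpcr_sim_config()].
#' @return List: `records` (an [expression_table()]) and `truth` (data.frame
#'   `group, true_log2_fold` relative to a zero-offset group).
#' @export
generate_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  with_seed(config$seed, {
    rows <- list()
    for (grp in names(config$offsets)) {
      for (i in seq_len(config$n_per_group)) {
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("%s_%02d", grp, i), group = grp,
          gene = config$gene, replicate = 1:3,
          ct_target = config$base_ct_target + config$offsets[[grp]] +
            stats::rnorm(3, 0, config$replicate_sd),
          ct_reference = config$base_ct_reference +
            stats::rnorm(3, 0, config$replicate_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    list(records = expression_table(do.call(rbind, rows)),
         truth = data.frame(group = names(config$offsets),
                            true_log2_fold = -unname(config$offsets),
                            stringsAsFactors = FALSE))
  })
}

#' Remove a 1-based inclusive interval from a DNA template
#'
#' @param template DNA string.
#' @param start,end interval to excise (1-based inclusive).
#' @return The shortened template string.
#' @export
excise_interval <- function(template, start, end) {
  template <- as.character(template)
  stopifnot(start >= 1, end >= start, end <= nchar(template))
  paste0(substr(template, 1, start - 1),
         substr(template, end + 1, nchar(template)))
}

#' Generate the WWOX deletion-assay amplicon fixture
#'
#' Builds a synthetic wild-type template that embeds the published assay
#' primer sites exactly 298 bp apart (outer edge to outer edge) around a
#' marked 70 bp interval, and the matching deletion-allele template with
#' that interval excised (amplifying 228 bp). Random filler is deterministic
#' under the seed; filler is re-drawn until neither primer site occurs
#' anywhere but its planted location in either template.
#'
#' @param seed integer seed.
#' @param flank filler length added on each side of the amplicon (bp).
#' @return List of class `amplicon_fixture`: `wildtype`, `deletion`
#'   (DNA strings), `primers` (a [primer_pair()]), `deletion_interval`
#'   (1-based inclusive coordinates on the wild-type template).
#' @export
generate_amplicon_fixture <- function(seed = 1L, flank = 60L) {
  primers <- wwox_assay_primers()
  fwd <- primers$forward
  rev_site <- revcomp(primers$reverse)
  del_len <- 70L; product <- 298L
  spacer1 <- 90L
  spacer2 <- product - nchar(fwd) - spacer1 - del_len - nchar(rev_site)
  stopifnot(spacer2 > 0L)
  with_seed(seed, {
    fixture <- NULL
    for (attempt in 1:100) {
      wt <- paste0(random_dna(flank), fwd, random_dna(spacer1),
                   random_dna(del_len), random_dna(spacer2), rev_site,
                   random_dna(flank))
      del_start <- flank + nchar(fwd) + spacer1 + 1L
      del_end <- del_start + del_len - 1L
      del <- excise_interval(wt, del_start, del_end)
      ok <- all(vapply(list(wt, del), function(tmpl) {
        length(Biostrings::matchPattern(fwd, Biostrings::DNAString(tmpl))) == 1L &&
          length(Biostrings::matchPattern(rev_site, Biostrings::DNAString(tmpl))) == 1L
      }, logical(1)))
      if (ok) {
        fixture <- structure(
          list(wildtype = wt, deletion = del, primers = primers,
               deletion_interval = c(start = del_start, end = del_end)),
          class = "amplicon_fixture")
        break
      }
    }
    if (is.null(fixture)) abort("could not place unique primer sites (try another seed)")
    fixture
  })
}

#' Write an amplicon fixture to FASTA
#'
#' @param fixture a [generate_amplicon_fixture()] result.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(fixture, path) {
  stopifnot(inherits(fixture, "amplicon_fixture"))
  seqs <- Biostrings::DNAStringSet(c(wildtype = fixture$wildtype,
                                     deletion = fixture$deletion))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read templates from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_templates <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}
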