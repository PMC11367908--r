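---
title: "Recessive variant screening and validation for SRY-negative XX DSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive variant screening and validation for SRY-negative XX DSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsdscreen)
```

## The problem

In pigs, XX differences of sex development (DSD) without the *SRY* gene are
common enough to matter economically: 38,XX animals develop testis-like or
ovotestis gonads, are infertile, and the condition behaves like an
autosomal-recessive trait in breeding data. The discovery design this
package implements compares the genome of one normal female (`NF`) against
two affected animals (`D1`, `D2`), then validates candidate variants in an
independent cohort of 32 affected and 32 control females.

`dsdscreen` packages every computational step of that workflow: the
trio-based recessive SNP screen, a two-step structural-variant (SV)
concordance screen, candidate-gene panel prioritisation, cohort genotype
and allele frequencies, ligation-probe relative copy-number calls, in-silico
PCR for the *WWOX* deletion and duplex *SRY* assays, and delta-delta-Ct
expression analysis. Seeded generators produce synthetic inputs with planted
ground truth for every stage, so the whole pipeline is testable without any
sequencing data.

## The recessive SNP screen

The screen works on per-sample zygosity calls of annotated SNVs. For each
sample we form three sets of nonsynonymous variant keys: `all_ns` (het or
hom), `hom_ns`, and `het_ns`. Writing `NF` for the control and `D1`, `D2`
for the affected genomes, the four criteria are pure set algebra:

* **A** — homozygous in all affected, absent from the control:
  $(D1_{hom} \cap D2_{hom}) \setminus NF_{all}$
* **B** — homozygous only in the control:
  $NF_{hom} \setminus (D1_{all} \cup D2_{all})$
* **C** — homozygous in affected, heterozygous in the control:
  $(D1_{hom} \cap D2_{hom}) \cap NF_{het}$
* **D** — heterozygous only in the control:
  $NF_{het} \setminus (D1_{all} \cup D2_{all})$

Criteria A and C encode the autosomal-recessive causal model (affected
animals homozygous, the control a non-carrier or carrier); B and D are the
mirror-image contrasts on the control side and are computed and reported
separately. The four sets are pairwise disjoint by construction — hom and
het are disjoint within a sample, and presence/absence in the control
separates A/C from B/D — so the screen total is simply the sum of the four
set sizes. With more than two affected genomes the intersections and unions
extend over all of them.

```{r screen}
g <- generate_trio_snvs(trio_sim_config(kA = 50, kB = 30, kC = 20, kD = 10,
                                        seed = 7))
screen_all(g$variants, g$roles)
```

Three decisions were genuinely open and are resolved as follows:

* **Missing genotypes.** A `no_call` enters no zygosity set: it is treated
  as unevaluable rather than as evidence of absence, and the count of
  excluded no-calls is recorded on the result. Imputing absence would let a
  failed call fabricate a criterion-A hit.
* **Effect classes.** The screen is restricted to `nonsynonymous` effects,
  matching the discovery design's own labels. Truncating classes
  (`stopgain`, `stoploss`) can be admitted through the `effects` argument
  of `build_zygosity_sets()`/`screen_all()`, since a stop-gain is, if
  anything, a stronger recessive candidate.
* **Variant identity.** Records are keyed by `(chrom, pos, ref, alt)` with
  upper-cased alleles; multi-allelic VCF rows are split into one record per
  alternate allele before keying, so the set algebra always operates on
  site-alleles.

## The SV concordance screen

SVs from de novo assemblies have imprecise breakpoints, so "the same SV" in
two genomes needs a matching policy. The default (`gene_and_type`) follows
the discovery criterion — same variant type and shared gene content — with
a positional sanity check: the intervals must overlap by at least 1 bp or
have nearest breakpoints within a tolerance (default 1000 bp; no tolerance
is stated in the source protocol, so this is a configurable package
decision). Intergenic SVs, for which a gene criterion is undefined, fall
back to type plus breakpoint proximity. A `reciprocal_overlap` mode
(default 50% both ways) is offered for gene-sparse regions; inversions are
always matched on breakpoints there, because overlap fraction is
uninformative for balanced events.

Screening is two monotone filters: step A keeps SVs carried by the primary
affected genome with no match among the control's SVs; step B keeps the
step-A survivors that match at least one SV carried by the second affected
genome.

```{r svscreen}
sg <- generate_sv_sets(sv_sim_config(n_concordant = 20, n_primary_only = 15,
                                     n_control_shared = 10, seed = 3))
a <- screen_step_a(sg$svs, "NF", "D2")
b <- screen_step_b(a, sg$svs, other_sample = "D1")
c(step_a = nrow(a), step_b = nrow(b))
```

All coordinates are 1-based inclusive with `size = end - start + 1`; the
curated candidate list validates this convention (the *WWOX* intron-5
deletion at 6:9669113–9669182 spans exactly 70 bp). BEDPE input/output is
converted to and from 0-based half-open breakpoints at the boundary.

## Cohort validation statistics

Genotype labels are unordered allele multisets displayed in lexicographic
order (`TC` and `CT` are the same genotype). Frequencies are counts over
typed individuals; missing genotypes reduce `n_typed` rather than being
imputed. Allele frequencies count two alleles per homozygote and one per
heterozygote: `freq(x) = (2 hom_x + het_x) / (2 n_typed)`.

```{r cohort}
tab <- generate_cohort(cohort_sim_config(
  loci = list(list(locus_id = "IFITM1_c218", alleles = c("T", "C"),
                   affected = c(TT = 28, TC = 4), control = c(CC = 32))),
  mode = "exact", seed = 1))$table
e <- genotype_frequencies(tab, "IFITM1_c218", "affected")
display_freq(e$genotype_freq)
display_freq(allele_frequencies(e))
```

Display rounding is round-half-even at three decimals; computation always
carries full precision. Half-even reproduces the published display values
0.938, 0.062, 0.906 and 0.094 from the exact fractions 60/64, 4/64, 58/64
and 6/64. (The published genotype-frequency pair 0.813/0.187 for 26/32 and
6/32 is internally inconsistent under any single rounding convention —
half-even gives 0.812/0.188 — and is left as-is rather than "corrected".)

`exclusivity_check()` partitions observed genotypes into affected-only,
control-only and shared; `carrier_prevalence()` reports the fraction of a
group with at most one intact copy at a deletion locus; and
`association_test()` adds a Fisher exact test on the 2×2 allele-count table
with a Haldane–Anscombe-corrected odds ratio. The test is explicitly an
extension of this package: the validation design it models reported
frequencies only.

## Copy-number quantification

Ligation-probe assays report fluorescent peak signals. Within a sample, the
target peak is normalised by the arithmetic mean of three reference probes
(`ACTB`, `COL10A1`, `GCG`), making the statistic invariant to per-sample
scaling. Across samples, normalised signals are anchored to the control
cohort: `relative_cn = 2 * norm(sample) / median(norm(controls))`, so
controls centre at two copies. The median (not mean) baseline is this
package's choice — the source protocol does not state one — because it
tolerates a contaminating deletion carrier among the controls. Copy classes
use thresholds at 0.5/1.5/2.5 copy units (also a package default, exposed
as an argument): below 0.5 is homozygous loss, then heterozygous loss, then
diploid, then gain.

The synthetic signal generator draws multiplicative log-normal noise with
configurable coefficient of variation (CV); zero-copy samples emit a small
positive floor (2% of baseline) so peaks stay positive. At CV 10% and 64
samples the classifier recovers ≥ 99% of planted classes; that bound is a
property of this noise model, not a claim about any particular instrument.

## PCR assays and expression

`predict_amplicons()` performs exact-match in-silico PCR: every forward
primer site paired with every downstream reverse-complemented reverse
site, product length measured outer edge to outer edge (1-based inclusive).
Degenerate bases are unsupported by design — the modelled assays use exact
primers. The packaged fixture generator builds a synthetic wild-type
template that embeds the published *WWOX* assay primers exactly 298 bp
apart around a marked 70 bp interval; excising the interval yields the
deletion allele and a 228 bp product, and excising any internal interval of
length *d* shortens every spanning product by exactly *d*.

`sry_status()` encodes the duplex typing logic: no GAPDH band voids the
assay; otherwise the SRY band decides.

`ddct()` implements relative expression: per individual,
`dCt = mean(Ct_target) - mean(Ct_reference)` over enforced triplicates;
`ddCt` subtracts the calibrator-group mean (default `normal_female`); fold
change is `2^-ddCt`. The calibrator's mean `ddCt` is zero by construction,
so its mean fold is exactly 1 only at zero noise (the mean of `2^-x` under
noise exceeds 1 slightly). A two-sided Welch t-test on `dCt` against the
calibrator is reported per group, labelled as a package convenience — the
original analysis marked significance without stating a test.

## What the generators emulate — and what they do not

The synthetic module plants truth for every stage: trio genotype patterns
per criterion plus non-selectable backgrounds (shared homozygotes,
single-affected homozygotes, synonymous and intronic variants), SV
concordance classes with jittered breakpoints, exact-count or sampled
cohort genotypes, noisy probe signals with known copy classes, and
group-structured Ct values. Default design points mirror the study:
a 32+32 validation cohort, triplicate qPCR with n = 3 per group, three
reference probes, the 70 bp deletion inside a 298 bp amplicon.

They do not emulate read-level sequencing error, assembly artefacts,
annotation mistakes, linkage between loci, batch effects in fluorescence,
or qPCR efficiency differences between genes. Passing planted-truth tests
therefore demonstrates that the set algebra, matching, normalisation and
arithmetic are correct — not that the upstream calling and annotation of
real genomes would be. Genome-scale figures from the discovery study
(millions of SNPs per genome, thousands of screened variants) depend on raw
data and are out of desk-scale reach; the per-criterion recovery tests at
planted counts (50, 30, 20, 10) stand in for them.

Test and example problem sizes (hundreds of variants, tens of SVs, 64-sample
cohorts, 100-table oracle-equivalence sweeps) were chosen so the full suite
runs in well under a minute while still exercising every code path;
convergence checks scale the cohort sampler up to n = 3200 with a
3·√(p(1−p)/n) binomial bound.

## Numerical and degenerate-input choices

* Seeded generators save and restore the caller's RNG state; identical
  configs give byte-identical outputs.
* `variant_key` upper-cases alleles; gene symbols are upper-cased on read.
* Frequencies are exact rational arithmetic in doubles; sums are asserted
  to 1e-9 in tests.
* Empty inputs: header-only tables read as empty; an empty amplicon result
  is a value, not an error; empty control sets, empty groups and zero typed
  individuals are errors.
* N50 follows the sort-descending-and-accumulate definition and is
  permutation invariant.

## Known limitations

* The screen consumes genotype calls as given; how heterozygosity is
  derived from haploid de novo consensus assemblies is upstream of this
  package.
* `gene_and_type` SV matching cannot distinguish two different events in
  the same gene closer than the breakpoint tolerance.
* The amplicon predictor models exact annealing only — no mismatches,
  degenerate bases, or thermodynamics.
* The association test assumes allele counts are independent draws, which
  ignores the two-alleles-per-animal structure; it is a screening
  convenience, not a genetic model.
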