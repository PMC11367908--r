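# dsdscreen

Variant screening and validation toolkit for SRY-negative XX differences of
sex development (DSD) in pigs — an R package plus a small analysis workflow.

XX DSD pigs carry a normal 38,XX female karyotype and no *SRY* gene, yet
develop testis-like or ovotestis gonads. The condition segregates like an
autosomal-recessive trait. `dsdscreen` implements the computational side of
a trio-plus-cohort discovery design for it:

* **Recessive SNP screen** — over one control female (`NF`) and two
  affected genomes (`D1`, `D2`), four set-algebra criteria on per-sample
  zygosity sets of nonsynonymous variants:
  * A: `(D1_hom ∩ D2_hom) \ NF_all` (homozygous only in affected)
  * B: `NF_hom \ (D1_all ∪ D2_all)` (homozygous only in the control)
  * C: `(D1_hom ∩ D2_hom) ∩ NF_het` (affected homozygous, control carrier)
  * D: `NF_het \ (D1_all ∪ D2_all)` (heterozygous only in the control)

  The four sets are provably disjoint; the screen total is their summed
  size. Candidate-gene panel prioritisation follows.
* **SV concordance screen** — step A keeps SVs specific to an affected
  genome versus the control, step B keeps those concordant (same gene and
  type at compatible positions) with the second affected genome; plus
  cohort burden summaries (animals with exactly one / two-or-more
  candidate SVs).
* **Cohort validation** — genotype and allele frequencies per group at
  validated loci, affected-exclusive genotype detection, deletion carrier
  prevalence, and a Fisher allele-count association test.
* **Quantification** — ligation-probe (MLPA/CNVplex-style) relative copy
  number: target peak / mean of three reference probes (`ACTB`, `COL10A1`,
  `GCG`), scaled so the control median sits at 2 copies, classified at
  0.5/1.5/2.5; in-silico PCR for the *WWOX* intron-5 deletion assay
  (298 bp wild type vs 228 bp deletion band) and duplex *SRY*/*GAPDH*
  typing; delta-delta-Ct expression analysis
  (`fold = 2^-(dCt - dCt_calibrator)`).
* **Synthetic data** — seeded generators with planted ground truth for
  every input above, so the full pipeline runs and is tested without any
  sequencing data.

## Worked example

```r
library(dsdscreen)

# a synthetic trio with 110 variants planted across the four criteria
g <- generate_trio_snvs(trio_sim_config(kA = 50, kB = 30, kC = 20, kD = 10,
                                        seed = 7))
screen_all(g$variants, g$roles)
#> Recessive screen: A=50 B=30 C=20 D=10 (total 110)

# cohort validation at the IFITM1 locus: 28 TT + 4 TC affected vs 32 CC controls
tab <- generate_cohort(cohort_sim_config(
  loci = list(list(locus_id = "IFITM1_c218", alleles = c("T", "C"),
                   affected = c(TT = 28, TC = 4), control = c(CC = 32))),
  mode = "exact", seed = 1))$table
e <- genotype_frequencies(tab, "IFITM1_c218", "affected")
display_freq(e$genotype_freq)
#>    CC    CT    TT
#> 0.000 0.125 0.875
display_freq(allele_frequencies(e))
#>     C     T
#> 0.062 0.938

# the WWOX deletion assay in silico
fx <- generate_amplicon_fixture(seed = 1)
predict_amplicons(fx$wildtype, fx$primers)   # 298
predict_amplicons(fx$deletion, fx$primers)   # 228
```

The affected cohort shows genotype frequencies TT = 0.875 and TC = 0.125
(allele T at 0.938), genotypes absent from controls — the pattern that
flags a locus as affected-exclusive. The two amplicon lengths differ by
exactly the 70 bp deletion, so heterozygous animals show both bands.

## The analysis workflow

Numbered drivers under `analysis/` run the whole pipeline on synthetic
inputs and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # all synthetic inputs, seeded
Rscript analysis/02_snp_screen.R        # recessive screen + panel filter
Rscript analysis/03_sv_screen.R         # SV steps A/B + cohort burden
Rscript analysis/04_cohort_validation.R # frequencies, exclusivity, association
Rscript analysis/05_copy_number.R       # relative CN calls + class recovery
Rscript analysis/06_assays.R            # amplicons, SRY typing, delta-delta-Ct
```

Each stage prints what it found (e.g. exact recovery of planted screen
classes, 22/10 one-SV/multi-SV burden split, 62.5% WWOX deletion carrier
prevalence) and leaves its outputs as TSV.

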