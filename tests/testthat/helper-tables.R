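# shared in-code fixtures

# the six-variant toy trio used across the screen tests:
# v1 NF=absent D1=hom D2=hom   -> criterion A
# v2 NF=hom    D1=absent D2=absent -> criterion B
# v3 NF=het    D1=hom D2=hom   -> criterion C
# v4 NF=het    D1=absent D2=absent -> criterion D
# v5 hom in all three           -> no criterion
# v6 NF=absent D1=hom D2=het   -> no criterion
toy_trio <- function() {
  snv_table(data.frame(
    chrom = "1", pos = 1:6, ref = "A", alt = "G",
    gene = sprintf("TOY%d", 1:6), region = "exonic", effect = "nonsynonymous",
    NF = c("absent", "hom", "het", "het", "hom", "absent"),
    D1 = c("hom", "absent", "hom", "absent", "hom", "hom"),
    D2 = c("hom", "absent", "hom", "absent", "hom", "het"),
    stringsAsFactors = FALSE
  ), samples = c("NF", "D1", "D2"))
}

toy_roles <- function() sample_roles("NF", c("D1", "D2"))

toy_cohort_table3 <- function() {
  cfg <- cohort_sim_config(
    loci = list(
      list(locus_id = "IFITM1_c218", alleles = c("T", "C"),
           affected = c(TT = 28, TC = 4), control = c(CC = 32)),
      list(locus_id = "NOBOX_c1043", alleles = c("C", "G"),
           affected = c(CC = 26, CG = 6), control = c(GG = 32))
    ),
    n_affected = 32, n_control = 32, mode = "exact", seed = 1
  )
  generate_cohort(cfg)$table
}
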