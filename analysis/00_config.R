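# Shared configuration for the analysis scripts. Desk-scale study
# conditions: an 11-strain conspecific population (sub-clades I-IV split
# 4+3+2+2), 200-kb linear chromosomes with 20-kb TIRs, one linear
# plasmid, and an inter-strain telomere swap planted on strain s10
# (donor s01, sub-clade I) so the congruence stage has a known positive:
# s10 should cluster with sub-clade I telomeres and leave its genome
# sister s11. Every stage seed derives from RUN_SEED; rerunning any
# script reproduces its outputs exactly.

library(linearends)

RUN_SEED <- 20260930
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

run_config <- function(stages) {
  default_run_config(
    seed = RUN_SEED,
    stages = stages,
    population = population_config(
      n_strains = 11,
      plasmids = list(list(id = "pS-14.1", length = 20000,
                           tir_length = 2000, motif = "GCA")),
      event_list = list(list(kind = "telomere_swap", strain = "s10",
                             donor = "s01"))),
    phylo = list(n_boot = 100),
    recomb = list(region = 6000, n_perm = 1000, n_perm_explore = 200),
    tp = list(region = 12000))
}
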