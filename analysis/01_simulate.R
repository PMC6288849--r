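#!/usr/bin/env Rscript
# Stage 1: simulate two admixed study cohorts with known truth.
#
# Two populations with contrasting three-way admixture (LATA leans European,
# LATB leans African), M = 20,000 SNPs, N = 100 diploid individuals each,
# Balding-Nichols source divergence F = 0.1, and 100 SNPs per cohort given a
# post-admixture frequency shift of +0.2 toward a donor source whose allele
# frequency leads the other sources by at least 0.3.
#
# Genotypes and per-individual truth go to scratch/analysis (large,
# regenerable); compact summaries go to results/analysis.

suppressMessages(library(admixscan))

seed <- 2018L
scratch <- "scratch/analysis"
resdir <- "results/analysis"
dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
dir.create(resdir, recursive = TRUE, showWarnings = FALSE)

alphas <- list(LATA = c(3, 5, 2),     # mean ancestry (0.30, 0.50, 0.20)
               LATB = c(5, 3, 2))     # mean ancestry (0.50, 0.30, 0.20)

cfg0 <- sim_config(n_snps = 20000L, n_individuals = 100L, fst = 0.1,
                   dirichlet_alpha = alphas[[1]], seed = seed)
panel <- simulate_ancestral_frequencies(cfg0)
write_frequency_panel(panel, file.path(scratch, "panel.tsv"))

summary_rows <- list()
for (pop in names(alphas)) {
  cfg <- sim_config(n_snps = 20000L, n_individuals = 100L, fst = 0.1,
                    dirichlet_alpha = alphas[[pop]], population = pop,
                    seed = seed + match(pop, names(alphas)))
  cohort <- simulate_admixed_genotypes(panel, cfg)
  spec <- pick_enrichment_candidates(panel, cohort$profiles, n = 100,
                                     delta = 0.2, margin = 0.3)
  inj <- inject_enrichment(cohort$gm, panel, cohort$profiles, spec,
                           seed = cfg$seed)
  write_vcf(inj$gm, file.path(scratch, paste0("genotypes_", pop, ".vcf")))
  write_profiles(cohort$profiles,
                 file.path(scratch, paste0("profiles_true_", pop, ".tsv")))
  write_results(inj$truth, file.path(scratch, paste0("truth_", pop, ".tsv")))

  qbar <- colMeans(cohort$q)
  summary_rows[[pop]] <- data.frame(
    population = pop, n = 100L, m_snps = 20000L,
    AFR = round(qbar["AFR"], 3), EUR = round(qbar["EUR"], 3),
    NAT = round(qbar["NAT"], 3), n_enriched = nrow(inj$truth),
    mean_injected_shift = round(mean(inj$truth$delta), 3))
  message(sprintf(
    "[01] %s: N=100, mean ancestry AFR=%.2f EUR=%.2f NAT=%.2f, %d SNPs shifted",
    pop, qbar["AFR"], qbar["EUR"], qbar["NAT"], nrow(inj$truth)))
}
write_results(do.call(rbind, summary_rows),
              file.path(resdir, "01_cohorts.tsv"))
message("[01] wrote ", resdir, "/01_cohorts.tsv and genotypes under ", scratch)
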