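#!/usr/bin/env Rscript
# Stage 2: estimate genome-wide ancestry proportions for each cohort with the
# supervised maximum-likelihood (EM) estimator and score them against the
# simulator's truth.  In a real study these proportions would come from an
# external unsupervised run; here the estimator closes the loop so the whole
# pipeline is checkable.

suppressMessages(library(admixscan))

scratch <- "scratch/analysis"
resdir <- "results/analysis"
panel <- read_frequency_panel(file.path(scratch, "panel.tsv"))

rows <- list()
for (pop in c("LATA", "LATB")) {
  gm <- read_vcf(file.path(scratch, paste0("genotypes_", pop, ".vcf")))
  est <- estimate_proportions(gm, panel)
  write_profiles(est, file.path(scratch, paste0("profiles_est_", pop, ".tsv")))
  tru <- read_profiles(file.path(scratch,
                                 paste0("profiles_true_", pop, ".tsv")))
  src <- c("AFR", "EUR", "NAT")
  err <- abs(as.matrix(est[src]) - as.matrix(tru[match(est$unit, tru$unit),
                                                 src]))
  pp <- population_profile(est, population = pop)
  rows[[pop]] <- data.frame(
    population = pop,
    AFR = round(pp$AFR, 4), EUR = round(pp$EUR, 4), NAT = round(pp$NAT, 4),
    median_max_error = round(median(apply(err, 1, max)), 4),
    em_iterations = attr(est, "iterations"))
  message(sprintf(
    "[02] %s: population profile AFR=%.3f EUR=%.3f NAT=%.3f; median per-individual max error %.3f",
    pop, pp$AFR, pp$EUR, pp$NAT, median(apply(err, 1, max))))
}
write_results(do.call(rbind, rows), file.path(resdir, "02_ancestry.tsv"))
message("[02] wrote ", resdir, "/02_ancestry.tsv")
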