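#!/usr/bin/env Rscript
# Stage 4: map significant SNPs to gene bodies (1-based inclusive interval
# containment), test curated gene sets for overrepresentation with the
# hypergeometric upper tail, and count how many genes are exclusive to one
# cohort or shared.  Gene models and sets are synthetic: one in four sets is
# seeded with genes that actually carry enriched SNPs, the rest are random.

suppressMessages(library(admixscan))

scratch <- "scratch/analysis"
resdir <- "results/analysis"
panel <- read_frequency_panel(file.path(scratch, "panel.tsv"))

genes <- simulate_gene_models(panel, n_genes = 400L, coverage = 0.5)
write_bed(genes, file.path(scratch, "genes.bed"))

gene_lists <- list()
scans <- list()
for (pop in c("LATA", "LATB")) {
  scans[[pop]] <- read_results(file.path(scratch,
                                         paste0("scan_", pop, ".tsv")))
  sig <- scans[[pop]][scans[[pop]]$q < 0.05, ]
  gene_lists[[pop]] <- map_snps_to_genes(sig, genes)$genes
}
signal <- unique(unlist(gene_lists))
sets <- simulate_gene_sets(genes$name, n_sets = 40L,
                           signal_genes = signal, n_signal_sets = 10L,
                           signal_fraction = 0.6, seed = 2018L)
write_gmt(sets, file.path(scratch, "sets.gmt"))

for (pop in c("LATA", "LATB")) {
  background <- map_snps_to_genes(scans[[pop]], genes)$genes
  res <- overlap_enrichment(intersect(gene_lists[[pop]], background),
                            sets, background)
  write_results(res, file.path(resdir, paste0("04_gsea_", pop, ".tsv")))
  message(sprintf("[04] %s: %d genes with enriched SNPs; %d / %d sets at q<0.05",
                  pop, length(gene_lists[[pop]]), sum(res$q < 0.05),
                  nrow(res)))
}

sharing <- gene_sharing(gene_lists)
write_results(sharing$shared_by, file.path(resdir, "04_gene_sharing.tsv"))
message(sprintf("[04] gene sharing: %d exclusive, %d shared by both (of %d)",
                sharing$shared_by$n_genes[1], sharing$shared_by$n_genes[2],
                sharing$n_total))
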