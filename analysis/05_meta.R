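#!/usr/bin/env Rscript
# Stage 5: pathway-level meta-analysis.  Every significant SNP mapped to a
# gene of an overrepresented set contributes a log odds ratio of observed vs
# expected allele frequencies (Woolf-type variance); per (pathway, cohort)
# the SNP effects are combined by inverse-variance fixed-effect
# meta-analysis with normal-theory 95% confidence intervals — the forest-
# plot view of how strongly each pathway deviates from its ancestry
# expectation.

suppressMessages(library(admixscan))

scratch <- "scratch/analysis"
resdir <- "results/analysis"
genes <- read_bed(file.path(scratch, "genes.bed"))
sets <- read_gmt(file.path(scratch, "sets.gmt"))

rows <- list()
for (pop in c("LATA", "LATB")) {
  scan <- read_results(file.path(scratch, paste0("scan_", pop, ".tsv")))
  sig <- scan[scan$q < 0.05, ]
  if (nrow(sig) == 0) next
  lo <- snp_log_odds(sig)
  gmap <- map_snps_to_genes(sig, genes)$map
  gsea <- read_results(file.path(resdir, paste0("04_gsea_", pop, ".tsv")))
  for (sn in gsea$set_name[gsea$q < 0.05]) {
    vars <- gmap$variant[gmap$gene %in% sets[[sn]]]
    sub <- lo[variant_id(lo) %in% vars, ]
    if (nrow(sub) == 0) next
    sub$pathway <- sn
    sub$population <- pop
    rows[[length(rows) + 1L]] <- sub[c("chrom", "pos", "ref", "alt",
                                       "log_or", "variance", "pathway",
                                       "population")]
  }
}
if (length(rows) == 0)
  stop("no overrepresented pathway carries mapped significant SNPs; ",
       "run analysis/04_gsea.R first")
snp_tab <- do.call(rbind, rows)
meta <- pathway_meta(snp_tab)
meta <- meta[order(meta$pathway, meta$population), ]
write_results(meta, file.path(resdir, "05_pathway_meta.tsv"))
for (i in seq_len(nrow(meta))) {
  message(sprintf("[05] %s / %s: combined log OR %+.3f [%+.3f, %+.3f] over %d SNPs",
                  meta$pathway[i], meta$population[i],
                  meta$combined_log_or[i], meta$ci95_low[i],
                  meta$ci95_high[i], meta$n_snps[i]))
}
message("[05] wrote ", resdir, "/05_pathway_meta.tsv")
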