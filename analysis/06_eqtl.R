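#!/usr/bin/env Rscript
# Stage 6: ancestry-specific eQTL.  Expression traits are simulated for the
# joint cohort with genotype effects that exist only in LATA (beta = 1) plus
# pure-noise genes; each cohort is scanned separately with an additive
# linear model (sex as covariate, MAF > 5%), and each (gene, SNP) pair is
# classified as cohort-specific, shared, or neither.

suppressMessages(library(admixscan))

scratch <- "scratch/analysis"
resdir <- "results/analysis"
panel <- read_frequency_panel(file.path(scratch, "panel.tsv"))
genes <- read_bed(file.path(scratch, "genes.bed"))

gms <- lapply(c("LATA", "LATB"), function(pop)
  read_vcf(file.path(scratch, paste0("genotypes_", pop, ".vcf"))))
joint <- genotype_matrix(do.call(rbind, lapply(gms, function(g) g$dosage)),
                         gms[[1]]$variants,
                         do.call(rbind, lapply(gms, function(g) g$sample_meta)))

# ten causal SNPs, common in every source, each inside a gene body
fmat <- as.matrix(panel[panel_sources(panel)])
candidates <- which(apply(fmat, 1, function(f) all(f > 0.2 & f < 0.8)))
gmap <- map_snps_to_genes(panel[candidates, c("chrom", "pos", "ref", "alt")],
                          genes)$map
gmap <- gmap[!duplicated(gmap$gene), ][1:10, ]
causal_idx <- match(gmap$variant, variant_id(panel))
effects <- data.frame(gene = rep(gmap$gene, each = 2),
                      snp_index = rep(causal_idx, each = 2),
                      group = rep(c("LATA", "LATB"), 10),
                      beta = rep(c(1, 0), 10))
# VCFs carry no population column; recover the cohort from the sample prefix
groups <- sub("_.*$", "", rownames(joint$dosage))
sim_expr <- simulate_expression(joint, effects, groups = groups, sd = 0.5,
                                sex_effect = 0.3, n_null_genes = 20L,
                                seed = 2018L)

scans <- lapply(c("LATA", "LATB"), function(pop)
  scan_eqtl(sim_expr$expr, joint, genes = genes, cis_window = 0,
            covariates = sim_expr$covariates, group = pop))
cls <- classify_ancestry_specific(scans[[1]], scans[[2]])
write_results(cls, file.path(resdir, "06_eqtl_classified.tsv"))

tab <- table(cls$label)
message("[06] eQTL classification over ", nrow(cls), " (gene, SNP) pairs:")
for (nm in names(tab)) message(sprintf("[06]   %-14s %d", nm, tab[[nm]]))
causal_lab <- cls$label[cls$gene %in% gmap$gene &
                          cls$variant %in% gmap$variant]
message(sprintf("[06] causal pairs called LATA-specific: %d / %d",
                sum(causal_lab == "LATA-specific"), length(causal_lab)))
message("[06] wrote ", resdir, "/06_eqtl_classified.tsv")
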