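#' Pipeline configuration
#'
#' A single structured configuration drives the end-to-end analysis:
#' simulate (or ingest) cohorts, estimate ancestry, scan for
#' ancestry-enriched SNPs, gene-set enrichment, pathway meta-analysis and
#' the eQTL stage.  Can be read from a YAML file.
#'
#' @param populations named list: one entry per admixed population, each a
#'   list with `n` (individuals) and `alpha` (Dirichlet parameters).
#' @param n_snps SNPs per cohort.
#' @param fst Balding-Nichols divergence per source.
#' @param n_enriched injected enriched SNPs per population.
#' @param delta injected frequency shift.
#' @param margin donor-frequency margin for injection candidates.
#' @param q_threshold scan significance threshold.
#' @param gsea_background `"tested"` (genes overlapping any tested SNP) or
#'   `"all"` (all genes in the model file).
#' @param n_genes,n_sets synthetic annotation sizes.
#' @param meta_moderator use the population moderator in [pathway_meta()].
#' @param eqtl settings list: `cis_window`, `maf`, `q_sig`, `p_null`,
#'   `beta`, `sd`, `n_effect_genes`, `n_null_genes`.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(populations = list(
                              POP1 = list(n = 100L, alpha = c(3, 5, 2)),
                              POP2 = list(n = 100L, alpha = c(5, 3, 2))),
                            n_snps = 5000L, fst = 0.1, n_enriched = 20L,
                            delta = 0.2, margin = 0.3, q_threshold = 0.05,
                            gsea_background = c("tested", "all"),
                            n_genes = 200L, n_sets = 20L,
                            meta_moderator = FALSE,
                            eqtl = list(), seed = 1L) {
  gsea_background <- match.arg(gsea_background)
  eqtl_defaults <- list(cis_window = 1e6, maf = 0.05, q_sig = 0.05,
                        p_null = 0.1, beta = 1, sd = 0.5,
                        n_effect_genes = 5L, n_null_genes = 10L)
  eqtl <- utils::modifyList(eqtl_defaults, eqtl)
  stopifnot(length(populations) >= 1, !is.null(names(populations)))
  structure(list(populations = populations, n_snps = as.integer(n_snps),
                 fst = fst, n_enriched = as.integer(n_enriched),
                 delta = delta, margin = margin, q_threshold = q_threshold,
                 gsea_background = gsea_background,
                 n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 meta_moderator = meta_moderator, eqtl = eqtl,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# internal: hash of a config (stable across sessions)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[sort(names(unclass(config)))], file = tmp)
  unname(tools::md5sum(tmp))
}

# internal: metadata header lines for every output file
output_meta <- function(config, extra = NULL) {
  c(paste0("admixscan ",
           as.character(utils::packageVersion("admixscan"))),
    paste0("config_hash=", config_hash(config)),
    paste0("seed=", config$seed), extra)
}

#' Validate a sample manifest against expected group counts
#'
#' Computes per-population sample counts and the total, and compares them
#' with an expected table when one is given.  Duplicate sample IDs are an
#' error.
#'
#' @param manifest data.frame with columns `sample`, `population` (empty
#'   manifests are allowed, with a warning).
#' @param expected optional data.frame `population`, `n`.
#' @return list: `counts` (data.frame `population`, `n`), `total`,
#'   `matches_expected` (NA when no expectation given), `mismatches`.
#' @export
validate_manifest <- function(manifest, expected = NULL) {
  manifest <- as.data.frame(manifest)
  if (nrow(manifest) == 0) {
    warning("empty sample manifest")
    counts <- data.frame(population = character(), n = integer())
    return(list(counts = counts, total = 0L, matches_expected = NA,
                mismatches = character()))
  }
  stopifnot(all(c("sample", "population") %in% names(manifest)))
  dup <- manifest$sample[duplicated(manifest$sample)]
  if (length(dup) > 0)
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  tab <- table(manifest$population)
  counts <- data.frame(population = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  total <- sum(counts$n)
  matches <- NA
  mism <- character()
  if (!is.null(expected)) {
    expected <- as.data.frame(expected)
    got <- setNames(counts$n, counts$population)
    for (i in seq_len(nrow(expected))) {
      pop <- expected$population[i]
      if (is.na(got[pop]) || got[pop] != expected$n[i])
        mism <- c(mism, sprintf("%s: expected %d, found %d", pop,
                                expected$n[i],
                                ifelse(is.na(got[pop]), 0L, got[pop])))
    }
    matches <- length(mism) == 0
  }
  list(counts = counts, total = total, matches_expected = matches,
       mismatches = mism)
}

# internal: stage-tagged log line to stderr
stage_log <- function(stage, ...) {
  message(sprintf("[admixscan:%s] %s", stage, paste0(...)))
}

# internal: list the files a stage produces
stage_outputs <- function(outdir, stage, pops) {
  p <- function(...) file.path(outdir, paste0(...))
  switch(stage,
    simulate = c(p("panel.tsv"),
                 as.vector(vapply(pops, function(x)
                   c(p("genotypes_", x, ".vcf"), p("profiles_true_", x, ".tsv"),
                     p("truth_", x, ".tsv")), character(3))),
                 p("genes.bed"), p("expression.tsv"), p("covariates.tsv")),
    ancestry = vapply(pops, function(x) p("profiles_est_", x, ".tsv"), ""),
    scan = vapply(pops, function(x) p("scan_", x, ".tsv"), ""),
    gsea = c(vapply(pops, function(x) p("gsea_", x, ".tsv"), ""),
             p("gene_sharing.tsv"), p("sets.gmt")),
    meta = p("pathway_meta.tsv"),
    eqtl = p("eqtl_classified.tsv"),
    stop("unknown stage ", stage))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the stages in dependency order — simulate, ancestry estimation,
#' enrichment scan, gene-set enrichment, pathway meta-analysis, eQTL — and
#' writes each stage's tables under `outdir` with metadata headers (tool
#' version, config hash, seed).  A stage is skipped when all of its output
#' files already exist and the stored manifest shows the same config hash;
#' re-running with an identical config and seed therefore reproduces
#' byte-identical outputs and skips everything.  A stage failure stops the
#' downstream stages; the manifest written so far records partial
#' completion.
#'
#' @param config [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param force re-run all stages even when outputs exist.
#' @return the run manifest (named list, also written to
#'   `outdir/manifest.json`): per-stage file hashes, row counts, config
#'   echo, stage order.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pops <- names(config$populations)
  hash <- config_hash(config)
  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL

  manifest <- list(config_hash = hash, seed = config$seed,
                   stage_order = character(), stages = list())
  state <- new.env(parent = emptyenv())

  state$dirty <- FALSE   # set once any stage re-executes; forces downstream
  stage_done <- function(stage) {
    outs <- stage_outputs(outdir, stage, pops)
    !force && !state$dirty && !is.null(old_manifest) &&
      identical(old_manifest$config_hash, hash) &&
      stage %in% names(old_manifest$stages) && all(file.exists(outs))
  }
  record_stage <- function(stage, skipped) {
    if (!skipped) state$dirty <- TRUE
    outs <- stage_outputs(outdir, stage, pops)
    manifest$stage_order <<- c(manifest$stage_order, stage)
    manifest$stages[[stage]] <<- list(
      skipped = skipped,
      files = as.list(setNames(unname(tools::md5sum(outs)), basename(outs))))
    # persist after every stage so failures leave a partial manifest
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  meta <- output_meta(config)
  p <- function(...) file.path(outdir, paste0(...))

  ## ---- simulate ----
  if (stage_done("simulate")) {
    stage_log("simulate", "outputs up to date, skipped")
    record_stage("simulate", TRUE)
  } else {
    stage_log("simulate", "generating cohorts (M=", config$n_snps, ")")
    base_cfg <- sim_config(n_snps = config$n_snps,
                           n_individuals = config$populations[[1]]$n,
                           fst = config$fst,
                           dirichlet_alpha = config$populations[[1]]$alpha,
                           population = pops[1], seed = config$seed)
    panel <- simulate_ancestral_frequencies(base_cfg)
    write_frequency_panel(panel, p("panel.tsv"), meta)
    genes <- simulate_gene_models(panel, n_genes = config$n_genes)
    write_bed(genes, p("genes.bed"))
    for (i in seq_along(pops)) {
      cfg_i <- sim_config(n_snps = config$n_snps,
                          n_individuals = config$populations[[i]]$n,
                          fst = config$fst,
                          dirichlet_alpha = config$populations[[i]]$alpha,
                          population = pops[i],
                          seed = config$seed + i)
      cohort <- simulate_admixed_genotypes(panel, cfg_i)
      spec <- if (config$n_enriched > 0)
        pick_enrichment_candidates(panel, cohort$profiles,
                                   config$n_enriched, config$delta,
                                   config$margin)
      else data.frame(snp_index = integer(), donor = character(),
                      delta = numeric())
      inj <- inject_enrichment(cohort$gm, panel, cohort$profiles, spec,
                               seed = config$seed + i)
      write_vcf(inj$gm, p("genotypes_", pops[i], ".vcf"),
                meta = paste0("##", meta))
      write_profiles(cohort$profiles, p("profiles_true_", pops[i], ".tsv"),
                     meta)
      write_results(inj$truth, p("truth_", pops[i], ".tsv"), meta)
      state[[paste0("gm_", pops[i])]] <- inj$gm
      state[[paste0("profiles_", pops[i])]] <- cohort$profiles
    }
    # expression for the first two populations (or one, duplicated groups)
    expr_pops <- pops[seq_len(min(2, length(pops)))]
    gms <- lapply(expr_pops, function(x) state[[paste0("gm_", x)]])
    joint_dosage <- do.call(rbind, lapply(gms, function(g) g$dosage))
    joint_meta <- do.call(rbind, lapply(gms, function(g) g$sample_meta))
    joint <- genotype_matrix(joint_dosage, gms[[1]]$variants, joint_meta)
    ecfg <- config$eqtl
    # effect SNPs: common in every source, so every group's scan can see them
    maf_ok <- which(apply(as.matrix(panel[panel_sources(panel)]), 1,
                          function(f) all(f > 0.1 & f < 0.9)))
    eff_snps <- maf_ok[seq(1, length(maf_ok),
                           length.out = ecfg$n_effect_genes)]
    gmap <- map_snps_to_genes(panel[eff_snps, c("chrom", "pos", "ref",
                                                "alt")], genes)
    eff_genes <- gmap$map$gene[match(variant_id(panel[eff_snps, ]),
                                     gmap$map$variant)]
    eff_genes[is.na(eff_genes)] <- sprintf("EGENE%02d",
                                           which(is.na(eff_genes)))
    effects <- data.frame(gene = rep(eff_genes, each = 2),
                          snp_index = rep(eff_snps, each = 2),
                          group = rep(expr_pops[c(1, min(2, length(expr_pops)))],
                                      times = length(eff_snps)),
                          beta = rep(c(ecfg$beta, 0),
                                     times = length(eff_snps)))
    sim_expr <- simulate_expression(joint, effects, sd = ecfg$sd,
                                    n_null_genes = ecfg$n_null_genes,
                                    seed = config$seed)
    expr_df <- data.frame(gene = rownames(sim_expr$expr), sim_expr$expr,
                          check.names = FALSE)
    write_results(expr_df, p("expression.tsv"), meta)
    write_results(sim_expr$covariates, p("covariates.tsv"), meta)
    record_stage("simulate", FALSE)
  }

  load_gm <- function(pop) {
    nm <- paste0("gm_", pop)
    if (is.null(state[[nm]]))
      state[[nm]] <- read_vcf(p("genotypes_", pop, ".vcf"))
    state[[nm]]
  }
  panel <- read_frequency_panel(p("panel.tsv"))
  genes <- read_bed(p("genes.bed"))

  ## ---- ancestry ----
  if (stage_done("ancestry")) {
    stage_log("ancestry", "outputs up to date, skipped")
    record_stage("ancestry", TRUE)
  } else {
    for (pop in pops) {
      stage_log("ancestry", "estimating proportions for ", pop)
      est <- estimate_proportions(load_gm(pop), panel)
      write_profiles(est, p("profiles_est_", pop, ".tsv"), meta)
    }
    record_stage("ancestry", FALSE)
  }

  ## ---- scan ----
  if (stage_done("scan")) {
    stage_log("scan", "outputs up to date, skipped")
    record_stage("scan", TRUE)
  } else {
    for (pop in pops) {
      stage_log("scan", "ancestry-enrichment scan for ", pop)
      prof_ind <- read_profiles(p("profiles_est_", pop, ".tsv"))
      prof_pop <- population_profile(prof_ind, population = pop)
      scan <- run_enrichment_scan(load_gm(pop), panel,
                                  profile_vector(prof_pop, pop),
                                  q_threshold = config$q_threshold)
      write_results(scan$records, p("scan_", pop, ".tsv"), meta)
    }
    record_stage("scan", FALSE)
  }

  ## ---- gsea ----
  if (stage_done("gsea")) {
    stage_log("gsea", "outputs up to date, skipped")
    record_stage("gsea", TRUE)
  } else {
    gene_lists <- list()
    sig_genes_all <- character()
    for (pop in pops) {
      scan <- read_results(p("scan_", pop, ".tsv"))
      sig <- scan[scan$q < config$q_threshold, , drop = FALSE]
      gene_lists[[pop]] <- map_snps_to_genes(sig, genes)$genes
      sig_genes_all <- union(sig_genes_all, gene_lists[[pop]])
    }
    if (!file.exists(p("sets.gmt"))) {
      sets <- simulate_gene_sets(genes$name, n_sets = config$n_sets,
                                 signal_genes = sig_genes_all,
                                 n_signal_sets = max(1L, config$n_sets %/% 4L),
                                 seed = config$seed)
      write_gmt(sets, p("sets.gmt"))
    }
    sets <- read_gmt(p("sets.gmt"))
    for (pop in pops) {
      stage_log("gsea", "overlap enrichment for ", pop)
      scan <- read_results(p("scan_", pop, ".tsv"))
      background <- if (config$gsea_background == "all") genes$name else
        map_snps_to_genes(scan, genes)$genes
      res <- overlap_enrichment(intersect(gene_lists[[pop]], background),
                                sets, background)
      write_results(res, p("gsea_", pop, ".tsv"), meta)
    }
    if (length(pops) >= 2) {
      sharing <- gene_sharing(gene_lists)
      write_results(sharing$shared_by, p("gene_sharing.tsv"), meta)
    } else {
      write_results(data.frame(n_pops = 1L,
                               n_genes = length(gene_lists[[1]])),
                    p("gene_sharing.tsv"), meta)
    }
    record_stage("gsea", FALSE)
  }

  ## ---- meta ----
  if (stage_done("meta")) {
    stage_log("meta", "outputs up to date, skipped")
    record_stage("meta", TRUE)
  } else {
    stage_log("meta", "pathway meta-analysis")
    sets <- read_gmt(p("sets.gmt"))
    rows <- list()
    for (pop in pops) {
      scan <- read_results(p("scan_", pop, ".tsv"))
      sig <- scan[scan$q < config$q_threshold, , drop = FALSE]
      if (nrow(sig) == 0) next
      lo <- snp_log_odds(sig)
      gm_map <- map_snps_to_genes(sig, genes)$map
      gsea <- read_results(p("gsea_", pop, ".tsv"))
      top_sets <- gsea$set_name[gsea$q < 0.25]
      for (sn in top_sets) {
        sel_genes <- sets[[sn]]
        sel_vars <- gm_map$variant[gm_map$gene %in% sel_genes]
        sel <- variant_id(lo) %in% sel_vars
        if (!any(sel)) next
        sub <- lo[sel, , drop = FALSE]
        sub$pathway <- sn
        sub$population <- pop
        rows[[length(rows) + 1L]] <-
          sub[c("chrom", "pos", "ref", "alt", "log_or", "variance",
                "pathway", "population")]
      }
    }
    if (length(rows) > 0) {
      snp_tab <- do.call(rbind, rows)
      res <- pathway_meta(snp_tab, moderator = config$meta_moderator)
    } else {
      res <- data.frame(pathway = character(), population = character(),
                        combined_log_or = numeric(), se = numeric(),
                        ci95_low = numeric(), ci95_high = numeric(),
                        n_snps = integer())
    }
    write_results(res, p("pathway_meta.tsv"), meta)
    record_stage("meta", FALSE)
  }

  ## ---- eqtl ----
  if (stage_done("eqtl")) {
    stage_log("eqtl", "outputs up to date, skipped")
    record_stage("eqtl", TRUE)
  } else {
    stage_log("eqtl", "per-group eQTL scans and classification")
    expr_df <- read_results(p("expression.tsv"))
    expr <- as.matrix(expr_df[-1])
    rownames(expr) <- expr_df$gene
    covars <- read_results(p("covariates.tsv"))
    expr_pops <- pops[seq_len(min(2, length(pops)))]
    gms <- lapply(expr_pops, load_gm)
    joint_dosage <- do.call(rbind, lapply(gms, function(g) g$dosage))
    joint <- genotype_matrix(joint_dosage, gms[[1]]$variants,
                             do.call(rbind,
                                     lapply(gms, function(g) g$sample_meta)))
    ecfg <- config$eqtl
    if (length(expr_pops) >= 2) {
      scans <- lapply(expr_pops, function(popx)
        scan_eqtl(expr, joint, genes = genes, cis_window = ecfg$cis_window,
                  covariates = covars, group = popx, maf = ecfg$maf))
      cls <- classify_ancestry_specific(scans[[1]], scans[[2]],
                                        q_sig = ecfg$q_sig,
                                        p_null = ecfg$p_null)
    } else {
      scan1 <- scan_eqtl(expr, joint, genes = genes,
                         cis_window = ecfg$cis_window, covariates = covars,
                         maf = ecfg$maf)
      cls <- scan1
    }
    write_results(cls, p("eqtl_classified.tsv"), meta)
    record_stage("eqtl", FALSE)
  }

  stage_log("pipeline", "complete; manifest at ", manifest_path)
  invisible(manifest)
}
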