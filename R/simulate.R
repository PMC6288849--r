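#' Simulation configuration for synthetic admixed cohorts
#'
#' Defines the generative model used throughout the test suite: K ancestral
#' sources whose per-SNP allele frequencies diverge from a shared base
#' frequency under a Balding-Nichols (Beta) model with divergence `fst`;
#' admixed individuals whose ancestry proportions are Dirichlet-distributed;
#' genotypes drawn haplotype by haplotype (source ~ Categorical(q), allele ~
#' Bernoulli(source frequency)); and optional post-admixture frequency shifts
#' at designated "enriched" SNPs.
#'
#' Defaults reflect a three-way admixed cohort of the kind formed by
#' African/European/Native American gene flow: `fst = 0.1` per source
#' (continental-scale divergence), Dirichlet mean (0.3, 0.5, 0.2) with
#' concentration 10 (per-individual ancestry s.d. about 0.14), and a 5%
#' floor on the ancestral base minor-allele frequency.
#'
#' @param n_snps number of SNPs M.
#' @param n_individuals diploid individuals N in the admixed cohort.
#' @param n_sources number of ancestral sources K.
#' @param fst Balding-Nichols divergence per source, each in (0, 1); recycled
#'   to length K.
#' @param dirichlet_alpha K-vector of Dirichlet parameters for individual
#'   admixture proportions.
#' @param maf_floor ancestral base frequencies are drawn Uniform(maf_floor,
#'   1 - maf_floor).
#' @param source_labels labels for the K sources.
#' @param population label for the simulated admixed cohort.
#' @param seed master RNG seed; per-stage seeds are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps, n_individuals, n_sources = 3L,
                       fst = 0.1, dirichlet_alpha = c(3, 5, 2),
                       maf_floor = 0.05,
                       source_labels = c("AFR", "EUR", "NAT"),
                       population = "ADM", seed = 1L) {
  K <- as.integer(n_sources)
  fst <- rep_len(fst, K)
  if (any(fst <= 0 | fst >= 1)) stop("fst values must lie in (0, 1)")
  if (length(dirichlet_alpha) != K) stop("dirichlet_alpha must have length K")
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (length(source_labels) != K) {
    if (K <= 3 && identical(source_labels, c("AFR", "EUR", "NAT")))
      source_labels <- source_labels[seq_len(K)]
    else stop("source_labels must have length K")
  }
  if (maf_floor <= 0 || maf_floor >= 0.5) stop("maf_floor must be in (0, 0.5)")
  structure(list(n_snps = as.integer(n_snps),
                 n_individuals = as.integer(n_individuals),
                 n_sources = K, fst = fst,
                 dirichlet_alpha = as.numeric(dirichlet_alpha),
                 maf_floor = maf_floor, source_labels = source_labels,
                 population = population, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate ancestral source allele frequencies
#'
#' For each SNP a base frequency p ~ Uniform(maf_floor, 1 - maf_floor) is
#' drawn, then each source k gets a frequency from
#' Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k) — the Balding-Nichols model, whose
#' mean is p and whose variance is F_k p (1-p).  Frequencies are clamped to
#' \[1e-6, 1-1e-6\].  `fst` values below 1e-12 degenerate to the base
#' frequency exactly.
#'
#' @param cfg [sim_config()].
#' @return A `frequency_panel` with attribute `base_freq` (the vector p).
#' @export
simulate_ancestral_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "frequencies"))
  M <- cfg$n_snps
  p <- runif(M, cfg$maf_floor, 1 - cfg$maf_floor)
  freqs <- matrix(NA_real_, M, cfg$n_sources,
                  dimnames = list(NULL, cfg$source_labels))
  for (k in seq_len(cfg$n_sources)) {
    Fk <- cfg$fst[k]
    if (Fk < 1e-12) {
      freqs[, k] <- p
    } else {
      lambda <- (1 - Fk) / Fk
      freqs[, k] <- rbeta(M, p * lambda, (1 - p) * lambda)
    }
  }
  freqs <- clamp(freqs, 1e-6, 1 - 1e-6)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  panel <- data.frame(chrom = "1", pos = seq_len(M) * 150L,
                      ref = ref, alt = unname(alt),
                      stringsAsFactors = FALSE)
  for (k in seq_len(cfg$n_sources)) panel[[cfg$source_labels[k]]] <- freqs[, k]
  panel <- frequency_panel(panel)
  attr(panel, "base_freq") <- p
  panel
}

# internal: Dirichlet draws via normalised gammas, rows sum to 1
rdirichlet_rows <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Simulate an admixed cohort from a frequency panel
#'
#' Each individual i gets ancestry proportions q_i ~ Dirichlet(alpha).  Each
#' of the individual's 2M haplotype alleles is drawn by first sampling its
#' source from Categorical(q_i), then the allele from Bernoulli(f_source).
#' The cohort's marginal alternate-allele frequency at SNP j therefore
#' converges to sum_k mean(q_k) f_kj.
#'
#' @param panel `frequency_panel` with the cfg's K sources.
#' @param cfg [sim_config()].
#' @return list: `gm` ([genotype_matrix()] with population and sex metadata),
#'   `profiles` (individual-level ancestry-profile table, [read_profiles()]
#'   format), `q` (N x K matrix of true proportions).
#' @export
simulate_admixed_genotypes <- function(panel, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  src <- cfg$source_labels
  if (!all(src %in% panel_sources(panel)))
    stop("panel lacks source(s): ",
         paste(setdiff(src, panel_sources(panel)), collapse = ", "))
  set.seed(stage_seed(cfg$seed, "genotypes"))
  N <- cfg$n_individuals
  M <- nrow(panel)
  K <- cfg$n_sources
  q <- rdirichlet_rows(N, cfg$dirichlet_alpha)
  colnames(q) <- src
  fmat <- t(as.matrix(panel[src]))          # K x M

  # 2N haplotypes x M SNPs; per-haplotype source via the individual's
  # cumulative q thresholds (column-recycled against the uniform draws)
  qh <- q[rep(seq_len(N), each = 2L), , drop = FALSE]
  cum <- t(apply(qh, 1, cumsum))
  u <- matrix(runif(2L * N * M), nrow = 2L * N)
  source_idx <- matrix(1L, nrow = 2L * N, ncol = M)
  for (k in seq_len(K - 1L)) source_idx <- source_idx + (u > cum[, k])
  pall <- fmat[cbind(as.vector(source_idx),
                     rep(seq_len(M), each = 2L * N))]
  hap <- matrix(as.integer(runif(2L * N * M) < pall), nrow = 2L * N)
  dosage <- hap[seq(1L, 2L * N, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * N, by = 2L), , drop = FALSE]

  ids <- sprintf("%s_%04d", cfg$population, seq_len(N))
  rownames(dosage) <- ids
  meta <- data.frame(sample = ids, population = cfg$population,
                     sex = sample(c("M", "F"), N, replace = TRUE),
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, panel[c("chrom", "pos", "ref", "alt")], meta)
  profiles <- data.frame(unit = ids, level = "individual",
                         stringsAsFactors = FALSE)
  for (k in seq_len(K)) profiles[[src[k]]] <- q[, k]
  list(gm = gm, profiles = profiles, q = q)
}

#' Inject post-admixture frequency shifts at designated SNPs
#'
#' For each entry of `spec`, the cohort's genotypes at that SNP are redrawn
#' as Binomial(2, f_exp + delta), where f_exp is the ancestry-expected
#' frequency (population-mean proportions times panel frequencies).  This
#' reproduces, as a marginal frequency shift, the signature that
#' post-admixture selection on an introgressed allele leaves at a single SNP.
#' All other SNPs are untouched.
#'
#' @param gm cohort [genotype_matrix()].
#' @param panel `frequency_panel` used to build the cohort.
#' @param profiles individual-level profile table for the cohort.
#' @param spec data.frame with columns `snp_index`, `donor` (source label),
#'   `delta` (shift of the alternate-allele frequency).
#' @param seed RNG seed for the resampling stage (defaults derived from 1).
#' @return list: `gm` (modified matrix), `truth` (TruthTable data.frame:
#'   `snp_index`, `variant`, `donor`, `f_exp`, `f_target`, `delta`,
#'   `f_realized`).
#' @export
inject_enrichment <- function(gm, panel, profiles, spec, seed = 1L) {
  spec <- as.data.frame(spec)
  src <- panel_sources(panel)
  truth_cols <- c("snp_index", "variant", "donor", "f_exp", "f_target",
                  "delta", "f_realized")
  if (nrow(spec) == 0) {
    truth <- as.data.frame(setNames(rep(list(logical(0)), length(truth_cols)),
                                    truth_cols))
    return(list(gm = gm, truth = truth))
  }
  stopifnot(all(c("snp_index", "donor", "delta") %in% names(spec)))
  if (any(spec$snp_index < 1 | spec$snp_index > nrow(panel)))
    stop("snp_index outside the panel")
  if (!all(spec$donor %in% src)) stop("unknown donor source label(s)")
  qbar <- colMeans(as.matrix(profiles[src]))
  qbar <- qbar / sum(qbar)
  f_exp <- as.matrix(panel[src])[spec$snp_index, , drop = FALSE] %*% qbar
  f_target <- as.numeric(f_exp) + spec$delta
  bad <- f_target < 0 | f_target > 1
  if (any(bad))
    stop("infeasible shift for snp_index: ",
         paste(spec$snp_index[bad], collapse = ", "))
  set.seed(stage_seed(seed, "injection"))
  N <- nrow(gm$dosage)
  for (r in seq_len(nrow(spec))) {
    gm$dosage[, spec$snp_index[r]] <- rbinom(N, 2L, f_target[r])
  }
  f_real <- colMeans(gm$dosage[, spec$snp_index, drop = FALSE]) / 2
  truth <- data.frame(snp_index = spec$snp_index,
                      variant = variant_id(gm$variants)[spec$snp_index],
                      donor = spec$donor, f_exp = as.numeric(f_exp),
                      f_target = f_target, delta = spec$delta,
                      f_realized = as.numeric(f_real),
                      stringsAsFactors = FALSE)
  list(gm = gm, truth = truth)
}

#' Choose enrichment candidates with a donor-frequency margin
#'
#' Selects SNPs at which one source's alternate-allele frequency leads every
#' other source by at least `margin`, and at which shifting the expected
#' frequency by `delta` keeps it between the expectation and the donor's own
#' frequency (so the shifted cohort moves toward the donor, as adaptive
#' introgression of a donor allele would).
#'
#' @param panel `frequency_panel`.
#' @param profiles individual-level profile table (for the expected
#'   frequency).
#' @param n number of SNPs to draw.
#' @param delta frequency shift that will be injected (positive).
#' @param margin minimum lead of the donor frequency over all other sources.
#' @return data.frame usable as the `spec` of [inject_enrichment()].
#' @export
pick_enrichment_candidates <- function(panel, profiles, n, delta = 0.2,
                                       margin = 0.3) {
  src <- panel_sources(panel)
  fmat <- as.matrix(panel[src])
  qbar <- colMeans(as.matrix(profiles[src]))
  qbar <- qbar / sum(qbar)
  f_exp <- as.numeric(fmat %*% qbar)
  donor_idx <- max.col(fmat, ties.method = "first")
  lead <- fmat[cbind(seq_len(nrow(fmat)), donor_idx)] -
    apply(fmat, 1, function(x) max(x[-which.max(x)]))
  f_donor <- fmat[cbind(seq_len(nrow(fmat)), donor_idx)]
  ok <- lead >= margin & (f_exp + delta) <= f_donor & (f_exp + delta) <= 1
  if (sum(ok) < n)
    stop("only ", sum(ok), " candidate SNPs satisfy the margin; need ", n)
  pick <- sample(which(ok), n)
  data.frame(snp_index = pick, donor = src[donor_idx[pick]], delta = delta,
             stringsAsFactors = FALSE)
}

#' Simulate expression traits with group-specific genotype effects
#'
#' For each configured (gene, SNP) pair, expression is
#' `y = b0 + beta_group * dosage + sex_effect * I(sex == "F") + e`,
#' `e ~ Normal(0, sd)`, where `beta_group` depends on the sample's group
#' label.  Group-specific betas provide the ground truth for
#' ancestry-specific eQTL classification.  Additional pure-noise genes can be
#' appended as nulls.
#'
#' @param gm cohort [genotype_matrix()] (sex taken from its metadata).
#' @param effects data.frame with columns `gene`, `snp_index`, `group`,
#'   `beta` (long format: one row per gene x group).
#' @param groups character vector of group labels per sample; defaults to
#'   the cohort's population label.
#' @param intercept,sex_effect,sd scalar model constants.
#' @param n_null_genes extra genes with no genotype effect.
#' @param seed RNG seed for this stage.
#' @return list: `expr` (genes x samples matrix), `covariates` (data.frame
#'   `sample`, `sex`, `group`), `effects` (echo of the design).
#' @export
simulate_expression <- function(gm, effects, groups = NULL, intercept = 0,
                                sex_effect = 0, sd = 0.5, n_null_genes = 0L,
                                seed = 1L) {
  effects <- as.data.frame(effects)
  stopifnot(all(c("gene", "snp_index", "group", "beta") %in% names(effects)))
  if (any(effects$snp_index < 1 | effects$snp_index > ncol(gm$dosage)))
    stop("effects reference SNP index absent from the genotype matrix")
  N <- nrow(gm$dosage)
  if (is.null(groups)) groups <- gm$sample_meta$population
  if (length(groups) != N) stop("groups must have one label per sample")
  if (!all(effects$group %in% unique(groups)))
    stop("effects reference group label(s) absent from the cohort")
  sex <- gm$sample_meta$sex
  if (is.null(sex)) sex <- rep("M", N)
  set.seed(stage_seed(seed, "expression"))
  genes <- unique(effects$gene)
  expr <- matrix(NA_real_, nrow = length(genes) + n_null_genes, ncol = N,
                 dimnames = list(c(genes, if (n_null_genes > 0)
                   sprintf("NULLG%03d", seq_len(n_null_genes))),
                   rownames(gm$dosage)))
  for (g in genes) {
    rows <- effects[effects$gene == g, , drop = FALSE]
    snp <- rows$snp_index[1]
    if (length(unique(rows$snp_index)) > 1)
      stop("gene ", g, " mapped to several SNPs in effects")
    beta <- setNames(rows$beta, rows$group)[groups]
    beta[is.na(beta)] <- 0
    expr[g, ] <- intercept + beta * gm$dosage[, snp] +
      sex_effect * (sex == "F") + rnorm(N, 0, sd)
  }
  if (n_null_genes > 0) {
    for (i in seq_len(n_null_genes)) {
      expr[length(genes) + i, ] <- intercept + rnorm(N, 0, sd)
    }
  }
  covariates <- data.frame(sample = rownames(gm$dosage), sex = sex,
                           group = groups, stringsAsFactors = FALSE)
  list(expr = expr, covariates = covariates, effects = effects)
}

#' Simulate gene models tiling the synthetic chromosome
#'
#' Places `n_genes` non-overlapping gene bodies of equal span across the
#' positions covered by the panel, so that a predictable fraction of SNPs
#' falls inside gene bodies.
#'
#' @param panel `frequency_panel` (defines the position range).
#' @param n_genes number of genes.
#' @param coverage fraction of the chromosome covered by gene bodies.
#' @return gene-model data.frame ([read_bed()] format).
#' @export
simulate_gene_models <- function(panel, n_genes = 100L, coverage = 0.5) {
  span <- max(panel$pos)
  slot <- floor(span / n_genes)
  width <- max(1L, floor(slot * coverage))
  start <- (seq_len(n_genes) - 1L) * slot + 1L
  data.frame(name = sprintf("GENE%04d", seq_len(n_genes)),
             chrom = panel$chrom[1], start = start,
             end = start + width - 1L, strand = "+",
             stringsAsFactors = FALSE)
}

#' Simulate gene-set collections over a gene universe
#'
#' Draws random sets; optionally biases a subset of them toward a supplied
#' pool of "signal" genes so that overrepresentation is detectable by
#' construction.
#'
#' @param genes gene-name universe.
#' @param n_sets number of sets.
#' @param set_size size range, inclusive.
#' @param signal_genes genes to overrepresent in the first
#'   `n_signal_sets` sets.
#' @param n_signal_sets how many sets are signal-biased.
#' @param signal_fraction fraction of a signal set drawn from `signal_genes`.
#' @param seed RNG seed.
#' @return named list of character vectors with a `category` attribute.
#' @export
simulate_gene_sets <- function(genes, n_sets = 20L, set_size = c(10L, 40L),
                               signal_genes = character(),
                               n_signal_sets = 0L, signal_fraction = 0.5,
                               seed = 1L) {
  set.seed(stage_seed(seed, "annotation"))
  cats <- c("disease", "metabolism", "immune", "other")
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    size <- sample(seq(set_size[1], set_size[2]), 1L)
    if (i <= n_signal_sets && length(signal_genes) > 0) {
      n_sig <- min(length(signal_genes), max(1L, round(size * signal_fraction)))
      members <- c(sample(signal_genes, n_sig),
                   sample(setdiff(genes, signal_genes), size - n_sig))
    } else {
      members <- sample(genes, size)
    }
    sets[[i]] <- unique(members)
  }
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  attr(sets, "category") <- setNames(sample(cats, n_sets, replace = TRUE),
                                     names(sets))
  sets
}
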