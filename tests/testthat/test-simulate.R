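test_that("Balding-Nichols source frequencies have the stated moments", {
  cfg <- sim_config(n_snps = 50000, n_individuals = 10, fst = 0.1, seed = 101)
  panel <- simulate_ancestral_frequencies(cfg)
  p <- attr(panel, "base_freq")
  f <- as.matrix(panel[c("AFR", "EUR", "NAT")])
  # mean across sources tracks the base frequency
  expect_lt(abs(mean(rowMeans(f) - p)), 0.002)
  # between-source variance ~ F * p * (1 - p)
  ratio <- apply(f, 1, var) / (p * (1 - p))
  expect_lt(abs(mean(ratio) - 0.1), 0.005)
  expect_true(all(f >= 1e-6 & f <= 1 - 1e-6))
})

test_that("vanishing divergence degenerates to the base frequency", {
  cfg <- sim_config(n_snps = 200, n_individuals = 10, fst = 1e-13, seed = 5)
  panel <- simulate_ancestral_frequencies(cfg)
  p <- attr(panel, "base_freq")
  for (s in panel_sources(panel)) expect_equal(panel[[s]], p)
})

test_that("a fixed seed reproduces every simulation stage exactly", {
  cfg <- sim_config(n_snps = 500, n_individuals = 40, seed = 77)
  p1 <- simulate_ancestral_frequencies(cfg)
  p2 <- simulate_ancestral_frequencies(cfg)
  expect_identical(p1, p2)
  s1 <- simulate_admixed_genotypes(p1, cfg)
  s2 <- simulate_admixed_genotypes(p1, cfg)
  expect_identical(s1$gm$dosage, s2$gm$dosage)
  expect_identical(s1$q, s2$q)
})

test_that("one-hot admixture reproduces the single source's frequencies", {
  cfg <- sim_config(n_snps = 2000, n_individuals = 300,
                    dirichlet_alpha = c(1e6, 1e-6, 1e-6), seed = 13)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)
  expect_true(all(abs(sim$q[, 1] - 1) < 1e-3))
  f_hat <- allele_frequencies(sim$gm)$freq
  # binomial error sqrt(f(1-f)/2N) ~ 0.02; mean abs deviation well inside
  expect_lt(mean(abs(f_hat - panel$AFR)), 0.02)
})

test_that("cohort frequencies converge to the ancestry-weighted panel mean", {
  cfg <- sim_config(n_snps = 5000, n_individuals = 500,
                    dirichlet_alpha = c(2, 5, 3), seed = 29)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)
  qbar <- colMeans(sim$q)
  f_exp <- as.numeric(as.matrix(panel[names(qbar)]) %*% qbar)
  f_hat <- allele_frequencies(sim$gm)$freq
  slope <- coef(lm(f_hat ~ f_exp))[2]
  expect_lt(abs(slope - 1), 0.01)
})

test_that("identical source frequencies make the cohort independent of q", {
  f <- runif(1000, 0.1, 0.9)
  panel <- make_panel(cbind(f, f, f))
  cfg_a <- sim_config(n_snps = 1000, n_individuals = 200,
                      dirichlet_alpha = c(10, 1, 1), seed = 3)
  cfg_b <- sim_config(n_snps = 1000, n_individuals = 200,
                      dirichlet_alpha = c(1, 1, 10), seed = 4)
  fa <- allele_frequencies(simulate_admixed_genotypes(panel, cfg_a)$gm)$freq
  fb <- allele_frequencies(simulate_admixed_genotypes(panel, cfg_b)$gm)$freq
  expect_lt(mean(abs(fa - f)), 0.03)
  expect_lt(mean(abs(fb - f)), 0.03)
})

test_that("enrichment injection shifts only the targeted SNPs", {
  cfg <- sim_config(n_snps = 2000, n_individuals = 200, seed = 55)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)

  # no-op injection
  empty <- inject_enrichment(sim$gm, panel, sim$profiles,
                             data.frame(snp_index = integer(),
                                        donor = character(),
                                        delta = numeric()))
  expect_identical(empty$gm$dosage, sim$gm$dosage)
  expect_equal(nrow(empty$truth), 0L)

  spec <- pick_enrichment_candidates(panel, sim$profiles, n = 25,
                                     delta = 0.2, margin = 0.3)
  inj <- inject_enrichment(sim$gm, panel, sim$profiles, spec, seed = 55)
  # realized frequency near the target, within binomial error
  tol <- 4 * sqrt(inj$truth$f_target * (1 - inj$truth$f_target) / 400)
  expect_true(all(abs(inj$truth$f_realized - inj$truth$f_target) <= tol))
  # donors respect the margin by construction
  fmat <- as.matrix(panel[panel_sources(panel)])[spec$snp_index, ]
  lead <- vapply(seq_len(nrow(fmat)), function(i) {
    d <- match(spec$donor[i], panel_sources(panel))
    fmat[i, d] - max(fmat[i, -d])
  }, 1)
  expect_true(all(lead >= 0.3))
  # conservation: untouched columns identical
  untouched <- setdiff(seq_len(2000), spec$snp_index)
  expect_identical(inj$gm$dosage[, untouched], sim$gm$dosage[, untouched])

  # null injection keeps the frequency in expectation
  spec0 <- data.frame(snp_index = 42L, donor = "AFR", delta = 0)
  inj0 <- inject_enrichment(sim$gm, panel, sim$profiles, spec0, seed = 9)
  expect_equal(nrow(inj0$truth), 1L)
  tol0 <- 4 * sqrt(inj0$truth$f_exp * (1 - inj0$truth$f_exp) / 400)
  expect_lt(abs(inj0$truth$f_realized - inj0$truth$f_exp), tol0)

  # infeasible shifts are reported with the offending index
  expect_error(inject_enrichment(sim$gm, panel, sim$profiles,
                                 data.frame(snp_index = 1L, donor = "AFR",
                                            delta = 2)),
               "infeasible.*1")
})

test_that("expression simulation: noiseless limit is exact, nulls calibrated", {
  cfg <- sim_config(n_snps = 50, n_individuals = 150, seed = 7)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)
  eff <- data.frame(gene = "G1", snp_index = 1L, group = "ADM", beta = 2)
  ex0 <- simulate_expression(sim$gm, eff, sd = 0, sex_effect = 0, seed = 1)
  fit <- fit_eqtl(ex0$expr["G1", ], sim$gm$dosage[, 1])
  expect_equal(fit$beta, 2, tolerance = 1e-10)

  # beta = 0: genotype-independent expression, type-I error near nominal
  ex_null <- simulate_expression(sim$gm,
                                 data.frame(gene = "G1", snp_index = 1L,
                                            group = "ADM", beta = 0),
                                 sd = 0.5, n_null_genes = 299, seed = 99)
  pvals <- apply(ex_null$expr, 1, function(y)
    fit_eqtl(y, sim$gm$dosage[, 2])$p)
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)

  expect_error(simulate_expression(sim$gm,
                                   data.frame(gene = "G", snp_index = 999L,
                                              group = "ADM", beta = 1)),
               "absent")
})

test_that("scan p-values are uniform under the simulator's null", {
  cfg <- sim_config(n_snps = 20000, n_individuals = 100, seed = 808)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)
  prof <- profile_vector(population_profile(sim$profiles,
                                            population = "ADM"), "ADM")
  scan <- run_enrichment_scan(sim$gm, panel, prof)
  ks <- suppressWarnings(ks.test(scan$records$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
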