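test_that("expected frequency is the ancestry-weighted source average", {
  panel <- make_panel(rbind(c(0.4, 0.4, 0.4), c(0.1, 0.5, 0.9)))
  anyprof <- c(AFR = 0.2, EUR = 0.3, NAT = 0.5)
  fe <- expected_frequency(panel, anyprof)
  expect_equal(fe[1], 0.4)                       # symmetric sources
  expect_equal(fe[2], 0.62)                      # 0.02 + 0.15 + 0.45
  onehot <- c(AFR = 1, EUR = 0, NAT = 0)
  expect_equal(expected_frequency(panel, onehot), panel$AFR)
  expect_error(expected_frequency(panel, c(X = 0.5, Y = 0.5)), "labels")
  expect_error(expected_frequency(panel, c(AFR = 0.5, EUR = 0.4, NAT = 0.4)),
               "sum to 1")
})

test_that("expected frequency is linear in the profile", {
  set.seed(41)
  panel <- make_panel(matrix(runif(60), 20))
  for (i in 1:20) {
    a <- c(AFR = 0.1, EUR = 0.2, NAT = 0.7)
    b <- c(AFR = 0.5, EUR = 0.3, NAT = 0.2)
    lam <- runif(1)
    mix <- lam * a + (1 - lam) * b
    expect_equal(expected_frequency(panel, mix),
                 lam * expected_frequency(panel, a) +
                   (1 - lam) * expected_frequency(panel, b),
                 tolerance = 1e-12)
  }
})

test_that("the chi-square statistic matches hand-computed counts", {
  et <- enrichment_test(0.6, 0.5, 200)
  expect_identical(et$obs_alt, 120)
  expect_identical(et$obs_ref, 80)
  expect_equal(et$exp_alt, 100)
  expect_equal(et$chi2, 8.0)                     # 400/100 + 400/100
  # independent chi2(1) survival function: 2 * Phi(-sqrt(x))
  expect_equal(et$p, 2 * pnorm(-sqrt(8)), tolerance = 1e-10)

  # null identity
  et0 <- enrichment_test(0.37, 0.37, 142)
  expect_equal(et0$chi2, 0)
  expect_equal(et0$p, 1)

  # doubling the chromosome count doubles the statistic
  e1 <- enrichment_test(0.6, 0.5, 200)
  e2 <- enrichment_test(0.6, 0.5, 400)
  expect_equal(e2$chi2, 2 * e1$chi2)

  # exact counts path overrides rounding
  ec <- enrichment_test(119 / 200, 0.5, 200, obs_alt = 119)
  expect_identical(ec$obs_alt, 119)

  expect_error(enrichment_test(1.2, 0.5, 100), "frequencies")
  expect_error(enrichment_test(0.5, 0.5, 0), "n_chrom")
})

test_that("swapping ref and alt labels leaves chi2 and p unchanged", {
  set.seed(51)
  for (i in 1:200) {
    n <- 2 * sample(30:300, 1)
    k <- sample(0:n, 1)
    fe <- runif(1)
    a <- enrichment_test(k / n, fe, n, obs_alt = k)
    b <- enrichment_test((n - k) / n, 1 - fe, n, obs_alt = n - k)
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("BH q-values match the brute-force step-up on random vectors", {
  expect_equal(fdr_adjust(0.03), 0.03)           # m = 1
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.7)), "\\[0, 1\\]")

  set.seed(61)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("ancestry attribution balances closeness and separation", {
  sc <- attribute_ancestry(0.8, c(AFR = 0.9, EUR = 0.1, NAT = 0.2))
  expect_equal(unname(sc$scores[1, ]), c(0.65, -1.15, -0.90),
               tolerance = 1e-12)
  expect_equal(sc$enriched_ancestry, "AFR")
  expect_false(sc$tie)
  expect_false(sc$generalized)

  # equal source frequencies tie, broken by column order and flagged
  tie <- attribute_ancestry(0.5, c(AFR = 0.3, EUR = 0.3, NAT = 0.3))
  expect_true(tie$tie)
  expect_equal(tie$enriched_ancestry, "AFR")
  expect_equal(unname(tie$scores[1, ]), rep(-0.2, 3))

  # observed sitting exactly on the max-margin source maximises its score
  con <- attribute_ancestry(0.9, c(AFR = 0.9, EUR = 0.2, NAT = 0.3))
  expect_equal(con$enriched_ancestry, "AFR")

  # K != 3 uses the generalized mean-pairwise form and flags it
  g2 <- attribute_ancestry(0.7, c(A = 0.8, B = 0.2))
  expect_true(g2$generalized)
  expect_equal(unname(g2$scores[1, ]), c(0.6 - 0.1, -0.6 - 0.5))
  expect_error(attribute_ancestry(0.5, c(A = 0.5)), "at least 2")
})

test_that("the scan joins cohort and panel, annotates and thresholds", {
  set.seed(71)
  panel <- make_panel(matrix(runif(90, 0.2, 0.8), 30))
  prof <- c(AFR = 0.3, EUR = 0.5, NAT = 0.2)
  fe <- expected_frequency(panel, prof)
  d <- sapply(fe, function(f) rbinom(50, 2, f))
  gm <- make_gm(d)
  scan <- run_enrichment_scan(gm, panel, prof)
  r <- scan$records
  expect_equal(nrow(r), 30)
  expect_equal(r$obs_ref + r$obs_alt, r$n_chrom)
  expect_equal(r$exp_ref + r$exp_alt, r$n_chrom, tolerance = 1e-9)
  expect_true(all(r$q >= 0 & r$q <= 1))
  expect_equal(r$enriched_allele, ifelse(r$obs_alt > r$exp_alt, "alt", "ref"))

  # threshold boundary: q_threshold = 0 selects nothing
  scan0 <- run_enrichment_scan(gm, panel, prof, q_threshold = 0)
  expect_equal(nrow(scan0$significant), 0L)

  # disjoint variant keys are a hard error
  panel_off <- make_panel(matrix(runif(90, 0.2, 0.8), 30),
                          pos = seq_len(30) * 100L + 1L)
  expect_error(run_enrichment_scan(gm, panel_off, prof), "no SNPs shared")

  # frequency-table input mode agrees with the genotype mode
  af <- allele_frequencies(gm)
  scan_f <- run_enrichment_scan(af, panel, prof)
  expect_equal(scan_f$records$chi2, scan$records$chi2)
})

test_that("a small null scan is calibrated and injected signals are found", {
  cfg <- sim_config(n_snps = 5000, n_individuals = 100, seed = 909)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)
  prof <- profile_vector(population_profile(sim$profiles,
                                            population = "ADM"), "ADM")
  scan <- run_enrichment_scan(sim$gm, panel, prof)
  expect_gt(mean(scan$records$p < 0.05), 0.03)
  expect_lt(mean(scan$records$p < 0.05), 0.07)

  spec <- pick_enrichment_candidates(panel, sim$profiles, n = 30,
                                     delta = 0.2, margin = 0.3)
  inj <- inject_enrichment(sim$gm, panel, sim$profiles, spec, seed = 909)
  scan2 <- run_enrichment_scan(inj$gm, panel, prof)
  sig_ids <- variant_id(scan2$significant)
  recall <- mean(inj$truth$variant %in% sig_ids)
  expect_gte(recall, 0.8)
  rec <- scan2$records[match(inj$truth$variant, variant_id(scan2$records)), ]
  hit <- rec$enriched_ancestry == inj$truth$donor
  expect_gte(mean(hit[inj$truth$variant %in% sig_ids]), 0.8)
})
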