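test_that("MAF filter folds frequencies and counts survivors", {
  # 10 SNPs; columns 1-3 below the 5% floor (freq 0.04, 0.96, 0.00)
  n <- 50
  freqs <- c(0.04, 0.96, 0.0, 0.3, 0.5, 0.7, 0.2, 0.4, 0.6, 0.25)
  d <- sapply(freqs, function(f) {
    k <- round(2 * n * f)
    dos <- c(rep(2L, k %/% 2), rep(1L, k %% 2))
    c(dos, rep(0L, n - length(dos)))
  })
  gm <- make_gm(d)
  f_check <- allele_frequencies(gm)$freq
  expect_equal(f_check, freqs)
  kept <- maf_filter(gm, floor = 0.05)
  expect_equal(ncol(kept$dosage), 7L)
  expect_true(all(pmin(allele_frequencies(kept)$freq,
                       1 - allele_frequencies(kept)$freq) > 0.05))
})

test_that("the OLS fit matches hand arithmetic and independent oracles", {
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 1.05, 2.0, 0.0, 1.1, 1.9)
  fit <- fit_eqtl(y, g)
  expect_equal(fit$beta, 0.95, tolerance = 1e-12)   # 3.8 / 4

  # noiseless limit
  fit2 <- fit_eqtl(2 * g, g)
  expect_equal(fit2$beta, 2, tolerance = 1e-12)
  expect_lt(fit2$p, 1e-12)

  # shifting y moves only the intercept
  fit3 <- fit_eqtl(y + 5, g)
  expect_equal(fit3$beta, fit$beta, tolerance = 1e-12)
  expect_equal(fit3$t, fit$t, tolerance = 1e-10)
  expect_equal(unname(fit3$coefficients["(Intercept)"]),
               unname(fit$coefficients["(Intercept)"]) + 5,
               tolerance = 1e-10)

  # closed-form two-variable regression on random instances
  set.seed(131)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    gg <- sample(0:2, n, replace = TRUE)
    if (length(unique(gg)) == 1) next
    yy <- rnorm(n, 0.5 * gg)
    f <- fit_eqtl(yy, gg)
    slope <- sum((gg - mean(gg)) * (yy - mean(yy))) / sum((gg - mean(gg))^2)
    expect_equal(f$beta, slope, tolerance = 1e-10)
    o <- ols_oracle(yy, cbind(1, gg))
    expect_equal(f$se, unname(o$se[2]), tolerance = 1e-10)
  }

  # with covariates: agree with stats::lm (QR) including t and p
  set.seed(141)
  for (i in 1:100) {
    n <- 80
    gg <- sample(0:2, n, replace = TRUE)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    popl <- sample(c("P1", "P2", "P3"), n, replace = TRUE)
    yy <- rnorm(n, 0.3 * gg + 0.5 * (sex == "M"))
    f <- fit_eqtl(yy, gg, data.frame(sex = sex, pop = popl))
    lmfit <- summary(lm(yy ~ gg + sex + popl))$coefficients
    expect_equal(f$beta, lmfit["gg", 1], tolerance = 1e-10)
    expect_equal(f$se, lmfit["gg", 2], tolerance = 1e-10)
    expect_equal(f$p, lmfit["gg", 4], tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected with named columns", {
  g <- c(0, 1, 2, 0, 1, 2)
  y <- rnorm(6)
  expect_error(fit_eqtl(y, g, data.frame(dup = g)), "collinear.*dup")
  expect_error(fit_eqtl(y[1:3], g[1:3], data.frame(x = rnorm(3))),
               "fewer observations")
})

test_that("the scan pairs genes with SNPs and adjusts q across all tests", {
  cfg <- sim_config(n_snps = 60, n_individuals = 120, seed = 151)
  panel <- simulate_ancestral_frequencies(cfg)
  sim <- simulate_admixed_genotypes(panel, cfg)
  # two causal genes on well-separated common SNPs (safe from the MAF filter)
  f_cohort <- allele_frequencies(sim$gm)$freq
  common <- which(f_cohort > 0.25 & f_cohort < 0.75)
  causal <- c(common[1], common[length(common)])
  eff <- data.frame(gene = c("GA", "GB"), snp_index = causal,
                    group = "ADM", beta = c(1, 0))
  ex <- simulate_expression(sim$gm, eff, sd = 0.5, seed = 151)
  causal_pos <- panel$pos[causal]
  models <- data.frame(name = c("GA", "GB"), chrom = "1",
                       start = causal_pos - 50L, end = causal_pos + 50L,
                       strand = "+")
  # window 0: only the SNP inside each gene body is paired
  res0 <- scan_eqtl(ex$expr, sim$gm, genes = models, cis_window = 0,
                    covariates = ex$covariates[c("sample", "sex")])
  expect_equal(sort(res0$pos), sort(causal_pos))
  expect_equal(res0$q, fdr_adjust(res0$p))
  ga <- res0[res0$gene == "GA", ]
  expect_lt(abs(ga$beta - 1), 0.3)
  expect_lt(ga$p, 1e-6)

  # wider window: more pairs, q over all of them
  res <- scan_eqtl(ex$expr, sim$gm, genes = models, cis_window = 2000,
                   covariates = ex$covariates[c("sample", "sex")])
  expect_gt(nrow(res), nrow(res0))
  expect_equal(res$q, fdr_adjust(res$p))
  expect_true(all(res$maf > 0.05))

  # sample alignment errors
  expr_bad <- ex$expr
  colnames(expr_bad) <- paste0("zz", seq_len(ncol(expr_bad)))
  expect_error(scan_eqtl(expr_bad, sim$gm, genes = models),
               "no overlapping samples")
  # group restriction below the parameter count errors in the fit
  cov_small <- ex$covariates
  cov_small$group <- c(rep("tiny", 3), rep("ADM", nrow(cov_small) - 3))
  expect_error(scan_eqtl(ex$expr, sim$gm, genes = models, cis_window = 0,
                         covariates = cov_small, group = "tiny"),
               "fewer observations")
})

test_that("ancestry-specific classification follows the declared rules", {
  ra <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   variant = "1:100:A:G", group = "AFR",
                   beta = c(1, 1, 1, 1), p = c(1e-6, 1e-6, 0.5, 0.2),
                   q = c(0.01, 0.01, 0.8, 0.4))
  rb <- data.frame(gene = c("g1", "g2", "g3"),
                   variant = "1:100:A:G", group = "EUR",
                   beta = c(0.1, 1, 1), p = c(0.5, 1e-6, 1e-6),
                   q = c(0.9, 0.01, 0.01))
  cls <- classify_ancestry_specific(ra, rb)
  lab <- setNames(cls$label, cls$gene)
  expect_equal(unname(lab["g1"]), "AFR-specific")   # sig in A, null in B
  expect_equal(unname(lab["g2"]), "shared")         # sig both, same sign
  expect_equal(unname(lab["g3"]), "EUR-specific")
  expect_equal(unname(lab["g4"]), "untestable")     # absent from B

  # opposite signs are not "shared"
  rb2 <- rb
  rb2$beta[2] <- -1
  cls2 <- classify_ancestry_specific(ra, rb2)
  expect_equal(cls2$label[cls2$gene == "g2"], "none")
})

test_that("group-specific effects are classified A-specific in most replicates", {
  set.seed(161)
  n <- 200
  hits <- 0
  reps <- 30
  for (r in 1:reps) {
    gA <- rbinom(n, 2, 0.3)
    gB <- rbinom(n, 2, 0.3)
    yA <- 1 * gA + rnorm(n, 0, 0.5)
    yB <- 0 * gB + rnorm(n, 0, 0.5)
    fa <- fit_eqtl(yA, gA)
    fb <- fit_eqtl(yB, gB)
    ra <- data.frame(gene = "g", variant = "v", group = "A",
                     beta = fa$beta, p = fa$p, q = fa$p)
    rb <- data.frame(gene = "g", variant = "v", group = "B",
                     beta = fb$beta, p = fb$p, q = fb$p)
    if (classify_ancestry_specific(ra, rb)$label == "A-specific")
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("the interaction test is calibrated under equal group effects", {
  set.seed(171)
  reps <- 1000
  n <- 100
  p <- numeric(reps)
  for (r in 1:reps) {
    g <- rbinom(n, 2, 0.4)
    grp <- rep(c("A", "B"), each = n / 2)
    y <- 0.5 * g + rnorm(n, 0, 0.5)
    p[r] <- fit_interaction(y, g, grp)$p_interaction
  }
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})
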