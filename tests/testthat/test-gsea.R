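test_that("SNP-to-gene mapping is 1-based inclusive of both boundaries", {
  models <- data.frame(name = c("G1", "G2"), chrom = "1",
                       start = c(100L, 150L), end = c(200L, 250L),
                       strand = "+")
  snps <- data.frame(chrom = "1", pos = c(100L, 200L, 201L, 175L, 99L, 251L),
                     ref = "A", alt = "G")
  m <- map_snps_to_genes(snps, models)
  hits <- function(pos) sort(m$map$gene[m$map$pos == pos])
  expect_equal(hits(100), "G1")             # pos == start mapped
  expect_equal(hits(200), c("G1", "G2"))    # pos == end mapped; overlap both
  expect_equal(hits(201), "G2")             # one past G1's end: G2 only
  expect_equal(hits(175), c("G1", "G2"))
  expect_length(hits(99), 0)                # before every start
  expect_length(hits(251), 0)               # one past the last end

  expect_setequal(m$genes, c("G1", "G2"))

  other <- data.frame(chrom = "2", pos = 175L, ref = "A", alt = "G")
  expect_equal(nrow(map_snps_to_genes(other, models)$map), 0L)
})

test_that("mapping agrees with a naive double loop on random instances", {
  set.seed(81)
  for (i in 1:20) {
    n_g <- sample(5:30, 1)
    start <- sample(1:5000, n_g)
    models <- data.frame(name = sprintf("g%02d", seq_len(n_g)),
                         chrom = sample(c("1", "2"), n_g, replace = TRUE),
                         start = start,
                         end = start + sample(50:500, n_g, replace = TRUE),
                         strand = "+")
    snps <- data.frame(chrom = sample(c("1", "2"), 200, replace = TRUE),
                       pos = sample(1:6000, 200), ref = "A", alt = "G")
    got <- map_snps_to_genes(snps, models)$map
    want <- map_oracle(snps, models)
    key <- function(df) sort(paste(df$pos, df$gene))
    expect_equal(key(got), key(want))
  }
})

test_that("overlap enrichment uses the hypergeometric upper tail", {
  bg <- sprintf("B%04d", 1:1000)
  set1 <- bg[1:50]
  query <- c(bg[1:5], bg[101:115])            # k = 5, n = 20
  res <- overlap_enrichment(query, list(S1 = set1), bg)
  expect_equal(res$k, 5L)
  expect_equal(res$K, 50L)
  expect_equal(res$n, 20L)
  expect_equal(res$N, 1000L)
  expect_equal(res$p, hyper_tail_oracle(5, 50, 1000, 20), tolerance = 1e-12)
  expect_lt(res$p, 5e-3)                      # ~3e-3 per the worked example
  expect_equal(res$overlap_genes, paste(sort(bg[1:5]), collapse = ","))

  # zero overlap: P(X >= 0) = 1
  res0 <- overlap_enrichment(bg[900:920], list(S1 = set1), bg)
  expect_equal(res0$p, 1)

  # set disjoint from the background is skipped with a warning
  expect_warning(resd <- overlap_enrichment(query,
                                            list(S1 = set1, SX = c("zz")),
                                            bg),
                 "disjoint")
  expect_equal(nrow(resd), 1L)
  expect_error(overlap_enrichment(c(query, "stranger"), list(S1 = set1), bg),
               "outside the background")
  expect_error(overlap_enrichment(query, list(S1 = set1), character(0)),
               "empty")
})

test_that("hypergeometric tails agree with enumeration on small universes", {
  set.seed(91)
  for (i in 1:1000) {
    N <- sample(5:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k_lo <- max(0, n - (N - K))      # feasibility: n - k non-set genes exist
    ks <- k_lo:min(K, n)
    k <- ks[sample.int(length(ks), 1)]
    bg <- sprintf("x%03d", 1:N)
    query <- c(bg[seq_len(k)],
               if (n > k) bg[(K + 1):(K + n - k)] else character(0))
    res <- overlap_enrichment(query, list(S = bg[1:K]), bg)
    expect_equal(res$p, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("gene sharing partitions the union of population lists", {
  same <- list(P1 = c("a", "b"), P2 = c("a", "b"), P3 = c("a", "b"),
               P4 = c("a", "b"))
  gs <- gene_sharing(same)
  expect_equal(gs$shared_by$n_genes, c(0L, 0L, 0L, 2L))

  disjoint <- list(P1 = "a", P2 = "b", P3 = "c")
  gd <- gene_sharing(disjoint)
  expect_equal(gd$shared_by$n_genes, c(3L, 0L, 0L))

  ab <- gene_sharing(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(ab$shared_by$n_genes, c(2L, 1L))
  expect_equal(ab$classes$populations[ab$classes$gene == "g2"], "A,B")

  # partition property on random lists
  set.seed(101)
  rl <- lapply(1:4, function(i) sample(letters, sample(5:20, 1)))
  names(rl) <- paste0("P", 1:4)
  gr <- gene_sharing(rl)
  expect_equal(sum(gr$shared_by$n_genes), gr$n_total)
  expect_equal(gr$n_total, length(unique(unlist(rl))))
  expect_error(gene_sharing(list(A = "x")), ">= 2")
})
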