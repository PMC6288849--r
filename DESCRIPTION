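Package: admixscan
Title: Ancestry-Enrichment Scans for Admixed Population Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects single nucleotide polymorphisms whose allele frequency in
    an admixed population deviates from the expectation implied by the
    population's genetic ancestry profile, attributes each signal to an
    ancestral source population, aggregates signals over genes and curated
    gene sets, summarises pathway-level enrichment by fixed-effect
    meta-analysis of per-SNP log odds ratios, and tests ancestry-specific
    gene-regulatory (eQTL) effects with an additive linear model. Includes a
    supervised maximum-likelihood estimator of genome-wide ancestry
    proportions and a synthetic-cohort generator (Balding-Nichols source
    frequencies, Dirichlet admixture, injected frequency shifts, matched
    expression traits) so the full pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
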