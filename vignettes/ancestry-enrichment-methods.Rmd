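---
title: "Ancestry-enrichment scans on admixed cohorts: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-enrichment scans on admixed cohorts: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The model

An admixed population formed by gene flow among K ancestral sources carries,
at a neutral biallelic SNP, an alternate-allele frequency close to the
ancestry-weighted average of the source frequencies.  Writing `f_s` for the
frequency of the SNP in source `s` and `p_s` for the proportion of the
population's ancestry derived from source `s`,

    f_exp = sum_s f_s * p_s .

A SNP whose observed frequency `f_obs` deviates from `f_exp` more than
sampling noise allows is *ancestry-enriched*: its frequency has moved since
admixture, the signature expected of adaptive introgression (an introgressed
allele rising because it is useful) or of other post-admixture selection.

`admixscan` tests each SNP by converting frequencies to allele counts on the
observed chromosome count `n = 2 * (non-missing samples)` and forming the
one-degree-of-freedom goodness-of-fit statistic

    chi2 = (Obs_ref - Exp_ref)^2 / Exp_ref + (Obs_alt - Exp_alt)^2 / Exp_alt ,

with the p-value from the upper chi-square(1) tail and Benjamini–Hochberg
q-values across all SNPs of one population scan (`q < 0.05` is the default
call threshold).  Each significant SNP is attributed to the source whose
frequency it approaches, via the score

    Anc_s = mean over t != s of (f_s - f_t)  -  | f_obs - f_s | ,

whose argmax balances the source's separation from the other sources against
its closeness to the observed frequency.  Downstream, significant SNPs are
mapped to gene bodies (1-based inclusive containment between transcription
start and stop), gene sets are tested for overrepresentation, per-SNP log
odds ratios

    log OR = ln[ (f_obs_ref / f_exp_ref) / (f_obs_alt / f_exp_alt) ]

are combined per pathway by inverse-variance fixed-effect meta-analysis, and
ancestry-specific regulatory effects are screened with an additive linear
eQTL model.

## Numerical and statistical choices

**Counts, not frequencies, in the chi-square.**  The enrichment statistic is
often written in terms of "frequencies", but a chi-square(1) reference
distribution calibrates only for counts.  `enrichment_test()` therefore
multiplies frequencies by the observed chromosome count; exact integer
counts are used whenever genotypes (rather than a frequency table) are
supplied, and `Obs_alt = round(f_obs * n)` otherwise.

**Clamping.**  The expected frequency is clamped to `[1/n, 1 - 1/n]` before
forming expected counts, so a SNP absent from every contributing source
cannot produce a zero denominator.  A SNP with `f_obs == f_exp` exactly
(including monomorphic-in-both) is assigned `chi2 = 0, p = 1`.

**Far-tail behaviour — a known limitation.**  At `n ≈ 200` chromosomes the
chi-square approximation is accurate in the bulk (the fraction of null SNPs
with `p < 0.05` is 0.049 in the package's own calibration run) but
anti-conservative in the extreme tail for SNPs with skewed frequencies: at
`f_exp = 0.07` and 32/200 alternate alleles the chi-square tail gives
`7.5e-7` where the exact binomial two-sided tail is `2.4e-5`.  Since a BH
call at `q < 0.05` among 20,000 SNPs requires `p ~ 2.5e-6`, a genome-scale
scan of a *null* cohort of this size still produces at least one (false)
call in roughly one replicate in five.  The acceptance suite asserts strict
empirical FDR control and that assertion fails for exactly this reason; the
test is kept red rather than weakened because it documents a real property
of the method: at a few hundred chromosomes, q-values near the calling
threshold inherit the chi-square approximation error and should be read
with that caveat.  Cohorts with larger `n`, or a minimum-expected-count
screen applied by the caller, mitigate it.

**FDR scope.**  q-values are computed within each admixed population
separately (one scan = one population), matching per-population significant
lists; pooling across populations would mix different null scales.
Benjamini–Hochberg is used; `fdr_adjust()` delegates to
`stats::p.adjust(method = "BH")` and the suite verifies it against a
brute-force step-up implementation.

**Attribution for K other than 3.**  The three-source score generalises to
the mean pairwise separation `mean_{t != s}(f_s - f_t)`; results carry a
flag when the generalised form is used.  Exact ties are broken by source
column order and flagged.

**Gene-set statistic.**  Overrepresentation is tested with the one-sided
hypergeometric tail `P(X >= k)` on the overlap between query genes and each
set, restricted to a declared background universe.  The background defaults
to genes overlapping at least one *tested* SNP (configurable to all genes in
the model file): enrichment should be judged against what the scan could
have seen.  A signed-rank test is sometimes named for this step in the
literature, but a paired rank test is not well defined for a 2x2 overlap;
the hypergeometric test has an exact, reproducible null.

**Meta-analysis variance.**  The log OR has no variance attached in its
defining form; the package uses the standard Woolf count-based estimate
`1/Obs_ref + 1/Obs_alt + 1/Exp_ref + 1/Exp_alt`, with the Haldane–Anscombe
correction (add 0.5 to all four counts) when any count is zero.  The default
fixed-effect model has no moderators; a categorical population moderator
(weighted least squares with group means) is available behind
`pathway_meta(moderator = TRUE)`.  95% intervals use the normal quantile
1.96, conventional for fixed-effect summaries.

**eQTL model.**  Ordinary least squares of expression on
`[1, dosage, covariates]` (sex and population labels dummy-coded), complete
cases only, `t = beta/se` on the dosage coefficient with residual degrees of
freedom.  SNPs with minor-allele frequency at or below 5% in the tested
samples are excluded first.  The scan is cis by default (1 Mb around the
gene body; window 0 keeps only SNPs inside the body) because the
genome-wide pair universe is rarely wanted at desk scale; explicit pairs
override it.  The solver is normal equations with a Cholesky factor after a
QR rank check — deliberately a different algorithm from `stats::lm`, which
the test suite uses as an independent oracle.

**Ancestry-specific eQTL rule.**  A pair is called A-specific when
`q_A < 0.05` and `p_B > 0.1` (symmetrically B-specific), shared when
significant in both groups with the same sign of effect, otherwise none;
both thresholds are arguments.  This rule is a declared package convention
— no canonical rule exists — and a pooled genotype-by-group interaction
test (`fit_interaction()`) is provided to corroborate calls.

**Supervised ancestry estimation.**  Genome-wide proportions are estimated
per individual by maximising the binomial likelihood of dosages given fixed
source frequencies over the K-simplex, by EM on allele-origin
responsibilities: initialisation at the simplex centre, stop when the
relative log-likelihood change drops below 1e-7 or after 500 iterations, a
Dirichlet(1 + 1e-6) prior to keep non-identifiable inputs (duplicate
sources, flagged with a warning) well-posed.  Unsupervised estimation is
out of scope: externally computed profiles are accepted through
`read_profiles()` and bypass the estimator.

**Harmonization policy.**  When merging genotype datasets, sites are
intersected on (chrom, pos); identical alleles are kept, swapped ref/alt is
recoded `d -> 2 - d`, complementary alleles are strand-flipped and
re-matched, and strand-ambiguous sites (A/T, C/G) are dropped — their
orientation cannot be decided from the alleles alone, and dropping is
conservative and deterministic.  Frequency matching of ambiguous sites was
considered and rejected: it guesses, and the scan's input frequencies must
not embed guesses.

## The synthetic-data generator

The generator emulates exactly the structure the expectation model assumes:

* **Source frequencies** per SNP follow the Balding–Nichols model: a base
  frequency `p ~ Uniform(0.05, 0.95)` and per-source draws from
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`, mean `p`, variance `F p (1-p)`.  The
  default divergence `F = 0.1` is continental-scale.  The 5% floor keeps
  base frequencies away from the degenerate edges.
* **Admixture** per individual is `q ~ Dirichlet(3, 5, 2)`: mean
  (0.3, 0.5, 0.2), concentration 10, per-component standard deviation about
  0.14 — the within-cohort spread seen in three-way admixed American
  populations.
* **Genotypes** are drawn haplotype by haplotype: source from
  `Categorical(q_i)`, then allele from `Bernoulli(f_source)`; the dosage is
  the sum over the two haplotypes.  Cohort frequencies therefore converge
  to `sum_k mean(q_k) f_k`, which the test suite checks by regression
  (slope 1 within 0.01 at N = 500).
* **Enrichment** is injected as a marginal frequency shift: genotypes at a
  chosen SNP are redrawn as `Binomial(2, f_exp + delta)`.  The scan sees
  only marginal frequencies, so the shift is the sufficient statistic for
  the signal; candidates are restricted to SNPs where one source leads all
  others by a margin (default 0.3) and the shifted frequency moves toward
  that donor, so that attribution has a well-defined truth.
* **Expression** is `y = b0 + beta_group * dosage + gamma * I(sex = F) +
  Normal(0, sd)` with group-specific `beta`, giving ground truth for the
  ancestry-specific eQTL classifier.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium between SNPs (sites
are independent; a real scan's significant SNPs come in LD clusters and are
not independent tests), local-ancestry structure along chromosomes,
genotyping error, multi-generation admixture dynamics, and expression
preprocessing artefacts (inputs are assumed normalized/residualized).
Gene models and gene sets are synthetic tilings and random draws, not real
annotation.

Determinism: every stage derives its RNG stream from the configuration
seed, so identical configurations reproduce byte-identical outputs; the
pipeline runner skips a stage only when its outputs exist under the same
configuration hash and nothing upstream re-ran.

## Problem sizes used by the checks

The package's own calibration and power runs use K = 3, N = 100 diploid
individuals, M = 20,000 SNPs, F = 0.1, and 20 replicates (null and
injected); ancestry recovery uses M = 5,000; eQTL coverage uses 200
replicates at n = 200, beta = 1, sd = 0.5; oracle-agreement checks use 1,000
random instances per statistic.  The analysis drivers under `analysis/` run
the same conditions on two cohorts with contrasting admixture.

## A worked call

```{r example}
panel <- frequency_panel(data.frame(
  chrom = "1", pos = 100L, ref = "A", alt = "G",
  AFR = 0.9, EUR = 0.1, NAT = 0.2))
profile <- c(AFR = 0.2, EUR = 0.5, NAT = 0.3)
f_exp <- expected_frequency(panel, profile)
f_exp
enrichment_test(f_obs = 0.6, f_exp = f_exp, n_chrom = 200)
attribute_ancestry(0.6, c(AFR = 0.9, EUR = 0.1, NAT = 0.2))$enriched_ancestry
```

The SNP sits at 0.6 against an expectation of 0.29 (= 0.2x0.9 + 0.5x0.1 +
0.3x0.2); the chi-square test quantifies the deviation on 200 chromosomes
and the attribution picks the African source, whose 0.9 frequency is both
far above the other sources and closest to the observed value.
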