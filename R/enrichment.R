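#' Ancestry-expected SNP frequency
#'
#' The expected alternate-allele frequency of a SNP in an admixed population
#' is the ancestry-weighted average of its source-population frequencies:
#' `f_exp = sum_s f_s * p_s`, with p the population's ancestry proportions.
#'
#' @param panel `frequency_panel` (or any data.frame with one frequency
#'   column per source).
#' @param profile named numeric vector of ancestry proportions over the same
#'   source labels; must sum to 1 within 1e-6.
#' @return numeric vector of expected frequencies, one per panel row.
#' @export
expected_frequency <- function(panel, profile) {
  src <- names(profile)
  if (is.null(src) || !all(src %in% names(panel)))
    stop("profile source labels do not match the panel: ",
         paste(setdiff(src, names(panel)), collapse = ", "))
  if (abs(sum(profile) - 1) > 1e-6) stop("profile must sum to 1")
  as.numeric(as.matrix(panel[src]) %*% as.numeric(profile))
}

#' Chi-square ancestry-enrichment test for one or more SNPs
#'
#' Converts observed and expected alternate-allele frequencies into allele
#' counts on the observed chromosome count and compares them with the
#' one-degree-of-freedom goodness-of-fit statistic
#' `chi2 = (Obs_Ref - Exp_Ref)^2 / Exp_Ref + (Obs_Alt - Exp_Alt)^2 / Exp_Alt`.
#'
#' The reference distribution requires counts, so frequencies are multiplied
#' by `n_chrom` (the non-missing chromosome count): observed counts are
#' rounded to integers when only a frequency is supplied (`obs_alt` passes
#' exact counts when genotypes are available); expected counts may be
#' fractional.  The expected frequency is clamped to
#' \[1/n_chrom, 1 - 1/n_chrom\] before forming expected counts, so SNPs
#' absent from every contributing source cannot produce a zero denominator.
#' A SNP whose observed frequency equals its expected frequency exactly
#' (including both monomorphic) gets chi2 = 0, p = 1.
#'
#' @param f_obs observed alternate-allele frequency (vectorised).
#' @param f_exp expected frequency from [expected_frequency()].
#' @param n_chrom observed chromosome count (2 x non-missing samples).
#' @param obs_alt optional exact observed alternate-allele counts.
#' @return data.frame: `obs_ref`, `obs_alt`, `exp_ref`, `exp_alt`, `chi2`,
#'   `p`.
#' @export
enrichment_test <- function(f_obs, f_exp, n_chrom, obs_alt = NULL) {
  if (any(n_chrom <= 0)) stop("n_chrom must be positive")
  if (any(f_obs < 0 | f_obs > 1, na.rm = TRUE) ||
      any(f_exp < 0 | f_exp > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  n <- max(length(f_obs), length(f_exp), length(n_chrom))
  f_obs <- rep_len(f_obs, n); f_exp <- rep_len(f_exp, n)
  n_chrom <- rep_len(n_chrom, n)
  if (is.null(obs_alt)) obs_alt <- round(f_obs * n_chrom)
  else obs_alt <- rep_len(obs_alt, n)
  obs_ref <- n_chrom - obs_alt
  f_exp_c <- clamp(f_exp, 1 / n_chrom, 1 - 1 / n_chrom)
  exp_alt <- f_exp_c * n_chrom
  exp_ref <- n_chrom - exp_alt
  chi2 <- (obs_ref - exp_ref)^2 / exp_ref + (obs_alt - exp_alt)^2 / exp_alt
  chi2[f_obs == f_exp] <- 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(obs_ref = obs_ref, obs_alt = obs_alt,
             exp_ref = exp_ref, exp_alt = exp_alt, chi2 = chi2, p = p)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1, in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Attribute an enrichment signal to an ancestral source
#'
#' For each source s the attribution score balances that source's frequency
#' separation from the other sources against the distance of the observed
#' frequency from the source:
#' `Anc_s = mean_{t != s}(f_s - f_t) - |f_obs - f_s|`.
#' For three sources this is
#' `[(f_s - f_t) + (f_s - f_u)]/2 - |f_obs - f_s|`; for other K the mean
#' pairwise difference generalisation is used and flagged.  The enriched
#' ancestry is the argmax; exact ties are broken by source-column order and
#' flagged.
#'
#' @param f_obs observed frequency (vectorised over SNPs).
#' @param freqs matrix (SNPs x sources) or single named vector of source
#'   frequencies.
#' @return list: `scores` (matrix SNPs x sources), `enriched_ancestry`
#'   (character), `tie` (logical), `generalized` (TRUE when K != 3).
#' @export
attribute_ancestry <- function(f_obs, freqs) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1,
                                           dimnames = list(NULL, names(freqs)))
  freqs <- as.matrix(freqs)
  K <- ncol(freqs)
  if (K < 2) stop("attribution requires at least 2 sources")
  n <- nrow(freqs)
  f_obs <- rep_len(f_obs, n)
  scores <- matrix(NA_real_, n, K, dimnames = list(NULL, colnames(freqs)))
  rs <- rowSums(freqs)
  for (s in seq_len(K)) {
    sep <- (K * freqs[, s] - rs) / (K - 1)   # mean of f_s - f_t over t != s
    scores[, s] <- sep - abs(f_obs - freqs[, s])
  }
  best <- max.col(scores, ties.method = "first")
  maxv <- scores[cbind(seq_len(n), best)]
  tie <- rowSums(abs(scores - maxv) < 1e-12) > 1
  list(scores = scores,
       enriched_ancestry = colnames(freqs)[best],
       tie = tie,
       generalized = K != 3)
}

#' Run the ancestry-enrichment scan over a cohort
#'
#' One scan = one admixed population: joins cohort observed frequencies with
#' the ancestral-frequency panel, computes expected frequencies from the
#' population's ancestry profile, tests every SNP, adjusts p-values by
#' Benjamini-Hochberg across all tested SNPs of the population, annotates
#' the enriched allele (the one observed above expectation) and attributes
#' each SNP's signal to an ancestral source.
#'
#' @param x either a [genotype_matrix()] (exact allele counts are used) or a
#'   data.frame with columns `chrom`, `pos`, `ref`, `alt`, `freq`,
#'   `n_chrom` (e.g. from [allele_frequencies()]).
#' @param panel `frequency_panel`.
#' @param profile named proportion vector (see [profile_vector()]).
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @return list of class `enrichment_scan`: `records` (one row per tested
#'   SNP with observed/expected frequencies and counts, `chi2`, `p`, `q`,
#'   `enriched_allele`, per-source `anc_<SRC>` scores, `enriched_ancestry`,
#'   `attribution_tie`) and `significant` (subset with `q < q_threshold`).
#' @export
run_enrichment_scan <- function(x, panel, profile, q_threshold = 0.05) {
  if (inherits(x, "genotype_matrix")) {
    freq_tab <- allele_frequencies(x)
  } else {
    freq_tab <- as.data.frame(x)
    need <- c("chrom", "pos", "ref", "alt", "freq", "n_chrom")
    if (!all(need %in% names(freq_tab)))
      stop("frequency table needs columns: ", paste(need, collapse = ", "))
    if (!"alt_count" %in% names(freq_tab)) freq_tab$alt_count <- NA
  }
  freq_tab <- freq_tab[!is.na(freq_tab$freq) & freq_tab$n_chrom > 0, ,
                       drop = FALSE]
  ids_obs <- variant_id(freq_tab)
  ids_panel <- variant_id(panel)
  keep <- match(ids_obs, ids_panel)
  ok <- !is.na(keep)
  if (!any(ok)) stop("no SNPs shared between the cohort and the panel")
  freq_tab <- freq_tab[ok, , drop = FALSE]
  prow <- panel[keep[ok], , drop = FALSE]
  src <- panel_sources(panel)

  f_exp <- expected_frequency(prow, profile)
  obs_alt <- if (all(!is.na(freq_tab$alt_count))) freq_tab$alt_count else NULL
  test <- enrichment_test(freq_tab$freq, f_exp, freq_tab$n_chrom,
                          obs_alt = obs_alt)
  q <- fdr_adjust(test$p)
  att <- attribute_ancestry(freq_tab$freq, as.matrix(prow[src]))

  records <- data.frame(chrom = freq_tab$chrom, pos = freq_tab$pos,
                        ref = freq_tab$ref, alt = freq_tab$alt,
                        f_exp = f_exp, f_obs = freq_tab$freq,
                        n_chrom = freq_tab$n_chrom,
                        stringsAsFactors = FALSE)
  records <- cbind(records, test)
  records$q <- q
  records$enriched_allele <- ifelse(records$obs_alt > records$exp_alt,
                                    "alt", "ref")
  sc <- att$scores
  colnames(sc) <- paste0("anc_", colnames(sc))
  records <- cbind(records, as.data.frame(sc))
  records$enriched_ancestry <- att$enriched_ancestry
  records$attribution_tie <- att$tie
  rownames(records) <- NULL

  structure(list(records = records,
                 significant = records[records$q < q_threshold, ,
                                       drop = FALSE],
                 q_threshold = q_threshold,
                 sources = src),
            class = "enrichment_scan")
}

#' @export
print.enrichment_scan <- function(x, ...) {
  cat("<enrichment_scan> ", nrow(x$records), " SNPs tested, ",
      nrow(x$significant), " significant at q < ", x$q_threshold, "\n",
      sep = "")
  invisible(x)
}
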