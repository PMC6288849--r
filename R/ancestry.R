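#' Supervised maximum-likelihood ancestry proportions
#'
#' Estimates each individual's genome-wide ancestry proportions q over K
#' fixed source populations by maximising the binomial log-likelihood
#' `sum_j [ d_j log(q . f_j) + (2 - d_j) log(q . (1 - f_j)) ]`
#' over the K-simplex, where d_j is the dosage at SNP j and f_j the vector
#' of source alternate-allele frequencies.  This is the supervised analogue
#' of model-based clustering of admixed genomes: source frequencies are
#' known and held fixed, only the proportions are estimated.  Optimisation
#' is by EM with allele-origin responsibilities; a small Dirichlet(1 + 1e-6)
#' prior keeps degenerate (non-identifiable) inputs well-posed.
#'
#' @param gm [genotype_matrix()] of the admixed cohort.
#' @param panel `frequency_panel` of source frequencies; matched to the
#'   cohort by variant key.  Frequencies are clamped to
#'   \[1e-6, 1 - 1e-6\].
#' @param min_snps minimum number of informative (shared, non-missing-panel)
#'   SNPs required.
#' @param max_iter,tol EM stopping rule: stop when the relative change of
#'   the total log-likelihood falls below `tol`, or after `max_iter`
#'   iterations.
#' @return profile table ([read_profiles()] format, level "individual")
#'   with attributes: `loglik` (per-individual final log-likelihood),
#'   `loglik_trace` (total log-likelihood per EM iteration), `iterations`,
#'   `n_snps_used`, `degenerate_sources` (labels of sources with identical
#'   frequency columns, if any).
#' @export
estimate_proportions <- function(gm, panel, min_snps = 50L,
                                 max_iter = 500L, tol = 1e-7) {
  src <- panel_sources(panel)
  K <- length(src)
  ids_gm <- variant_id(gm$variants)
  ids_panel <- variant_id(panel)
  shared <- intersect(ids_gm, ids_panel)
  if (length(shared) < min_snps)
    stop("only ", length(shared), " SNPs shared with the panel; need >= ",
         min_snps)
  D <- gm$dosage[, match(shared, ids_gm), drop = FALSE]
  fmat <- as.matrix(panel[match(shared, ids_panel), src, drop = FALSE])
  fmat <- clamp(fmat, 1e-6, 1 - 1e-6)          # M x K

  degenerate <- character()
  if (K >= 2) {
    for (a in seq_len(K - 1)) for (b in seq((a + 1), K)) {
      if (max(abs(fmat[, a] - fmat[, b])) < 1e-12)
        degenerate <- union(degenerate, src[c(a, b)])
    }
    if (length(degenerate) > 0)
      warning("sources with identical frequencies (non-identifiable): ",
              paste(degenerate, collapse = ", "),
              "; returning the prior-regularized solution")
  }

  N <- nrow(D)
  obs <- !is.na(D)
  D0 <- D; D0[!obs] <- 0L
  Dm <- matrix(as.numeric(D0), N)
  Cm <- matrix(as.numeric(obs) * 2 - Dm, N)    # reference-allele copies
  m_eff <- rowSums(obs)                        # informative SNPs per sample

  # initialise at the simplex centre (deterministic)
  q <- matrix(1 / K, N, K, dimnames = list(rownames(D), src))
  if (K == 1) q[] <- 1

  prior <- 1e-6
  trace <- numeric(0)
  loglik_rows <- function(q) {
    Pa <- q %*% t(fmat)                        # N x M: P(alt allele)
    Pr <- q %*% t(1 - fmat)
    rowSums(obs * (Dm * log(Pa) + Cm * log(Pr)))
  }
  ll_row <- loglik_rows(q)
  ll_old <- sum(ll_row)
  iter <- 0L
  if (K > 1) {
    repeat {
      iter <- iter + 1L
      Pa <- q %*% t(fmat)
      Pr <- q %*% t(1 - fmat)
      # expected allele-copy counts attributed to each source
      Aa <- (Dm / Pa) %*% fmat                 # N x K
      Ar <- (Cm / Pr) %*% (1 - fmat)
      q <- q * (Aa + Ar)
      q <- q + prior
      q <- q / rowSums(q)
      ll_row <- loglik_rows(q)
      ll <- sum(ll_row)
      trace <- c(trace, ll)
      if (iter >= max_iter) break
      if (abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
      ll_old <- ll
    }
  } else {
    trace <- sum(ll_row)
    iter <- 1L
  }

  out <- data.frame(unit = rownames(D), level = "individual",
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[src[k]]] <- q[, k]
  attr(out, "loglik") <- ll_row
  attr(out, "loglik_trace") <- trace
  attr(out, "iterations") <- iter
  attr(out, "n_snps_used") <- length(shared)
  attr(out, "degenerate_sources") <- degenerate
  out
}

#' Aggregate individual profiles into a population profile
#'
#' The population's ancestry profile is the arithmetic mean of its members'
#' proportions (renormalised against accumulated rounding), the standard
#' population-level summary of per-individual admixture fractions.
#'
#' @param profiles individual-level profile table.
#' @param grouping optional factor/character of group labels per row;
#'   default puts every row in one group named `population`.
#' @param population group label used when `grouping` is NULL.
#' @return profile table with `level = "population"`, one row per group.
#' @export
population_profile <- function(profiles, grouping = NULL,
                               population = "ALL") {
  if (nrow(profiles) == 0) stop("profiles table is empty")
  src <- setdiff(names(profiles), c("unit", "level"))
  if (is.null(grouping)) grouping <- rep(population, nrow(profiles))
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  out <- data.frame(unit = groups, level = "population",
                    stringsAsFactors = FALSE)
  for (s in src) out[[s]] <- NA_real_
  for (g in groups) {
    m <- colMeans(as.matrix(profiles[grouping == g, src, drop = FALSE]))
    out[out$unit == g, src] <- m / sum(m)
  }
  out
}
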