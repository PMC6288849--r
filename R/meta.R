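#' Per-SNP log odds ratio of observed vs expected allele frequencies
#'
#' For a SNP with observed and expected reference/alternate allele
#' frequencies, `log_or = ln[(f_obs_ref / f_exp_ref) / (f_obs_alt /
#' f_exp_alt)]`.  The sampling variance is the Woolf-type count-based
#' estimate `1/obs_ref + 1/obs_alt + 1/exp_ref + 1/exp_alt`; when any of the
#' four counts is zero, the Haldane-Anscombe continuity correction adds 0.5
#' to all four counts (for both the log-OR and its variance).
#'
#' @param records enrichment-record data.frame containing `f_obs`, `f_exp`,
#'   `obs_ref`, `obs_alt`, `exp_ref`, `exp_alt` (a scan's `records`).
#' @return data.frame with the record key columns present in the input plus
#'   `log_or`, `variance`; rows whose frequencies cannot be corrected into
#'   (0, 1) are dropped with a warning.
#' @export
snp_log_odds <- function(records) {
  records <- as.data.frame(records)
  need <- c("f_obs", "f_exp", "obs_ref", "obs_alt", "exp_ref", "exp_alt")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  o_r <- records$obs_ref; o_a <- records$obs_alt
  e_r <- records$exp_ref; e_a <- records$exp_alt
  zero <- o_r == 0 | o_a == 0 | e_r == 0 | e_a == 0
  o_r[zero] <- o_r[zero] + 0.5; o_a[zero] <- o_a[zero] + 0.5
  e_r[zero] <- e_r[zero] + 0.5; e_a[zero] <- e_a[zero] + 0.5
  bad <- o_r <= 0 | o_a <= 0 | e_r <= 0 | e_a <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with zero counts after correction skipped")
    records <- records[!bad, , drop = FALSE]
    o_r <- o_r[!bad]; o_a <- o_a[!bad]; e_r <- e_r[!bad]; e_a <- e_a[!bad]
  }
  n_obs <- o_r + o_a; n_exp <- e_r + e_a
  log_or <- log((o_r / n_obs) / (e_r / n_exp)) -
    log((o_a / n_obs) / (e_a / n_exp))
  variance <- 1 / o_r + 1 / o_a + 1 / e_r + 1 / e_a
  out <- records
  out$log_or <- log_or
  out$variance <- variance
  out
}

#' Fixed-effect (inverse-variance) combination
#'
#' Combines per-SNP log odds ratios with weights `w_i = 1 / variance_i`:
#' `combined = sum(w y) / sum(w)`, `se = sqrt(1 / sum(w))`, and a
#' normal-theory 95% confidence interval `combined +/- 1.96 se`.
#'
#' @param log_or numeric vector of effect estimates (>= 1).
#' @param variance positive sampling variances, same length.
#' @return one-row data.frame: `combined_log_or`, `se`, `ci95_low`,
#'   `ci95_high`, `n_snps`.
#' @export
combine_fixed_effect <- function(log_or, variance) {
  if (length(log_or) == 0) stop("need at least one effect estimate")
  if (length(variance) != length(log_or)) stop("lengths differ")
  if (any(variance <= 0)) stop("variances must be positive")
  w <- 1 / variance
  combined <- sum(w * log_or) / sum(w)
  se <- sqrt(1 / sum(w))
  data.frame(combined_log_or = combined, se = se,
             ci95_low = combined - 1.96 * se,
             ci95_high = combined + 1.96 * se,
             n_snps = length(log_or))
}

#' Pathway-level meta-analysis of ancestry enrichment
#'
#' Groups per-SNP log odds ratios by (pathway, population) and combines each
#' group by fixed-effect meta-analysis, yielding the per-pathway
#' forest-plot summary.  With `moderator = TRUE` a single weighted
#' least-squares model with categorical population terms is fitted per
#' pathway instead, and per-population estimates are the group coefficients.
#'
#' @param snp_table data.frame with `log_or`, `variance`, `pathway`,
#'   `population`.
#' @param moderator include population as a categorical moderator in a
#'   joint weighted least-squares fit per pathway (default FALSE: each
#'   (pathway, population) cell combined separately).
#' @return data.frame: `pathway`, `population`, `combined_log_or`, `se`,
#'   `ci95_low`, `ci95_high`, `n_snps`.
#' @export
pathway_meta <- function(snp_table, moderator = FALSE) {
  snp_table <- as.data.frame(snp_table)
  need <- c("log_or", "variance", "pathway", "population")
  if (!all(need %in% names(snp_table)))
    stop("snp_table needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (pw in unique(snp_table$pathway)) {
    sub <- snp_table[snp_table$pathway == pw, , drop = FALSE]
    if (moderator && length(unique(sub$population)) > 1) {
      # weighted least squares with one mean per population group
      g <- factor(sub$population)
      X <- stats::model.matrix(~ 0 + g)
      w <- 1 / sub$variance
      XtWX <- crossprod(X * sqrt(w))
      est <- solve(XtWX, crossprod(X * w, sub$log_or))
      se <- sqrt(diag(solve(XtWX)))
      for (i in seq_along(levels(g))) {
        out[[length(out) + 1L]] <- data.frame(
          pathway = pw, population = levels(g)[i],
          combined_log_or = est[i], se = se[i],
          ci95_low = est[i] - 1.96 * se[i],
          ci95_high = est[i] + 1.96 * se[i],
          n_snps = sum(g == levels(g)[i]),
          stringsAsFactors = FALSE)
      }
    } else {
      for (pop in unique(sub$population)) {
        cell <- sub[sub$population == pop, , drop = FALSE]
        cmb <- combine_fixed_effect(cell$log_or, cell$variance)
        out[[length(out) + 1L]] <- cbind(
          data.frame(pathway = pw, population = pop,
                     stringsAsFactors = FALSE), cmb)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
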