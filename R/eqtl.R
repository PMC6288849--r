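#' Minor-allele-frequency filter
#'
#' Retains SNPs with `min(f, 1 - f) > floor`, where f is the alternate-allele
#' frequency over the non-missing genotypes of the tested samples.  Low-MAF
#' SNPs carry little association information and unreliable genotype calls,
#' so they are excluded before the eQTL scan.
#'
#' @param gm [genotype_matrix()].
#' @param floor MAF threshold (default 0.05, i.e. MAF must exceed 5%).
#' @param samples optional sample subset on which the MAF is computed.
#' @return filtered genotype_matrix (all samples retained).
#' @export
maf_filter <- function(gm, floor = 0.05, samples = NULL) {
  freq <- allele_frequencies(gm, samples = samples)
  maf <- pmin(freq$freq, 1 - freq$freq)
  keep <- !is.na(maf) & maf > floor
  subset_gm(gm, variants = which(keep))
}

# internal: build the OLS design matrix [1, g, covariate dummies]
build_design <- function(g, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, genotype = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        X <- cbind(X, setNames(data.frame(v), nm))
      } else {
        f <- factor(v)
        if (nlevels(f) > 1) {
          d <- stats::model.matrix(~ f)[, -1, drop = FALSE]
          colnames(d) <- paste0(nm, levels(f)[-1])
          X <- cbind(X, d)
        }
      }
    }
  }
  as.matrix(X)
}

#' Additive linear-model eQTL fit for one (gene, SNP) pair
#'
#' Ordinary least squares of expression on `[1, genotype, covariates]`
#' (covariate factors dummy-coded), restricted to complete cases.  Inference
#' on the genotype coefficient: `t = beta / se` with `n - p` residual
#' degrees of freedom.  Solved by normal equations (Cholesky); the design is
#' checked for full column rank first and collinear columns are named in
#' the error.
#'
#' @param y expression vector.
#' @param g dosage vector (0/1/2, may contain NA).
#' @param covariates optional data.frame of per-sample covariates (e.g. sex,
#'   population label); factors are dummy-coded.
#' @return list: `beta`, `se`, `t`, `p`, `n` (complete cases), `df`
#'   (residual degrees of freedom), `coefficients` (all OLS coefficients).
#' @export
fit_eqtl <- function(y, g, covariates = NULL) {
  X <- build_design(g, covariates)
  cc <- complete.cases(y, X)
  y <- y[cc]
  X <- X[cc, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n - p < 1) stop("fewer observations than model parameters + 1")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  R <- chol(XtX)
  coef <- backsolve(R, forwardsolve(t(R), Xty))
  coef <- drop(coef)
  names(coef) <- colnames(X)
  resid <- y - drop(X %*% coef)
  df <- n - p
  sigma2 <- sum(resid^2) / df
  XtX_inv <- chol2inv(R)
  se_all <- sqrt(sigma2 * diag(XtX_inv))
  j <- match("genotype", colnames(X))
  beta <- unname(coef[j])
  se <- unname(se_all[j])
  t <- beta / se
  list(beta = beta, se = se, t = t,
       p = 2 * pt(abs(t), df, lower.tail = FALSE),
       n = n, df = df, coefficients = coef)
}

#' Genotype-by-group interaction test
#'
#' Pooled additive model with a genotype x group product term:
#' `y ~ 1 + g + group + g:group (+ covariates)`.  Returns the p-value of
#' the interaction (t-test for two groups; partial F-test otherwise), used
#' to corroborate ancestry-specific eQTL calls.
#'
#' @param y expression vector.
#' @param g dosage vector.
#' @param group factor/character of group labels (>= 2 levels).
#' @param covariates optional extra covariates (data.frame).
#' @return list: `p_interaction`, `stat`, `df1`, `df2`.
#' @export
fit_interaction <- function(y, g, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("interaction test needs >= 2 groups")
  dat <- data.frame(y = y, g = g, group = group)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  cov_terms <- if (is.null(covariates)) "" else
    paste("+", paste(names(as.data.frame(covariates)), collapse = " + "))
  f_full <- stats::as.formula(paste("y ~ g * group", cov_terms))
  f_null <- stats::as.formula(paste("y ~ g + group", cov_terms))
  full <- stats::lm(f_full, data = dat)
  null <- stats::lm(f_null, data = dat)
  an <- stats::anova(null, full)
  list(p_interaction = an[["Pr(>F)"]][2], stat = an$F[2],
       df1 = an$Df[2], df2 = an$Res.Df[2])
}

#' eQTL scan over (gene, SNP) pairs
#'
#' Fits [fit_eqtl()] for every requested pair within the chosen samples and
#' adjusts p-values by Benjamini-Hochberg across all tests of the scan.
#' Pairs come either from an explicit `pairs` table or from a cis window
#' around each gene body (`abs window` bp beyond start/end; window 0 keeps
#' only SNPs inside the gene body).
#'
#' @param expr genes x samples expression matrix (rownames = genes,
#'   colnames = sample IDs).
#' @param gm [genotype_matrix()]; samples are matched to `expr` columns by
#'   ID (intersection; error if empty).
#' @param pairs optional data.frame `gene`, `variant` ([variant_id()] keys).
#' @param genes optional gene models ([read_bed()] format) for cis-window
#'   pairing.
#' @param cis_window cis window in bp (default 1e6).
#' @param covariates optional data.frame with a `sample` column plus
#'   covariate columns (e.g. `sex`, `group`).
#' @param group optional group label: restricts the scan to the samples
#'   whose `covariates$group` equals it (the per-ancestry scan mode).
#' @param maf MAF floor applied within the tested samples (default 0.05).
#' @param group_col name of the grouping column in `covariates`.
#' @return data.frame of class `eqtl_scan`: `gene`, `variant`, `chrom`,
#'   `pos`, `group`, `beta`, `se`, `t`, `p`, `q`, `maf`, `n`.
#' @export
scan_eqtl <- function(expr, gm, pairs = NULL, genes = NULL,
                      cis_window = 1e6, covariates = NULL, group = NULL,
                      maf = 0.05, group_col = "group") {
  samples <- intersect(colnames(expr), rownames(gm$dosage))
  if (length(samples) == 0) stop("no overlapping samples between expr and gm")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"sample" %in% names(covariates))
      stop("covariates need a 'sample' column")
    samples <- intersect(samples, covariates$sample)
  }
  if (!is.null(group)) {
    if (is.null(covariates) || !group_col %in% names(covariates))
      stop("group restriction requires covariates with a '", group_col,
           "' column")
    samples <- intersect(samples,
                         covariates$sample[covariates[[group_col]] == group])
    if (length(samples) == 0) stop("no samples in group ", group)
  }
  gm_s <- subset_gm(gm, samples = samples)
  gm_s <- maf_filter(gm_s, floor = maf)
  freq <- allele_frequencies(gm_s)
  vid <- variant_id(gm_s$variants)

  if (is.null(pairs)) {
    if (is.null(genes)) stop("provide either 'pairs' or gene models 'genes'")
    plist <- list()
    for (i in seq_len(nrow(genes))) {
      sel <- gm_s$variants$chrom == genes$chrom[i] &
        gm_s$variants$pos >= genes$start[i] - cis_window &
        gm_s$variants$pos <= genes$end[i] + cis_window
      if (any(sel))
        plist[[length(plist) + 1L]] <- data.frame(
          gene = genes$name[i], variant = vid[sel], stringsAsFactors = FALSE)
    }
    if (length(plist) == 0) stop("no (gene, SNP) pairs within the cis window")
    pairs <- do.call(rbind, plist)
  } else {
    pairs <- as.data.frame(pairs)
    stopifnot(all(c("gene", "variant") %in% names(pairs)))
  }
  pairs <- pairs[pairs$gene %in% rownames(expr) & pairs$variant %in% vid, ,
                 drop = FALSE]
  if (nrow(pairs) == 0) stop("no testable (gene, SNP) pairs")

  cov_cols <- if (is.null(covariates)) NULL else
    setdiff(names(covariates), "sample")
  cov_use <- if (!is.null(cov_cols) && length(cov_cols) > 0) {
    cv <- covariates[match(samples, covariates$sample), cov_cols,
                     drop = FALSE]
    # a restricted group makes its own label constant; drop constant columns
    keep <- vapply(cv, function(x) length(unique(x[!is.na(x)])) > 1, TRUE)
    if (any(keep)) cv[, keep, drop = FALSE] else NULL
  } else NULL

  res <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    gidx <- match(pairs$variant[r], vid)
    fit <- fit_eqtl(expr[pairs$gene[r], samples],
                    gm_s$dosage[samples, gidx], cov_use)
    res[[r]] <- data.frame(
      gene = pairs$gene[r], variant = pairs$variant[r],
      chrom = gm_s$variants$chrom[gidx], pos = gm_s$variants$pos[gidx],
      group = if (is.null(group)) "pooled" else group,
      beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
      maf = pmin(freq$freq[gidx], 1 - freq$freq[gidx]), n = fit$n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- fdr_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("eqtl_scan", "data.frame")
  out
}

#' Classify eQTLs as ancestry-specific or shared
#'
#' Compares per-group scans pair by pair: a pair is `A-specific` when it is
#' significant in group A (`q < q_sig`) and clearly null in group B
#' (`p > p_null`), symmetrically `B-specific`; `shared` when significant in
#' both groups with the same sign of beta; otherwise `none`.  Pairs absent
#' from one scan are `untestable`.
#'
#' @param results_a,results_b [scan_eqtl()] outputs for the two groups.
#' @param q_sig significance threshold on the q-value (default 0.05).
#' @param p_null null threshold on the other group's p-value (default 0.1).
#' @param labels length-2 character: names of groups A and B used in the
#'   labels (defaults to the scans' group columns).
#' @return data.frame: `gene`, `variant`, per-group `beta`/`p`/`q`, `label`.
#' @export
classify_ancestry_specific <- function(results_a, results_b, q_sig = 0.05,
                                       p_null = 0.1, labels = NULL) {
  if (is.null(labels))
    labels <- c(results_a$group[1] %||% "A", results_b$group[1] %||% "B")
  key_a <- paste(results_a$gene, results_a$variant)
  key_b <- paste(results_b$gene, results_b$variant)
  all_keys <- union(key_a, key_b)
  ia <- match(all_keys, key_a)
  ib <- match(all_keys, key_b)
  out <- data.frame(
    gene = ifelse(is.na(ia), results_b$gene[ib], results_a$gene[ia]),
    variant = ifelse(is.na(ia), results_b$variant[ib],
                     results_a$variant[ia]),
    beta_a = results_a$beta[ia], p_a = results_a$p[ia],
    q_a = results_a$q[ia],
    beta_b = results_b$beta[ib], p_b = results_b$p[ib],
    q_b = results_b$q[ib],
    stringsAsFactors = FALSE)
  label <- rep("none", nrow(out))
  untestable <- is.na(ia) | is.na(ib)
  a_spec <- !untestable & out$q_a < q_sig & out$p_b > p_null
  b_spec <- !untestable & out$q_b < q_sig & out$p_a > p_null
  shared <- !untestable & out$q_a < q_sig & out$q_b < q_sig &
    sign(out$beta_a) == sign(out$beta_b)
  label[a_spec] <- paste0(labels[1], "-specific")
  label[b_spec] <- paste0(labels[2], "-specific")
  label[shared] <- "shared"
  label[untestable] <- "untestable"
  out$label <- label
  out
}
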