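#' Construct a genotype matrix
#'
#' The central genotype container: a samples x variants integer matrix of
#' diploid alternate-allele dosages (0, 1, 2 or `NA` for missing), a variant
#' table keyed by (chrom, pos, ref, alt), and optional per-sample metadata
#' (population label, sex).  Only biallelic SNPs are represented.
#'
#' @param dosage integer matrix, samples in rows, variants in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per dosage column.
#' @param sample_meta optional data.frame with column `sample` matching the
#'   dosage rownames, plus e.g. `population` and `sex`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `sample_meta`.
#' @export
genotype_matrix <- function(dosage, variants, sample_meta = NULL) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0)
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  ok_base <- function(x) x %in% c("A", "C", "G", "T")
  if (!all(ok_base(variants$ref)) || !all(ok_base(variants$alt)))
    stop("alleles must be single bases A/C/G/T (biallelic SNPs only)")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  colnames(dosage) <- variant_id(variants)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = rownames(dosage),
                              stringsAsFactors = FALSE)
  } else {
    sample_meta <- as.data.frame(sample_meta)
    if (!"sample" %in% names(sample_meta))
      stop("sample_meta needs a 'sample' column")
    if (!identical(as.character(sample_meta$sample), rownames(dosage)))
      stop("sample_meta$sample must match dosage rownames in order")
  }
  structure(list(dosage = dosage, variants = variants,
                 sample_meta = sample_meta),
            class = "genotype_matrix")
}

#' Canonical variant identifier
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_id <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " samples x ",
      ncol(x$dosage), " variants\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  missingness: ", format(100 * miss, digits = 3), "%\n", sep = "")
  if ("population" %in% names(x$sample_meta)) {
    tab <- table(x$sample_meta$population)
    cat("  populations: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x genotype_matrix.
#' @param samples character (IDs) or logical/integer index over samples.
#' @param variants logical/integer index over variants, or character variant
#'   IDs as produced by [variant_id()].
#' @return genotype_matrix restricted to the selection.
#' @export
subset_gm <- function(x, samples = NULL, variants = NULL) {
  si <- seq_len(nrow(x$dosage))
  vi <- seq_len(ncol(x$dosage))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, rownames(x$dosage)) else si[samples]
    if (anyNA(si)) stop("unknown sample ID(s)")
    if (length(si) == 0) stop("sample subset is empty")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, colnames(x$dosage)) else vi[variants]
    if (anyNA(vi)) stop("unknown variant selection")
  }
  genotype_matrix(x$dosage[si, vi, drop = FALSE],
                  x$variants[vi, , drop = FALSE],
                  x$sample_meta[si, , drop = FALSE])
}

#' Per-variant alternate-allele frequencies
#'
#' Frequencies are computed over non-missing genotypes only: the alternate
#' count is the sum of non-missing dosages and the denominator is twice the
#' number of non-missing samples (the observed chromosome count).  Variants
#' with all genotypes missing get `NA` frequency and are flagged.
#'
#' @param gm genotype_matrix.
#' @param samples optional sample subset (IDs or index); must be non-empty.
#' @return data.frame: variant key columns, `alt_count`, `n_chrom`, `freq`,
#'   `all_missing`.
#' @export
allele_frequencies <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- subset_gm(gm, samples = samples)
  if (nrow(gm$dosage) == 0) stop("sample subset is empty")
  d <- gm$dosage
  alt <- colSums(d, na.rm = TRUE)
  n_chrom <- 2L * colSums(!is.na(d))
  freq <- ifelse(n_chrom > 0, alt / n_chrom, NA_real_)
  out <- cbind(gm$variants,
               data.frame(alt_count = as.integer(alt),
                          n_chrom = as.integer(n_chrom),
                          freq = freq,
                          all_missing = n_chrom == 0))
  rownames(out) <- NULL
  out
}
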