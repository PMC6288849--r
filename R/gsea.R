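#' Map SNPs to gene bodies
#'
#' A SNP maps to a gene when it lies on the same chromosome with
#' `start <= pos <= end` (1-based inclusive, i.e. between transcription
#' start and stop).  Overlapping genes all receive the SNP.
#'
#' @param snps data.frame with `chrom`, `pos` (and optionally `ref`, `alt`).
#' @param models gene-model data.frame ([read_bed()] format).
#' @return list: `genes` (deduplicated gene symbols hit), `map` (data.frame
#'   `variant`, `chrom`, `pos`, `gene`).
#' @export
map_snps_to_genes <- function(snps, models) {
  snps <- as.data.frame(snps)
  if (!"variant" %in% names(snps)) {
    snps$variant <- if (all(c("ref", "alt") %in% names(snps)))
      variant_id(snps) else paste(snps$chrom, snps$pos, sep = ":")
  }
  maps <- list()
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    g <- models[models$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0 || nrow(s) == 0) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(s$pos, s$pos),
                                  IRanges::IRanges(g$start, g$end))
    if (length(hits) == 0) next
    maps[[ch]] <- data.frame(
      variant = s$variant[S4Vectors_from(hits)],
      chrom = ch,
      pos = s$pos[S4Vectors_from(hits)],
      gene = g$name[S4Vectors_to(hits)],
      stringsAsFactors = FALSE)
  }
  map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(variant = character(), chrom = character(),
               pos = integer(), gene = character())
  rownames(map) <- NULL
  list(genes = unique(map$gene), map = map)
}

# thin indirections so the Hits accessors stay in one place
S4Vectors_from <- function(h) as.integer(S4Vectors::queryHits(h))
S4Vectors_to <- function(h) as.integer(S4Vectors::subjectHits(h))

#' Gene-set overlap enrichment
#'
#' Tests each gene set for overrepresentation among the query genes with the
#' one-sided hypergeometric tail `P(X >= k)`, `X ~ Hypergeom(N, K, n)`,
#' where N is the background-universe size, K the set size restricted to the
#' background, n the query size and k the observed overlap.
#' Benjamini-Hochberg q-values are computed across all sets tested; results
#' are sorted by p.
#'
#' @param query_genes character vector; must be a subset of
#'   `background_genes`.
#' @param sets named list of character vectors (see [read_gmt()]); sets
#'   disjoint from the background are skipped with a warning.
#' @param background_genes the gene universe.
#' @param categories optional named character vector of per-set category
#'   labels (defaults to the `category` attribute of `sets`, else "other").
#' @return data.frame: `set_name`, `category`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `overlap_genes` (comma-separated).
#' @export
overlap_enrichment <- function(query_genes, sets, background_genes,
                               categories = NULL) {
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0) stop("background universe is empty")
  query_genes <- unique(query_genes)
  stray <- setdiff(query_genes, background_genes)
  if (length(stray) > 0)
    stop("query genes outside the background: ",
         paste(head(stray, 5), collapse = ", "))
  if (is.null(categories)) categories <- attr(sets, "category")
  if (is.null(categories))
    categories <- setNames(rep("other", length(sets)), names(sets))
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background_genes)
    K <- length(members)
    if (K == 0) {
      warning("gene set disjoint from the background, skipped: ", nm)
      return(NULL)
    }
    overlap <- intersect(members, query_genes)
    k <- length(overlap)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm,
               category = unname(categories[nm] %||% "other"),
               k = k, K = K, n = n, N = N, p = p,
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(set_name = character(), category = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      overlap_genes = character()))
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out <- out[order(out$p), c("set_name", "category", "k", "K", "n", "N",
                             "p", "q", "overlap_genes")]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Cross-population gene sharing
#'
#' Partitions the union of per-population gene lists into the 2^P - 1
#' membership classes (which combination of populations carries each gene)
#' and summarises how many genes are exclusive to one population or shared
#' by 2, 3, ..., P populations.
#'
#' @param gene_lists named list (>= 2 populations) of character vectors.
#' @return list: `classes` (data.frame `gene`, `populations`
#'   (comma-separated), `n_pops`), `shared_by` (data.frame `n_pops`,
#'   `n_genes` for m = 1..P), `n_total` (size of the union).
#' @export
gene_sharing <- function(gene_lists) {
  if (length(gene_lists) < 2) stop("need gene lists for >= 2 populations")
  if (is.null(names(gene_lists))) stop("gene_lists must be named")
  gene_lists <- lapply(gene_lists, unique)
  all_genes <- sort(unique(unlist(gene_lists)))
  member <- vapply(gene_lists, function(gl) all_genes %in% gl,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(gene_lists)))
  n_pops <- rowSums(member)
  pops <- apply(member, 1, function(m)
    paste(colnames(member)[m], collapse = ","))
  classes <- data.frame(gene = all_genes, populations = unname(pops),
                        n_pops = as.integer(n_pops),
                        stringsAsFactors = FALSE)
  shared_by <- data.frame(n_pops = seq_along(gene_lists),
                          n_genes = vapply(seq_along(gene_lists),
                                           function(m) sum(n_pops == m), 1L))
  list(classes = classes, shared_by = shared_by,
       n_total = length(all_genes))
}
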