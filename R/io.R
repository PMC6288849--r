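#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (GT field required) into diploid alternate-allele
#' dosages.  Only biallelic SNP records are retained: multiallelic records
#' and records whose REF or ALT is not a single A/C/G/T base are skipped
#' (with a message giving the count) or, with `non_snp = "error"`, rejected.
#' Missing genotypes (`./.` or `.`) become `NA` and are excluded from
#' frequency denominators downstream.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param non_snp `"skip"` (default) or `"error"` for non-biallelic-SNP
#'   records.
#' @return A [genotype_matrix()] preserving the header's sample order.
#' @export
read_vcf <- function(path, non_snp = c("skip", "error")) {
  non_snp <- match.arg(non_snp)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  is_snp <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    if (non_snp == "error")
      stop(n_drop, " non-biallelic-SNP record(s) in ", path)
    message("read_vcf: skipped ", n_drop, " non-biallelic-SNP record(s)")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  # strip phase separators and count alternate alleles per genotype
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  alleles <- gsub("\\|", "/", gt)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  idx <- match(alleles, names(known))
  dos[] <- known[idx]
  unresolved <- is.na(idx) & !is.na(alleles) & !alleles %in% c("./.", ".")
  if (any(unresolved))
    stop("unparseable GT value(s), e.g. '", alleles[which(unresolved)[1]], "'")
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  dosage <- t(dos)
  rownames(dosage) <- colnames(gt)
  genotype_matrix(dosage, variants)
}

#' Write a genotype matrix as VCF 4.2 text
#'
#' Minimal writer (GT field only, unphased) whose output round-trips through
#' [read_vcf()].
#'
#' @param gm genotype_matrix.
#' @param path output file.
#' @param meta optional character vector of extra `##`-header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, meta = NULL) {
  gt_code <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  nz <- !is.na(t(d))
  gt[nz] <- gt_code[t(d)[nz] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=admixscan",
              meta,
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(gm$variants$chrom, gm$variants$pos, variant_id(gm$variants),
                gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# internal: read a TSV written by write_results()/write_tsv_meta()
read_tsv <- function(path, required = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  df
}

# internal: full-precision TSV writer with optional '#' metadata header
write_tsv_meta <- function(df, path, meta = NULL) {
  df_out <- df
  for (j in seq_along(df_out)) {
    if (is.double(df_out[[j]]))
      df_out[[j]] <- sprintf("%.17g", df_out[[j]])
  }
  df_out[is.na(df)] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df_out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read an ancestral-frequency panel
#'
#' Expected columns: `chrom pos ref alt freq_<POP1> freq_<POP2> ...`, one row
#' per SNP, alternate-allele frequencies in `[0, 1]`.
#'
#' @param path TSV file.
#' @return A `frequency_panel`: data.frame with key columns plus one
#'   frequency column per source, named by the source label.
#' @export
read_frequency_panel <- function(path) {
  df <- read_tsv(path, required = c("chrom", "pos", "ref", "alt"))
  fcols <- grep("^freq_", names(df), value = TRUE)
  if (length(fcols) == 0) stop("no freq_<POP> columns in ", path)
  out <- df[c("chrom", "pos", "ref", "alt")]
  for (fc in fcols) {
    v <- as.numeric(df[[fc]])
    if (any(is.na(v)) || any(v < 0) || any(v > 1))
      stop("frequency outside [0,1] (or missing) in column ", fc)
    out[[sub("^freq_", "", fc)]] <- v
  }
  frequency_panel(out)
}

#' Construct/validate a frequency panel
#'
#' @param df data.frame with `chrom`, `pos`, `ref`, `alt` and one numeric
#'   frequency column per ancestral source.
#' @return data.frame of class `frequency_panel`.
#' @export
frequency_panel <- function(df) {
  df <- as.data.frame(df)
  key <- c("chrom", "pos", "ref", "alt")
  if (!all(key %in% names(df))) stop("panel needs chrom/pos/ref/alt columns")
  sources <- setdiff(names(df), key)
  if (length(sources) == 0) stop("panel has no source-frequency columns")
  for (s in sources) {
    if (!is.numeric(df[[s]]) || any(is.na(df[[s]])) ||
        any(df[[s]] < 0 | df[[s]] > 1))
      stop("panel frequencies for source ", s, " must be in [0,1]")
  }
  class(df) <- c("frequency_panel", "data.frame")
  df
}

#' Source labels of a frequency panel
#' @param panel frequency_panel.
#' @return character vector of source-population labels.
#' @export
panel_sources <- function(panel) {
  setdiff(names(panel), c("chrom", "pos", "ref", "alt"))
}

#' Write a frequency panel as TSV
#' @param panel frequency_panel.
#' @param path output file.
#' @param meta optional header comment lines.
#' @return `path`, invisibly.
#' @export
write_frequency_panel <- function(panel, path, meta = NULL) {
  src <- panel_sources(panel)
  out <- panel[c("chrom", "pos", "ref", "alt")]
  for (s in src) out[[paste0("freq_", s)]] <- panel[[s]]
  write_tsv_meta(out, path, meta)
}

#' Read ancestry profiles
#'
#' Expected columns: `unit level p_<POP1> ...` with `level` either
#' `"population"` or `"individual"`; proportions must be non-negative and sum
#' to 1 within 1e-6 per row.
#'
#' @param path TSV file.
#' @return data.frame with `unit`, `level` and one proportion column per
#'   source (label without the `p_` prefix).
#' @export
read_profiles <- function(path) {
  df <- read_tsv(path, required = c("unit", "level"))
  pcols <- grep("^p_", names(df), value = TRUE)
  if (length(pcols) == 0) stop("no p_<POP> columns in ", path)
  if (!all(df$level %in% c("population", "individual")))
    stop("level must be 'population' or 'individual'")
  out <- df[c("unit", "level")]
  for (pc in pcols) {
    v <- as.numeric(df[[pc]])
    if (any(is.na(v)) || any(v < 0) || any(v > 1))
      stop("proportion outside [0,1] in column ", pc)
    out[[sub("^p_", "", pc)]] <- v
  }
  sums <- rowSums(out[setdiff(names(out), c("unit", "level"))])
  if (any(abs(sums - 1) > 1e-6))
    stop("ancestry proportions must sum to 1 (worst deviation ",
         format(max(abs(sums - 1))), ")")
  out
}

#' Write ancestry profiles as TSV
#' @param profiles data.frame as returned by [read_profiles()] or
#'   [estimate_proportions()].
#' @param path output file.
#' @param meta optional header comment lines.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, meta = NULL) {
  src <- setdiff(names(profiles), c("unit", "level"))
  out <- profiles[c("unit", "level")]
  for (s in src) out[[paste0("p_", s)]] <- profiles[[s]]
  write_tsv_meta(out, path, meta)
}

#' Extract one profile as a named proportion vector
#'
#' @param profiles profile table ([read_profiles()] format).
#' @param unit unit identifier to extract.
#' @return named numeric vector over source labels, summing to 1.
#' @export
profile_vector <- function(profiles, unit) {
  i <- match(unit, profiles$unit)
  if (is.na(i)) stop("unit not found in profiles: ", unit)
  src <- setdiff(names(profiles), c("unit", "level"))
  setNames(as.numeric(profiles[i, src]), src)
}

#' Read gene models from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' internal 1-based inclusive convention (`start = bed_start + 1`,
#' `end = bed_end`), matching the rule that a SNP maps to a gene when its
#' position lies between transcription start and stop inclusive.
#'
#' @param path BED4+ file (chrom, start, end, name, \[score, strand\]).
#' @return data.frame: `name`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file needs at least 4 columns: ", path)
  out <- data.frame(name = as.character(df[[4]]),
                    chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+",
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene model with start > end in ", path)
  out
}

#' Write gene models as BED4/BED6
#' @param models gene-model data.frame ([read_bed()] format, 1-based
#'   inclusive); converted back to 0-based half-open on write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(models, path) {
  writeLines(paste(models$chrom, models$start - 1L, models$end, models$name,
                   0L, models$strand, sep = "\t"), path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' One set per line: name, description, then member gene symbols,
#' tab-separated.  Gene identity is by exact (case-sensitive) symbol match.
#'
#' @param path GMT file.
#' @param category functional category label attached to every set in this
#'   file (`"disease"`, `"metabolism"`, `"immune"` or `"other"`).
#' @return named list of character vectors, with a `category` attribute
#'   (named character vector) alongside.
#' @export
read_gmt <- function(path, category = "other") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad)) stop("GMT line with fewer than 3 fields in ", path)
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (any(vapply(sets, length, 1L) == 0)) stop("empty gene set in ", path)
  names(sets) <- nms
  attr(sets, "category") <- setNames(rep(category, length(sets)), nms)
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(n) {
    paste(c(n, "na", sets[[n]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab-separated with header, `NA` for missing, numeric columns at full
#' precision so that write-then-read round-trips exactly.  Metadata lines
#' (tool version, seed, ...) are written as leading `#` comments.
#'
#' @param records data.frame.
#' @param path output file.
#' @param meta optional character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, meta = NULL) {
  write_tsv_meta(as.data.frame(records), path, meta)
}

#' Read a result table written by [write_results()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_results <- function(path) read_tsv(path)

# internal: complementary bases, vectorised
complement_alleles <- function(x) chartr("ACGT", "TGCA", x)

#' Harmonize two genotype datasets onto one allele orientation
#'
#' Intersects two genotype matrices on (chrom, pos) and reconciles allele
#' coding site by site, the way array and sequencing panels are merged before
#' joint analysis: identical alleles are kept; swapped ref/alt in `b` is
#' recoded (dosage d -> 2-d); a strand flip (complementary alleles) is
#' resolved by complementing `b`'s alleles and re-matching; strand-ambiguous
#' sites (A/T or C/G pairs), whose orientation cannot be determined from the
#' alleles alone, are dropped; remaining allele mismatches are dropped.
#' Samples of the two datasets are concatenated.
#'
#' @param a,b genotype_matrix objects on the same reference build (1-based
#'   positions; build agreement is the caller's responsibility).
#' @return list with `gm` (merged genotype_matrix in `a`'s orientation) and
#'   `report` (named integer vector of per-category site counts).
#' @export
harmonize <- function(a, b) {
  key_a <- paste(a$variants$chrom, a$variants$pos, sep = ":")
  key_b <- paste(b$variants$chrom, b$variants$pos, sep = ":")
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("no overlapping sites between the datasets")
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  ra <- a$variants$ref[ia]; aa <- a$variants$alt[ia]
  rb <- b$variants$ref[ib]; ab <- b$variants$alt[ib]

  ambiguous <- aa == complement_alleles(ra)   # A/T or C/G pair in a
  identical_ <- ra == rb & aa == ab
  swapped <- ra == ab & aa == rb
  flipped <- ra == complement_alleles(rb) & aa == complement_alleles(ab)
  flip_swapped <- ra == complement_alleles(ab) & aa == complement_alleles(rb)
  category <- rep("mismatch", length(shared))
  category[flip_swapped] <- "flip_swapped"
  category[flipped] <- "flipped"
  category[swapped] <- "swapped"
  category[identical_] <- "identical"
  category[ambiguous] <- "ambiguous"

  keep <- category %in% c("identical", "swapped", "flipped", "flip_swapped")
  report <- c(n_sites_a = length(key_a), n_sites_b = length(key_b),
              n_shared = length(shared),
              identical = sum(category == "identical"),
              swapped = sum(category == "swapped"),
              strand_flipped = sum(category == "flipped"),
              flip_swapped = sum(category == "flip_swapped"),
              ambiguous_dropped = sum(category == "ambiguous"),
              mismatch_dropped = sum(category == "mismatch"))
  if (!any(keep)) stop("no sites survive harmonization")

  ia <- ia[keep]; ib <- ib[keep]
  recode <- category[keep] %in% c("swapped", "flip_swapped")
  dos_a <- a$dosage[, ia, drop = FALSE]
  dos_b <- b$dosage[, ib, drop = FALSE]
  if (any(recode)) dos_b[, recode] <- 2L - dos_b[, recode]

  samples_b <- rownames(b$dosage)
  clash <- samples_b %in% rownames(a$dosage)
  if (any(clash)) {
    warning(sum(clash), " duplicate sample ID(s) suffixed with '_2'")
    samples_b[clash] <- paste0(samples_b[clash], "_2")
  }
  dosage <- rbind(dos_a, dos_b)
  rownames(dosage) <- c(rownames(a$dosage), samples_b)
  meta_b <- b$sample_meta
  meta_b$sample <- samples_b
  all_cols <- union(names(a$sample_meta), names(meta_b))
  pad <- function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA
    df[all_cols]
  }
  gm <- genotype_matrix(dosage, a$variants[ia, , drop = FALSE],
                        rbind(pad(a$sample_meta), pad(meta_b)))
  list(gm = gm, report = report)
}
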