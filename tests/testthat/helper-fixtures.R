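# Small in-code fixtures shared across the suite.

# toy VCF: 3 biallelic SNPs, 1 triallelic, 1 indel; 2 samples
toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t1/1",
    "1\t400\trs4\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2",
    "1\t500\trs5\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1")
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(toy_vcf_lines(), path)
  path
}

# genotype matrix from a dosage matrix with auto variants on chrom 1
make_gm <- function(dosage, ref = NULL, alt = NULL, chrom = "1",
                    pos = NULL, population = "POP", samples = NULL) {
  dosage <- as.matrix(dosage)
  M <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(M) * 100L
  if (is.null(ref)) ref <- rep("A", M)
  if (is.null(alt)) alt <- rep("G", M)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(dosage)))
  rownames(dosage) <- samples
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE),
                  data.frame(sample = samples, population = population,
                             sex = rep_len(c("M", "F"), length(samples)),
                             stringsAsFactors = FALSE))
}

# frequency panel from a SNPs x sources matrix
make_panel <- function(freqs, labels = c("AFR", "EUR", "NAT"), pos = NULL,
                       ref = NULL, alt = NULL) {
  freqs <- as.matrix(freqs)
  M <- nrow(freqs)
  if (is.null(pos)) pos <- seq_len(M) * 100L
  df <- data.frame(chrom = "1", pos = pos,
                   ref = if (is.null(ref)) rep("A", M) else ref,
                   alt = if (is.null(alt)) rep("G", M) else alt,
                   stringsAsFactors = FALSE)
  for (k in seq_len(ncol(freqs))) df[[labels[k]]] <- freqs[, k]
  frequency_panel(df)
}
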