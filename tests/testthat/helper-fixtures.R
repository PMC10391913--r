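`%||%` <- function(x, y) if (is.null(x)) y else x

# quick in-memory genotype matrix: dosage given sites x samples
make_gm <- function(dosage, pops = NULL, pos = NULL, chrom = NULL) {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage); n <- ncol(dosage)
  samples <- sprintf("s%02d", seq_len(n))
  pops <- pops %||% rep(c("A", "B"), length.out = n)
  geno_matrix(
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% seq(100, by = 100, length.out = m),
    ref = rep("A", m), alt = rep("C", m),
    dosage = dosage, samples = samples,
    pops = stats::setNames(pops, samples)
  )
}

write_tmp_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

pop_map_for <- function(samples, pops = rep(c("A", "B"), length.out = length(samples))) {
  tibble::tibble(sample = samples, population = pops)
}
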