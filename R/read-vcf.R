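#' Read a VCF into a genotype dosage matrix
#'
#' Parses diploid GT fields into alt-allele dosages. Records that are not
#' biallelic SNPs (indels, multi-allelic sites, symbolic alleles) are skipped
#' and counted. Half-missing genotypes (e.g. `0/.`) are treated as missing;
#' phased separators are accepted and treated like unphased ones. When the
#' VCF carries per-genotype `DP`, depths are kept alongside the dosages so
#' that [filter_sites()] can apply a minimum-depth mask.
#'
#' @param path Path to a VCF (optionally bgzipped) with a GT FORMAT field.
#' @param pop_map Sample-to-population assignment: a two-column data frame
#'   (`sample`, `population`), a named character vector, or the path of a
#'   two-column TSV. Every VCF sample must be present.
#' @return A [geno_matrix()]. The number of skipped non-SNP records is
#'   attached as attribute `n_skipped`.
#' @export
read_vcf <- function(path, pop_map) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  pops <- as_pop_map(pop_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    inform(sprintf("read_vcf: skipped %d record(s) that are not biallelic SNPs",
                   n_skipped))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  absent <- setdiff(samples, names(pops))
  if (length(absent) > 0) {
    abort(paste0("VCF sample(s) absent from pop_map: ", paste(absent, collapse = ", ")))
  }
  gt <- gt[snp, , drop = FALSE]
  dosage <- gt_to_dosage(gt)
  dp <- NULL
  fmt <- v@gt[, 1]
  if (length(fmt) > 0 && any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    )
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = 1)
    dp <- dp[snp, , drop = FALSE]
  }
  gm <- geno_matrix(
    chrom = fix[snp, "CHROM"], pos = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp],
    dosage = dosage, samples = samples, pops = pops[samples], dp = dp
  )
  attr(gm, "n_skipped") <- n_skipped
  gm
}

gt_to_dosage <- function(gt) {
  codes <- c(
    "0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
    "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2
  )
  d <- codes[gt]
  unknown <- is.na(d) & !is.na(gt) & !grepl("\\.", gt)
  if (any(unknown)) {
    abort(paste0("malformed GT field(s): ",
                 paste(unique(gt[unknown]), collapse = ", ")))
  }
  matrix(unname(d), nrow = nrow(gt), dimnames = dimnames(gt))
}

as_pop_map <- function(pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    pop_map <- read_pop_map(pop_map)
  }
  if (is.data.frame(pop_map)) {
    if (ncol(pop_map) < 2) abort("pop_map must have columns sample, population")
    return(setNames(as.character(pop_map[[2]]), as.character(pop_map[[1]])))
  }
  if (is.character(pop_map) && !is.null(names(pop_map))) return(pop_map)
  abort("pop_map must be a data frame, a named character vector, or a TSV path")
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample<TAB>population`); a header row with those names is
#' accepted but not required.
#'
#' @param path TSV path.
#' @return A tibble with columns `sample` and `population`.
#' @export
read_pop_map <- function(path) {
  x <- readr::read_tsv(path, col_names = c("sample", "population"),
                       col_types = "cc", progress = FALSE)
  if (nrow(x) > 0 && identical(tolower(unlist(x[1, ])), c("sample", "population"))) {
    x <- x[-1, ]
  }
  x
}

#' Write a genotype matrix as VCF 4.2
#'
#' GT-only records, one per SNP site; missing dosages become `./.`.
#' Heterozygotes are written `0/1`.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n_sites(gm), n_samples(gm))
  ok <- !is.na(gm$dosage)
  gt[ok] <- gt_codes[gm$dosage[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=divscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(gm$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- if (n_sites(gm) == 0) character(0) else paste(
    gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
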