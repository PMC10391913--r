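#' Genotype dosage matrix for two labeled populations
#'
#' A `geno_matrix` holds biallelic SNP genotypes as counts of the alternate
#' allele (0, 1, 2; `NA` for missing) in a sites-by-samples matrix, together
#' with per-site coordinates and alleles and a sample-to-population labeling.
#' Positions are 1-based (as in VCF); all interval arithmetic elsewhere in the
#' package converts to 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt Single-base reference and alternate alleles per site.
#' @param dosage Numeric matrix, sites in rows, samples in columns; entries
#'   0, 1, 2 or `NA`.
#' @param samples Character vector of sample identifiers (column order).
#' @param pops Named character vector mapping each sample to its population
#'   label.
#' @param dp Optional matrix of per-genotype sequencing depths with the same
#'   shape as `dosage` (used by [filter_sites()] when present).
#'
#' @return An object of class `geno_matrix`.
#' @seealso [read_vcf()], [filter_sites()], [sites()], [simulate_genotypes()]
#' @export
geno_matrix <- function(chrom, pos, ref, alt, dosage, samples, pops, dp = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (!is.null(dp)) dp <- as.matrix(dp)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  gm <- structure(
    list(
      chrom = chrom, pos = pos,
      ref = as.character(ref), alt = as.character(alt),
      dosage = dosage, samples = as.character(samples),
      pops = setNames(as.character(pops), names(pops) %||% samples),
      dp = dp
    ),
    class = "geno_matrix"
  )
  validate_geno_matrix(gm)
}

validate_geno_matrix <- function(gm) {
  m <- nrow(gm$dosage)
  n <- ncol(gm$dosage)
  if (length(gm$chrom) != m || length(gm$pos) != m ||
      length(gm$ref) != m || length(gm$alt) != m) {
    abort("per-site fields must all have length nrow(dosage)")
  }
  if (length(gm$samples) != n) {
    abort("`samples` must have one entry per dosage column")
  }
  bad <- !(gm$dosage %in% c(0, 1, 2) | is.na(gm$dosage))
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA")
  if (m > 0 && (any(nchar(gm$ref) != 1L) || any(nchar(gm$alt) != 1L))) {
    abort("all sites must be biallelic SNPs (single-base ref and alt)")
  }
  if (m > 1) {
    ok <- unlist(lapply(split(gm$pos, factor(gm$chrom, unique(gm$chrom))),
                        function(p) length(p) <= 1 || all(diff(p) > 0)))
    if (!all(ok)) abort("positions must strictly increase within each chromosome")
  }
  missing_pop <- setdiff(gm$samples, names(gm$pops))
  if (length(missing_pop) > 0) {
    abort(paste0("samples missing a population label: ",
                 paste(missing_pop, collapse = ", ")))
  }
  gm$pops <- gm$pops[gm$samples]
  dimnames(gm$dosage) <- list(NULL, gm$samples)
  gm
}

#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(x$pops)
  cat(sprintf(
    "<geno_matrix> %d sites x %d samples (%s)\n",
    n_sites(x), n_samples(x),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%%s\n", 100 * miss,
              if (is.null(x$dp)) "" else "; per-genotype DP present"))
  invisible(x)
}

#' @rdname geno_matrix
#' @param gm A `geno_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$dosage)

#' @rdname geno_matrix
#' @export
n_samples <- function(gm) ncol(gm$dosage)

#' Per-site summary of a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with one row per site: `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `missing_frac` and `maf` computed over non-missing calls.
#' @export
sites <- function(gm) {
  tibble(
    chrom = gm$chrom, pos = gm$pos, ref = gm$ref, alt = gm$alt,
    missing_frac = rowMeans(is.na(gm$dosage)),
    maf = maf_by_site(gm$dosage)
  )
}

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param sites Integer or logical index over sites (rows).
#' @param samples Integer, logical, or character index over samples.
#' @return A `geno_matrix` restricted to the requested sites and samples.
#' @export
subset_geno <- function(gm, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(gm)) else seq_len(n_sites(gm))[sites]
  if (is.character(samples)) samples <- match(samples, gm$samples)
  ci <- if (is.null(samples)) seq_len(n_samples(gm)) else seq_len(n_samples(gm))[samples]
  if (anyNA(ci)) abort("unknown sample in `samples`")
  geno_matrix(
    chrom = gm$chrom[si], pos = gm$pos[si], ref = gm$ref[si], alt = gm$alt[si],
    dosage = gm$dosage[si, ci, drop = FALSE],
    samples = gm$samples[ci], pops = gm$pops[ci],
    dp = if (is.null(gm$dp)) NULL else gm$dp[si, ci, drop = FALSE]
  )
}

#' Population labels in a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @return Sorted unique population labels.
#' @export
pop_labels <- function(gm) sort(unique(unname(gm$pops)))

pop_index <- function(gm, label) which(unname(gm$pops) == label)
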