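#' Minor allele frequency from alt-allele dosages
#'
#' `min(p, 1 - p)` with `p = sum(dosage) / (2 * non-missing samples)`.
#'
#' @param dosages Numeric vector of per-sample alt-allele counts (0/1/2, `NA`
#'   for missing) at one site.
#' @return The minor allele frequency in `[0, 0.5]`. All-missing input is an
#'   error (distinct from a monomorphic site, which returns 0).
#' @export
minor_allele_freq <- function(dosages) {
  n <- sum(!is.na(dosages))
  if (n == 0) abort("minor_allele_freq: all calls missing", class = "divscan_all_missing")
  p <- sum(dosages, na.rm = TRUE) / (2 * n)
  min(p, 1 - p)
}

## row-wise MAF over a dosage matrix; NaN where a row is all-missing
maf_by_site <- function(dosage) {
  n <- rowSums(!is.na(dosage))
  p <- rowSums(dosage, na.rm = TRUE) / (2 * n)
  pmin(p, 1 - p)
}

#' Filter SNP sites on missingness and minor allele frequency
#'
#' Retains sites whose missing-call fraction is strictly below
#' `max_missing_frac` and whose minor allele frequency is strictly above
#' `min_maf` (both computed over non-missing calls), mirroring the usual
#' "missing < 10%, MAF > 5%" screens applied to resequencing call sets.
#' Boundary sites (exactly 10% missing, MAF exactly 0.05) are removed.
#'
#' When the matrix carries per-genotype depths (`dp`), genotypes with depth
#' below `min_depth` are first masked to missing; the site-level screens then
#' apply to the masked matrix.
#'
#' @param gm A [geno_matrix()].
#' @param max_missing_frac Maximum tolerated missing fraction (strict), in
#'   `[0, 1]`. Default 0.10.
#' @param min_maf Minimum minor allele frequency (strict), in `[0, 0.5]`.
#'   Default 0.05; the default therefore also drops monomorphic sites.
#' @param min_depth Minimum per-genotype depth, applied only when depths are
#'   present. Default 2.
#' @return A filtered `geno_matrix`, site order preserved. Removal counts per
#'   rule are attached as attribute `removed` (a named integer vector) and
#'   reported via a message. An empty result is a warning, not an error.
#' @export
filter_sites <- function(gm, max_missing_frac = 0.10, min_maf = 0.05,
                         min_depth = 2) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 0.5, min_depth >= 0)
  if (n_sites(gm) == 0) abort("filter_sites: empty genotype matrix")
  n_masked <- 0L
  if (!is.null(gm$dp) && min_depth > 0) {
    low <- !is.na(gm$dp) & gm$dp < min_depth & !is.na(gm$dosage)
    n_masked <- sum(low)
    gm$dosage[low] <- NA
  }
  miss <- rowMeans(is.na(gm$dosage))
  maf <- maf_by_site(gm$dosage)
  pass_miss <- miss < max_missing_frac
  # all-missing rows have NaN maf and already fail the missingness screen
  pass_maf <- !is.nan(maf) & maf > min_maf
  keep <- pass_miss & pass_maf
  removed <- c(
    missingness = sum(!pass_miss),
    maf = sum(pass_miss & !pass_maf),
    genotypes_masked_low_depth = n_masked
  )
  inform(sprintf(
    "filter_sites: kept %d / %d sites (removed %d on missingness, %d on MAF%s)",
    sum(keep), length(keep), removed[["missingness"]], removed[["maf"]],
    if (n_masked > 0) sprintf("; masked %d low-depth genotypes", n_masked) else ""
  ))
  if (!any(keep)) warn("filter_sites: all sites removed; returning empty matrix")
  out <- subset_geno(gm, sites = keep)
  out$dp <- NULL
  attr(out, "removed") <- removed
  out
}
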