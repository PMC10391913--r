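#' Tile simulated gene annotations over the simulated genome
#'
#' Genes of `cfg$gene_length` bp every `cfg$gene_spacing` bp on every
#' simulated chromosome, so any sweep region longer than the spacing
#' overlaps at least one gene.
#'
#' @param cfg A [sim_config()].
#' @return A gene tibble in the [read_genes()] layout (0-based half-open).
#' @export
simulate_genes <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom_sim))
  purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0, cfg$chrom_length - cfg$gene_length, by = cfg$gene_spacing)
    tibble(
      gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
      chrom = ch, start = as.integer(starts),
      end = as.integer(starts + cfg$gene_length),
      strand = rep_len(c("+", "-"), length(starts))
    )
  })
}

#' Simulate a differential-expression table with known structure
#'
#' Genes overlapping planted sweep regions receive, with probability
#' `cfg$deg_frac`, a strong expression difference (|log2FC| drawn from
#' Uniform(2.5, 5), p from Uniform(1e-6, 1e-3)); all other genes get
#' background values (log2FC ~ Normal(0, 0.7), p ~ Uniform(0, 1)).
#'
#' @param truth A `ground_truth`.
#' @param genes A gene tibble ([simulate_genes()] or [read_genes()]).
#' @param cfg The matching [sim_config()].
#' @return A DEG tibble `gene`, `log2fc`, `pvalue`; the identifiers of the
#'   genes planted as differentially expressed are attached as attribute
#'   `planted_degs`.
#' @export
simulate_deg_table <- function(truth, genes, cfg) {
  set.seed(cfg$seed + 3L)
  in_sweep <- rep(FALSE, nrow(genes))
  if (!is.null(truth$sweep_regions)) {
    hits <- overlapping_genes(truth$sweep_regions, genes)
    in_sweep <- genes$gene_id %in% unlist(hits)
  }
  planted <- in_sweep & runif(nrow(genes)) < cfg$deg_frac
  log2fc <- rnorm(nrow(genes), 0, 0.7)
  pvalue <- runif(nrow(genes))
  sign_p <- sample(c(-1, 1), sum(planted), replace = TRUE)
  log2fc[planted] <- sign_p * runif(sum(planted), 2.5, 5)
  pvalue[planted] <- runif(sum(planted), 1e-6, 1e-3)
  out <- tibble(gene = genes$gene_id, log2fc = log2fc, pvalue = pvalue)
  attr(out, "planted_degs") <- genes$gene_id[planted]
  out
}

#' Write a complete simulated fixture set
#'
#' Emits, under `outdir`: `sim.vcf` (VCF 4.2, GT only), `genes.gff3`,
#' `pops.tsv`, `phenotypes.tsv`, `deg.tsv` and `truth.json` (a
#' machine-readable ground-truth sidecar with the per-site frequencies,
#' sweep regions and realized causal effects).
#'
#' @param gm A [geno_matrix()] from [simulate_genotypes()].
#' @param truth The matching `ground_truth`.
#' @param cfg The matching [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Named list of the written paths, invisibly.
#' @export
write_fixture <- function(gm, truth, cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(outdir, "sim.vcf"),
    gff3 = file.path(outdir, "genes.gff3"),
    pops = file.path(outdir, "pops.tsv"),
    pheno = file.path(outdir, "phenotypes.tsv"),
    deg = file.path(outdir, "deg.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_vcf(gm, paths$vcf)
  genes <- simulate_genes(cfg)
  write_gff3(genes, paths$gff3)
  readr::write_tsv(tibble(sample = gm$samples, population = unname(gm$pops)),
                   paths$pops)
  pheno <- simulate_phenotypes(gm, truth, cfg)
  readr::write_tsv(pheno, paths$pheno)
  deg <- simulate_deg_table(truth, genes, cfg)
  readr::write_tsv(deg, paths$deg)
  sidecar <- list(
    pop_names = truth$pop_names,
    F_background = truth$F_background,
    sweep_regions = truth$sweep_regions,
    causal_snps = attr(pheno, "effects"),
    planted_degs = attr(deg, "planted_degs"),
    sites = truth$sites
  )
  jsonlite::write_json(sidecar, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

## minimal GFF3 writer for the simulated annotation (read back through
## rtracklayer like any external GFF3)
write_gff3 <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    paste(genes$chrom, "divscan", "gene",
          genes$start + 1L, genes$end, ".", genes$strand, ".",
          paste0("ID=", genes$gene_id),
          sep = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}
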