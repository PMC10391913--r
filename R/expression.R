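#' Read a differential-expression table
#'
#' TSV with header `gene`, `log2fc`, `pvalue` (the first three columns are
#' used positionally and renamed; the original p-value column name is
#' recorded in attribute `p_column` since tables differ in whether they
#' carry raw or adjusted p-values).
#'
#' @param path TSV path.
#' @return A tibble `gene`, `log2fc`, `pvalue`.
#' @export
read_deg_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 3) abort("DEG table needs gene, log2fc and p-value columns")
  p_col <- names(x)[3]
  x <- setNames(x[, 1:3], c("gene", "log2fc", "pvalue"))
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$gene)) abort("duplicate gene identifiers in DEG table")
  attr(x, "p_column") <- p_col
  x
}

#' Threshold a DEG table into up- and down-regulated gene sets
#'
#' Fold-change bounds are inclusive and the p-value cut strict, exactly as
#' customary for "log2FC >= 2 or <= -2, p < 0.01" style screens: up-regulated
#' means `log2fc >= lfc`, down-regulated `log2fc <= -lfc`, both requiring
#' `pvalue < p`.
#'
#' @param deg A DEG tibble (`gene`, `log2fc`, `pvalue`).
#' @param lfc Absolute log2 fold-change threshold (inclusive). Default 2.
#' @param p P-value threshold (strict). Default 0.01.
#' @return The passing rows with a `direction` column (`"up"`/`"down"`).
#' @export
filter_degs <- function(deg, lfc = 2, p = 0.01) {
  deg |>
    dplyr::filter(abs(.data$log2fc) >= lfc, .data$pvalue < p) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
}

#' Expression check for candidate genes
#'
#' Restricts a DEG table to supplied candidate genes (e.g. association hits)
#' and applies the looser thresholds used for candidate-gene expression
#' evidence (default `|log2fc| >= 1`, `p < 0.05`). Candidates absent from
#' the table are reported as `"not_assayed"` rather than erroring.
#'
#' @param deg A DEG tibble.
#' @param genes Character vector of candidate gene identifiers.
#' @param lfc Absolute log2 fold-change threshold (inclusive). Default 1.
#' @param p P-value threshold (strict). Default 0.05.
#' @return A tibble `gene`, `log2fc`, `pvalue`, `status` with status one of
#'   `"up"`, `"down"`, `"ns"`, `"not_assayed"`.
#' @export
candidate_expression <- function(deg, genes, lfc = 1, p = 0.05) {
  tibble(gene = unique(genes)) |>
    dplyr::left_join(deg, by = "gene") |>
    dplyr::mutate(status = dplyr::case_when(
      is.na(.data$log2fc) ~ "not_assayed",
      .data$log2fc >= lfc & .data$pvalue < p ~ "up",
      .data$log2fc <= -lfc & .data$pvalue < p ~ "down",
      TRUE ~ "ns"
    ))
}

#' Combine sweep, association and expression evidence per gene
#'
#' Outer union of all gene identifiers across the evidence sources, with one
#' boolean flag per source. Row order is lexicographic in the gene
#' identifier, so the output is deterministic and invariant to input order.
#'
#' @param sweep_a,sweep_b Gene identifiers from the two directional sweep
#'   scans (e.g. [psg_genes()] for each pi-ratio direction).
#' @param gwas Named list of gene-identifier vectors, one per trait.
#' @param deg_up,deg_down Up-/down-regulated gene identifiers (e.g. from
#'   [filter_degs()]).
#' @param candidates Genes passing the candidate expression check
#'   ([candidate_expression()] rows with status up or down).
#' @return A tibble with `gene`, `sweep_a_over_b`, `sweep_b_over_a`, one
#'   `gwas_<trait>` column per trait, `deg_up`, `deg_down`,
#'   `candidate_expression` and `n_sources`.
#' @export
build_evidence <- function(sweep_a = character(), sweep_b = character(),
                           gwas = list(), deg_up = character(),
                           deg_down = character(), candidates = character()) {
  if (length(gwas) > 0) {
    names(gwas) <- paste0("gwas_", names(gwas) %||% seq_along(gwas))
  }
  sources <- c(
    list(sweep_a_over_b = sweep_a, sweep_b_over_a = sweep_b),
    gwas,
    list(deg_up = deg_up, deg_down = deg_down,
         candidate_expression = candidates)
  )
  sources <- purrr::map(sources, ~ unique(as.character(.x)))
  all_genes <- sort(unique(unlist(sources)))
  out <- tibble(gene = all_genes)
  for (nm in names(sources)) out[[nm]] <- all_genes %in% sources[[nm]]
  flag_cols <- setdiff(names(out), "gene")
  out$n_sources <- rowSums(as.matrix(out[flag_cols]))
  out
}
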