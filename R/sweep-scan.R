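#' Flag the joint top-quantile windows by FST and log2 pi-ratio
#'
#' Computes the empirical `(1 - q)` quantile of FST and of the log2 pi-ratio
#' over usable windows and flags windows at or above *both* thresholds — the
#' intersection of the two marginal top-`q` sets. Thresholds use the order
#' statistic at rank `ceiling(q * N)` from the top, so with all-distinct
#' values each marginal set has exactly `ceiling(q * N)` members; ties at a
#' threshold are included.
#'
#' @param windows A [window_stats()] tibble.
#' @param q Upper-tail quantile, default 0.05.
#' @return `windows` with a logical `flagged` column; the thresholds are
#'   attached as attributes `fst_threshold` and `ratio_threshold`.
#' @export
select_top_windows <- function(windows, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  usable <- windows$usable
  if (!any(usable)) abort("select_top_windows: no usable windows")
  thr <- function(x) {
    x <- x[usable]
    sort(x, decreasing = TRUE)[ceiling(q * length(x))]
  }
  fst_thr <- thr(windows$fst)
  ratio_thr <- thr(windows$log2_pi_ratio)
  windows$flagged <- usable & windows$fst >= fst_thr &
    windows$log2_pi_ratio >= ratio_thr
  attr(windows, "fst_threshold") <- fst_thr
  attr(windows, "ratio_threshold") <- ratio_thr
  windows
}

#' Merge flagged windows into candidate sweep regions
#'
#' Adjacent or overlapping flagged windows (gap between them at most `gap`
#' bp) on the same chromosome are merged; summary statistics are maxima over
#' member windows.
#'
#' @param windows Output of [select_top_windows()] (or any window tibble with
#'   a logical `flagged` column), sorted by position within chromosome.
#' @param gap Maximum bp between consecutive flagged windows that still
#'   merges them. Default 0 (only abutting/overlapping windows merge).
#' @return A tibble of regions: `chrom`, `start`, `end` (0-based half-open),
#'   `member_windows`, `max_fst`, `max_log2_ratio`.
#' @export
merge_flagged <- function(windows, gap = 0) {
  fl <- dplyr::filter(windows, .data$flagged)
  if (nrow(fl) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  member_windows = integer(), max_fst = numeric(),
                  max_log2_ratio = numeric()))
  }
  fl |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_run = .data$start > dplyr::lag(cummax(.data$end), default = -Inf) + gap,
      run = cumsum(.data$new_run)
    ) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      member_windows = dplyr::n(),
      max_fst = max(.data$fst), max_log2_ratio = max(.data$log2_pi_ratio),
      .groups = "drop"
    ) |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Attach overlapping genes to sweep regions
#'
#' A gene is assigned to a region iff their half-open intervals share at
#' least 1 bp. A gene overlapping several regions appears in each region's
#' list but once in the deduplicated gene list ([psg_genes()]).
#'
#' @param regions Output of [merge_flagged()].
#' @param genes A [read_genes()] tibble.
#' @return `regions` with a `genes` list-column of gene identifiers.
#' @export
annotate_genes <- function(regions, genes) {
  regions$genes <- overlapping_genes(regions, genes)
  regions
}

#' Deduplicated candidate selected genes from annotated regions
#'
#' @param regions Output of [annotate_genes()].
#' @return Sorted unique gene identifiers overlapping any region.
#' @export
psg_genes <- function(regions) {
  sort(unique(unlist(regions$genes)))
}

#' Call candidate divergent regions from window statistics
#'
#' Convenience chain: [select_top_windows()] -> [merge_flagged()] ->
#' [annotate_genes()] (when `genes` is supplied).
#'
#' @inheritParams select_top_windows
#' @inheritParams merge_flagged
#' @param genes Optional [read_genes()] tibble.
#' @return A region tibble (see [merge_flagged()]), with a `genes`
#'   list-column when annotation was requested.
#' @export
call_sweeps <- function(windows, q = 0.05, gap = 0, genes = NULL) {
  regions <- merge_flagged(select_top_windows(windows, q = q), gap = gap)
  if (!is.null(genes)) regions <- annotate_genes(regions, genes)
  regions
}
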