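#' Read gene annotation from GFF3 or BED
#'
#' GFF3 records of type `gene` are used and their 1-based closed intervals
#' converted to 0-based half-open; BED intervals are taken as-is (already
#' 0-based half-open). Parsing goes through `rtracklayer`.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"`, or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`. Duplicate gene identifiers are an error.
#' @export
read_genes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) abort(paste0("failed to parse ", path, ": ", conditionMessage(e)))
  )
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- gr$ID %||% gr$Name
    if (is.null(ids)) abort("GFF3 gene records carry no ID attribute")
  } else {
    ids <- gr$name %||% paste0("region", seq_along(gr))
  }
  genes <- tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GRanges is 1-based closed in both cases; start-1 yields the original
    # BED coordinate back and converts GFF3 to 0-based half-open.
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (anyNA(genes$gene_id)) abort("gene records with missing identifiers")
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene identifier(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(genes$start >= genes$end)) abort("gene with start >= end")
  genes
}

## half-open interval overlap between a region tibble and a gene tibble;
## returns for each region row the character vector of overlapping gene ids
overlapping_genes <- function(regions, genes) {
  purrr::pmap(
    list(regions$chrom, regions$start, regions$end),
    function(ch, s, e) {
      hit <- genes$chrom == ch & genes$start < e & genes$end > s
      genes$gene_id[hit]
    }
  )
}
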