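fake_windows <- function(fst, ratio, chrom = "chr1", width = 5000) {
  n <- length(fst)
  tibble::tibble(
    chrom = chrom, start = seq(0, by = width, length.out = n),
    end = seq(width, by = width, length.out = n),
    n_sites = 10, n_fst_sites = 10,
    pi_a = 1e-3, pi_b = 1e-3, fst = fst, log2_pi_ratio = ratio,
    usable = TRUE
  )
}

test_that("joint top-quantile flagging is the intersection of marginal sets", {
  # 100 all-distinct windows engineered so exactly 3 are in both top-5 sets
  set.seed(5)
  fst <- seq(0.01, 1, length.out = 100)
  ratio <- c(sample(seq(-3, 0, length.out = 95)), 1.1, 1.2, 1.3, -4, -5)
  # fst ranks 96..100 are the top-5; give ranks 96,97,98 high ratios too
  w <- fake_windows(fst, ratio)
  fl <- select_top_windows(w, q = 0.05)
  # brute-force: sort and intersect
  topf <- order(fst, decreasing = TRUE)[1:5]
  topr <- order(ratio, decreasing = TRUE)[1:5]
  expect_equal(which(fl$flagged), sort(intersect(topf, topr)))
  expect_equal(sum(fl$flagged), 3)
})

test_that("the doubly maximal window is always flagged and ties are included", {
  set.seed(6)
  fst <- runif(40); ratio <- runif(40)
  fst[17] <- max(fst) + 1; ratio[17] <- max(ratio) + 1
  fl <- select_top_windows(fake_windows(fst, ratio), q = 0.025)
  expect_true(fl$flagged[17])

  const <- fake_windows(rep(0.3, 25), rep(1, 25))
  expect_true(all(select_top_windows(const, q = 0.05)$flagged))

  nouse <- fake_windows(0.1, 0.1)
  nouse$usable <- FALSE
  expect_error(select_top_windows(nouse), "no usable windows")
})

test_that("each marginal top set has exactly ceil(qN) members for distinct values", {
  set.seed(8)
  for (n in c(37, 100, 250)) {
    w <- fake_windows(sample(seq_len(n)) / n, sample(seq_len(n)) / n)
    fl <- select_top_windows(w, q = 0.05)
    expect_equal(sum(w$fst >= attr(fl, "fst_threshold")), ceiling(0.05 * n))
    expect_equal(sum(w$log2_pi_ratio >= attr(fl, "ratio_threshold")),
                 ceiling(0.05 * n))
  }
})

test_that("flagged windows merge by adjacency and chromosome", {
  w <- fake_windows(c(0.9, 0.9, 0.1, 0.9, 0.2), c(2, 2, 0, 2, 0))
  w$flagged <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  reg <- merge_flagged(w)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$end[1] - reg$start[1], 10000)
  expect_equal(reg$member_windows, c(2, 1))

  # gap bridging: one unflagged 5-kb hole merges when gap >= 5000
  reg2 <- merge_flagged(w, gap = 5000)
  expect_equal(nrow(reg2), 1)
  expect_equal(reg2$member_windows, 3)

  # different chromosomes never merge
  w2 <- rbind(fake_windows(0.9, 2), fake_windows(0.9, 2, chrom = "chr2"))
  w2$flagged <- TRUE
  expect_equal(nrow(merge_flagged(w2)), 2)
})

test_that("gene-region assignment uses half-open intersection", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(1000, 1000, 8000), end = c(2000, 2000, 9000), strand = "+"
  )
  genes$start[2] <- 6500; genes$end[2] <- 7000
  reg <- tibble::tibble(chrom = "chr1", start = 1500, end = 6500,
                        member_windows = 1L, max_fst = 1, max_log2_ratio = 1)
  ann <- annotate_genes(reg, genes)
  expect_equal(ann$genes[[1]], "g1")    # 500 bp overlap
  # touching half-open intervals do not intersect (g2 starts at region end)
  expect_false("g2" %in% ann$genes[[1]])
  # symmetry of the overlap predicate
  regions_as_genes <- tibble::tibble(gene_id = "r", chrom = "chr1",
                                     start = 1500, end = 6500, strand = "+")
  genes_as_regions <- tibble::tibble(chrom = "chr1", start = genes$start,
                                     end = genes$end)
  back <- annotate_genes(genes_as_regions, regions_as_genes)
  expect_equal(vapply(back$genes, length, 1L) > 0,
               c(TRUE, FALSE, FALSE))
})

test_that("a gene spanning two regions is listed once in the PSG set", {
  genes <- tibble::tibble(gene_id = "gX", chrom = "chr1",
                          start = 1000, end = 20000, strand = "+")
  reg <- tibble::tibble(chrom = "chr1", start = c(0, 10000), end = c(5000, 15000),
                        member_windows = 1L, max_fst = 1, max_log2_ratio = 1)
  ann <- annotate_genes(reg, genes)
  expect_equal(vapply(ann$genes, length, 1L), c(1L, 1L))
  expect_equal(psg_genes(ann), "gX")
})

test_that("planted sweeps are recovered at the joint top-5% threshold", {
  # direction log2(piA/piB) with sweeps eroding diversity in B
  regions <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(2e5, 6e5, 1e5, 7e5), end = c(2.2e5, 6.2e5, 1.2e5, 7.2e5),
    F_local = 0.8, reduction = 8, target_pop = "B"
  )
  hits <- 0; total <- 0
  for (seed in 1:10) {
    cfg <- sim_config(seed = 100 + seed, n_chrom_sim = 2, chrom_length = 1e6,
                      F_background = 0.1, sweep_regions = regions,
                      ld_decay_length = 10000)
    gm <- simulate_genotypes(simulate_frequencies(cfg), cfg)
    fl <- select_top_windows(window_stats(gm, direction = c("A", "B")), q = 0.05)
    flg <- dplyr::filter(fl, .data$flagged)
    for (k in seq_len(nrow(regions))) {
      total <- total + 1
      ov <- any(flg$chrom == regions$chrom[k] &
                  flg$start < regions$end[k] & flg$end > regions$start[k])
      hits <- hits + ov
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("null flagged windows are uniformly placed across the genome", {
  rejections <- 0
  for (seed in 1:10) {
    cfg <- sim_config(seed = 200 + seed, n_pop_a = 16, n_pop_b = 16,
                      n_chrom_sim = 2, chrom_length = 1e6, F_background = 0.1,
                      ld_decay_length = 10000)
    gm <- simulate_genotypes(simulate_frequencies(cfg), cfg)
    fl <- select_top_windows(window_stats(gm), q = 0.05)
    # intersection of marginal top sets: at most ceil(qN)/N without ties
    expect_lte(mean(fl$flagged[fl$usable]), 0.05 + 1 / sum(fl$usable) + 1e-9)
    flg <- which(fl$flagged)
    if (length(flg) >= 2) {
      bins <- cut(flg, breaks = seq(0, nrow(fl), length.out = 11),
                  include.lowest = TRUE)
      p <- suppressWarnings(chisq.test(table(bins))$p.value)
      if (!is.na(p) && p < 0.01) rejections <- rejections + 1
    }
  }
  expect_lte(rejections, 2)
})
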