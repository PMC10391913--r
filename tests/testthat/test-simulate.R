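test_that("frequency draws are seeded and respect the Balding-Nichols shape", {
  cfg <- sim_config(seed = 41, n_chrom_sim = 1, chrom_length = 1e5)
  t1 <- simulate_frequencies(cfg)
  t2 <- simulate_frequencies(cfg)
  expect_identical(t1$sites, t2$sites)

  # F -> 0 limit: population frequencies collapse onto the ancestral one
  cfg0 <- sim_config(seed = 42, n_chrom_sim = 1, chrom_length = 1e5,
                     F_background = 1e-4)
  t0 <- simulate_frequencies(cfg0)
  expect_lt(max(abs(t0$sites$freq_a - t0$sites$p_anc)), 0.1)

  # F = 0.5 around p = 0.5 is the U-shaped Beta(1/2, 1/2):
  # P(freq < 0.1 or > 0.9) = 2 * pbeta(0.1, .5, .5) ~ 0.41 > 0.35
  set.seed(43)
  draws <- rbeta(10000, 0.5 * (1 - 0.5) / 0.5, 0.5 * (1 - 0.5) / 0.5)
  expect_gt(mean(draws < 0.1 | draws > 0.9), 0.35)
  expect_equal(2 * pbeta(0.1, 0.5, 0.5), 0.4097, tolerance = 1e-4)
})

test_that("overlapping sweep regions are rejected", {
  sw <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(10000, 20000),
                       F_local = 0.5, reduction = 4, target_pop = "B")
  expect_error(sim_config(seed = 1, sweep_regions = sw), "overlap")
})

test_that("sweep regions divide the target population's heterozygosity", {
  sw <- tibble::tibble(chrom = "chr1", start = 2e5, end = 4e5,
                       F_local = 0.5, reduction = 5, target_pop = "B")
  cfg <- sim_config(seed = 44, n_chrom_sim = 1, chrom_length = 1e6,
                    F_background = 0.1, sweep_regions = sw)
  truth <- simulate_frequencies(cfg)
  st <- truth$sites
  het <- function(q) 2 * q * (1 - q)
  # the boundary push divides per-site expected heterozygosity exactly by 5
  # relative to the same sites' untransformed draw; compare sweep vs outside
  ratio <- mean(het(st$freq_b[st$in_sweep])) / mean(het(st$freq_b[!st$in_sweep]))
  expect_lt(ratio, 1 / 3)
  expect_gt(mean(het(st$freq_a[st$in_sweep])), mean(het(st$freq_b[st$in_sweep])))
})

test_that("genotype draws are seeded and LD vanishes as the decay length -> 0", {
  cfg <- sim_config(seed = 45, n_pop_a = 8, n_pop_b = 8, n_chrom_sim = 1,
                    chrom_length = 1e5)
  truth <- simulate_frequencies(cfg)
  g1 <- simulate_genotypes(truth, cfg)
  g2 <- simulate_genotypes(truth, cfg)
  expect_identical(g1$dosage, g2$dosage)

  adj_minus_bg <- numeric(5)
  for (seed in 1:5) {
    cfg0 <- sim_config(seed = 800 + seed, n_pop_a = 40, n_pop_b = 2,
                       n_chrom_sim = 1, chrom_length = 1e5, snp_density = 0.003,
                       F_background = 0.05, ld_decay_length = 0)
    gm <- simulate_genotypes(simulate_frequencies(cfg0), cfg0)
    ga <- subset_geno(gm, samples = which(unname(gm$pops) == "A"))
    m <- n_sites(ga)
    adj <- mean(vapply(seq_len(m - 1), function(k) {
      genotype_r2(ga$dosage[k, ], ga$dosage[k + 1, ])
    }, numeric(1)), na.rm = TRUE)
    set.seed(seed)
    far <- mean(vapply(1:200, function(...) {
      ij <- sample.int(m, 2)
      genotype_r2(ga$dosage[ij[1], ], ga$dosage[ij[2], ])
    }, numeric(1)), na.rm = TRUE)
    adj_minus_bg[seed] <- abs(adj - far)
  }
  expect_lt(max(adj_minus_bg), 0.05)
})

test_that("windowed FST recovers the divergence parameter near the null", {
  cfg <- sim_config(seed = 46, n_chrom_sim = 1, chrom_length = 1e6,
                    F_background = 0.005, ld_decay_length = 10000)
  gm <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  w <- window_stats(gm)
  expect_lt(abs(mean(w$fst, na.rm = TRUE)), 0.02)
})

test_that("phenotypes are seeded and carry the requested architecture", {
  cfg <- sim_config(seed = 47, n_pop_a = 20, n_pop_b = 20, n_chrom_sim = 1,
                    chrom_length = 2e5, causal_snps = data.frame(site = 10, weight = 1),
                    h2_causal = 0.2, h2_background = 0.3)
  truth <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(truth, cfg)
  p1 <- simulate_phenotypes(gm, truth, cfg)
  p2 <- simulate_phenotypes(gm, truth, cfg)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "effects")$site, 10)
  bad <- cfg; bad$causal_snps <- data.frame(site = 1e6, weight = 1)
  expect_error(simulate_phenotypes(gm, truth, bad), "out of range")
})

test_that("null phenotypes are standard noise", {
  cfg <- sim_config(seed = 48, n_pop_a = 150, n_pop_b = 150, n_chrom_sim = 1,
                    chrom_length = 1e5, h2_background = 0)
  truth <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(truth, cfg)
  ph <- simulate_phenotypes(gm, truth, cfg)
  expect_equal(sd(ph$trait), 1, tolerance = 0.15)
  expect_equal(stats::shapiro.test(ph$trait)$p.value > 1e-3, TRUE)
})

test_that("fixtures round-trip and the sidecar matches the configuration", {
  sw <- tibble::tibble(chrom = "chr1", start = 2e4, end = 5e4,
                       F_local = 0.6, reduction = 4, target_pop = "B")
  cfg <- sim_config(seed = 49, n_pop_a = 6, n_pop_b = 6, n_chrom_sim = 1,
                    chrom_length = 1e5, sweep_regions = sw,
                    causal_snps = data.frame(site = 5, weight = 1),
                    h2_causal = 0.2, h2_background = 0.2)
  truth <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(truth, cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(gm, truth, cfg, dir)
  back <- read_vcf(paths$vcf, paths$pops)
  expect_identical(back$dosage, gm$dosage)

  genes <- read_genes(paths$gff3)
  # gene tiling interval < region length => every sweep region hits a gene
  expect_gt(length(overlapping_genes <- annotate_genes(
    tibble::tibble(chrom = sw$chrom, start = sw$start, end = sw$end),
    genes)$genes[[1]]), 0)

  sidecar <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(sidecar$causal_snps$site, 5)
  expect_equal(sidecar$F_background, cfg$F_background)

  ph <- read_phenotypes(paths$pheno)
  expect_equal(names(ph), c("sample", "trait"))
  deg <- read_deg_table(paths$deg)
  expect_equal(nrow(deg), nrow(genes))

  # end-to-end determinism: regenerating yields byte-identical files
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture(gm, truth, cfg, dir2)
  for (f in c("vcf", "gff3", "pheno", "deg")) {
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  }
})
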