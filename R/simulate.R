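#' Configuration for the two-population genotype simulator
#'
#' The simulator draws per-site population allele frequencies from the
#' Balding-Nichols model (a Beta distribution around a shared ancestral
#' frequency, parameterized by a divergence coefficient `F` that windowed
#' Weir-Cockerham FST targets), generates haplotypes with first-order copy
#' correlation so r^2 decays roughly exponentially with distance, and builds
#' a continuous phenotype from planted causal SNPs plus a polygenic
#' background and noise.
#'
#' Defaults mirror a 32 + 32 two-breed resequencing design.
#'
#' @param n_pop_a,n_pop_b Diploid sample sizes. Default 32 each.
#' @param n_chrom_sim Number of simulated chromosomes. Default 2.
#' @param chrom_length Chromosome length, bp. Default 1e6.
#' @param snp_density Expected SNPs per bp. Default 0.002 (one SNP per
#'   500 bp, i.e. ~10 per 5-kb window).
#' @param F_background Balding-Nichols divergence in (0, 1). Default 0.1.
#' @param sweep_regions Data frame of planted divergent regions with columns
#'   `chrom`, `start`, `end` (0-based half-open bp), `F_local`,
#'   `reduction` (factor by which the target population's expected
#'   heterozygosity is divided; >= 1) and `target_pop` (population label).
#'   Regions may not overlap. Default: none.
#' @param ld_decay_length Length scale (bp) of the exponential r^2 decay.
#'   Default 25000. Zero gives independent sites.
#' @param causal_snps Data frame `site` (index into the simulated site
#'   table), `weight` (relative effect size; rescaled jointly so the causal
#'   component explains `h2_causal` of the phenotypic variance). Default:
#'   none.
#' @param h2_causal Phenotypic variance fraction of the causal component
#'   (ignored when there are no causal SNPs). Default 0.2.
#' @param h2_background Polygenic variance fraction, in `[0, 1)`.
#'   Default 0.3.
#' @param pop_names Labels of the two populations. Default `c("A", "B")`.
#' @param gene_length,gene_spacing Tiling of simulated gene annotations:
#'   genes of `gene_length` bp every `gene_spacing` bp. Defaults 2000 and
#'   10000.
#' @param deg_frac Fraction of sweep-region genes given a strong expression
#'   difference in the simulated DEG table. Default 0.8.
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pop_a = 32, n_pop_b = 32, n_chrom_sim = 2,
                       chrom_length = 1e6, snp_density = 0.002,
                       F_background = 0.1, sweep_regions = NULL,
                       ld_decay_length = 25000, causal_snps = NULL,
                       h2_causal = 0.2, h2_background = 0.3,
                       pop_names = c("A", "B"),
                       gene_length = 2000, gene_spacing = 10000,
                       deg_frac = 0.8, seed) {
  if (missing(seed)) abort("sim_config: a seed is mandatory")
  stopifnot(F_background > 0, F_background < 1,
            h2_background >= 0, h2_background < 1,
            h2_causal >= 0, h2_causal < 1,
            h2_causal + h2_background < 1,
            ld_decay_length >= 0, length(pop_names) == 2)
  if (!is.null(sweep_regions)) {
    sweep_regions <- as_tibble(sweep_regions)
    stopifnot(all(sweep_regions$F_local > 0 & sweep_regions$F_local < 1),
              all(sweep_regions$reduction >= 1),
              all(sweep_regions$target_pop %in% pop_names))
    check_no_overlap(sweep_regions)
  }
  if (!is.null(causal_snps)) causal_snps <- as_tibble(causal_snps)
  structure(
    list(n_pop_a = n_pop_a, n_pop_b = n_pop_b, n_chrom_sim = n_chrom_sim,
         chrom_length = chrom_length, snp_density = snp_density,
         F_background = F_background, sweep_regions = sweep_regions,
         ld_decay_length = ld_decay_length, causal_snps = causal_snps,
         h2_causal = h2_causal, h2_background = h2_background,
         pop_names = pop_names, gene_length = gene_length,
         gene_spacing = gene_spacing, deg_frac = deg_frac,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

check_no_overlap <- function(regions) {
  by_chrom <- split(regions, regions$chrom)
  for (r in by_chrom) {
    r <- r[order(r$start), ]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
      abort("sweep regions may not overlap")
    }
  }
  invisible(regions)
}

#' Draw per-site ancestral and population allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each population's
#' frequency is Beta(`p (1-F)/F`, `(1-p)(1-F)/F`) with `F = F_background`,
#' except inside planted sweep regions where `F = F_local` and the target
#' population's frequency is additionally pushed toward the nearer boundary
#' so that its expected heterozygosity is divided exactly by the region's
#' `reduction` factor.
#'
#' @param cfg A [sim_config()].
#' @return A `ground_truth` list: `sites` (tibble `chrom`, `pos`, `p_anc`,
#'   `freq_a`, `freq_b`, `in_sweep`), `sweep_regions`, `causal_snps`,
#'   `F_background` and `pop_names`.
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom_sim))
  sites <- purrr::map_dfr(chroms, function(ch) {
    m <- round(cfg$chrom_length * cfg$snp_density)
    tibble(chrom = ch,
           pos = sort(sample.int(cfg$chrom_length, m)))
  })
  m <- nrow(sites)
  sites$p_anc <- runif(m, 0.05, 0.95)

  F_a <- rep(cfg$F_background, m)
  F_b <- rep(cfg$F_background, m)
  in_sweep <- rep(FALSE, m)
  target_a <- rep(FALSE, m)
  target_b <- rep(FALSE, m)
  if (!is.null(cfg$sweep_regions)) {
    for (k in seq_len(nrow(cfg$sweep_regions))) {
      rg <- cfg$sweep_regions[k, ]
      idx <- sites$chrom == rg$chrom &
        (sites$pos - 1) >= rg$start & (sites$pos - 1) < rg$end
      in_sweep <- in_sweep | idx
      F_a[idx] <- rg$F_local
      F_b[idx] <- rg$F_local
      if (rg$target_pop == cfg$pop_names[1]) target_a[idx] <- TRUE
      else target_b[idx] <- TRUE
    }
  }
  bn_draw <- function(p, F) rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  freq_a <- bn_draw(sites$p_anc, F_a)
  freq_b <- bn_draw(sites$p_anc, F_b)
  reduction_at <- reduction_vector(sites, cfg)
  freq_a[target_a] <- reduce_het(freq_a[target_a], reduction_at[target_a])
  freq_b[target_b] <- reduce_het(freq_b[target_b], reduction_at[target_b])
  sites$freq_a <- freq_a
  sites$freq_b <- freq_b
  sites$in_sweep <- in_sweep

  structure(
    list(sites = sites, sweep_regions = cfg$sweep_regions,
         causal_snps = cfg$causal_snps, F_background = cfg$F_background,
         pop_names = cfg$pop_names),
    class = "ground_truth"
  )
}

reduction_vector <- function(sites, cfg) {
  out <- rep(1, nrow(sites))
  if (is.null(cfg$sweep_regions)) return(out)
  for (k in seq_len(nrow(cfg$sweep_regions))) {
    rg <- cfg$sweep_regions[k, ]
    idx <- sites$chrom == rg$chrom &
      (sites$pos - 1) >= rg$start & (sites$pos - 1) < rg$end
    out[idx] <- rg$reduction
  }
  out
}

## push frequency toward the nearer boundary so q'(1-q') = q(1-q)/R:
## exact per-site division of expected heterozygosity 2q(1-q) by R
reduce_het <- function(q, R) {
  disc <- sqrt(pmax(0, 1 - 4 * q * (1 - q) / R))
  ifelse(q <= 0.5, (1 - disc) / 2, (1 + disc) / 2)
}

#' Simulate genotypes from ground-truth frequencies
#'
#' Haplotypes carry a latent uniform "frequency quantile" that is copied
#' from the previous site with probability `exp(-d / (2 * ld_decay_length))`
#' (`d` the bp separation) and redrawn otherwise; the allele at a site is 1
#' when the latent uniform falls below the population frequency. Sharing the
#' quantile across nearby sites makes r^2 between sites decay approximately
#' as `exp(-d / ld_decay_length)` (the allele correlation decays with scale
#' `2 * ld_decay_length` and r^2 is its square). Two haplotypes per diploid
#' sum to the dosage.
#'
#' @param truth A `ground_truth` from [simulate_frequencies()].
#' @param cfg The matching [sim_config()].
#' @return A [geno_matrix()] with samples `A01...` / `B01...` labeled by
#'   population.
#' @export
simulate_genotypes <- function(truth, cfg) {
  set.seed(cfg$seed + 1L)
  st <- truth$sites
  nA <- cfg$n_pop_a; nB <- cfg$n_pop_b
  H <- 2L * (nA + nB)
  hap_pop <- rep(c(1L, 2L), c(2L * nA, 2L * nB))
  alle <- matrix(0L, nrow(st), H)
  for (ch in unique(st$chrom)) {
    rows <- which(st$chrom == ch)
    q <- cbind(st$freq_a[rows], st$freq_b[rows])
    pos <- st$pos[rows]
    u <- runif(H)
    for (k in seq_along(rows)) {
      if (k > 1) {
        rho <- if (cfg$ld_decay_length > 0) {
          exp(-(pos[k] - pos[k - 1]) / (2 * cfg$ld_decay_length))
        } else 0
        redraw <- runif(H) >= rho
        u[redraw] <- runif(sum(redraw))
      }
      alle[rows[k], ] <- as.integer(u < q[k, hap_pop])
    }
  }
  dosage <- alle[, seq(1, H, by = 2), drop = FALSE] +
    alle[, seq(2, H, by = 2), drop = FALSE]
  samples <- c(sprintf("%s%02d", cfg$pop_names[1], seq_len(nA)),
               sprintf("%s%02d", cfg$pop_names[2], seq_len(nB)))
  pops <- setNames(rep(cfg$pop_names, c(nA, nB)), samples)
  ra <- sample_ref_alt(nrow(st))
  geno_matrix(chrom = st$chrom, pos = st$pos, ref = ra$ref, alt = ra$alt,
              dosage = dosage, samples = samples, pops = pops)
}

sample_ref_alt <- function(m) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a continuous phenotype with causal SNPs
#'
#' `y = causal + polygenic + noise`, standardized so the three components
#' have expected variance fractions `h2_causal` (when causal SNPs exist),
#' `h2_background` and the remainder. The causal component is the weighted
#' dosage sum over `cfg$causal_snps`, jointly rescaled to its target
#' fraction; the polygenic term is drawn with covariance proportional to the
#' kinship of `gm`; units are arbitrary (micrometer-like trait scale).
#'
#' @param gm A [geno_matrix()] from [simulate_genotypes()].
#' @param truth The matching `ground_truth` (realized effects are recorded
#'   into its `causal_snps`).
#' @param cfg The matching [sim_config()].
#' @return A tibble `sample`, `trait`; the realized per-SNP effects are
#'   attached as attribute `effects`.
#' @export
simulate_phenotypes <- function(gm, truth, cfg) {
  set.seed(cfg$seed + 2L)
  n <- n_samples(gm)
  causal <- rep(0, n)
  h2c <- 0
  effects <- NULL
  if (!is.null(cfg$causal_snps) && nrow(cfg$causal_snps) > 0) {
    if (any(cfg$causal_snps$site < 1 | cfg$causal_snps$site > n_sites(gm))) {
      abort("causal SNP index out of range")
    }
    Zc <- gm$dosage[cfg$causal_snps$site, , drop = FALSE]
    raw <- drop(crossprod(Zc, cfg$causal_snps$weight))
    v <- var(raw)
    if (v == 0) abort("causal SNPs are monomorphic; no causal variance")
    h2c <- cfg$h2_causal
    scale_f <- sqrt(h2c / v)
    causal <- (raw - mean(raw)) * scale_f
    effects <- tibble(site = cfg$causal_snps$site,
                      effect = cfg$causal_snps$weight * scale_f)
  }
  polygenic <- rep(0, n)
  if (cfg$h2_background > 0) {
    K <- kinship_matrix(gm)
    ev <- eigen(K, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    u <- drop(L %*% rnorm(n))
    mean_diag <- mean(diag(K))
    polygenic <- u * sqrt(cfg$h2_background / mean_diag)
  }
  noise <- rnorm(n, sd = sqrt(1 - h2c - cfg$h2_background))
  out <- tibble(sample = gm$samples, trait = causal + polygenic + noise)
  attr(out, "effects") <- effects
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d + %d diploids, %d chrom x %g bp, density %g, F = %g, LD scale %g bp, seed %d\n",
    x$n_pop_a, x$n_pop_b, x$n_chrom_sim, x$chrom_length, x$snp_density,
    x$F_background, x$ld_decay_length, x$seed
  ))
  if (!is.null(x$sweep_regions)) {
    cat(sprintf("  %d planted sweep region(s)\n", nrow(x$sweep_regions)))
  }
  if (!is.null(x$causal_snps)) {
    cat(sprintf("  %d causal SNP(s), h2_causal %.2f, h2_background %.2f\n",
                nrow(x$causal_snps), x$h2_causal, x$h2_background))
  }
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d sites (%d in sweeps), F = %g\n",
              nrow(x$sites), sum(x$sites$in_sweep), x$F_background))
  invisible(x)
}
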