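#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 p (1 - p) n / (n - 1)` with
#' `p = alt_count / n_chrom`, i.e. the fraction of chromosome pairs in the
#' sample that differ at the site.
#'
#' @param alt_count Number of alternate alleles observed (vectorized).
#' @param n_chrom Number of non-missing chromosomes sampled (>= 2).
#' @return Per-site diversity in `[0, 1]`; `NA` where `n_chrom < 2`.
#' @export
site_pi <- function(alt_count, n_chrom) {
  stopifnot(all(alt_count >= 0 & alt_count <= n_chrom, na.rm = TRUE))
  p <- alt_count / n_chrom
  out <- 2 * p * (1 - p) * n_chrom / (n_chrom - 1)
  out[n_chrom < 2] <- NA_real_
  out
}

#' Weir-Cockerham variance components for one site, two populations
#'
#' Computes the among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) components of the Weir & Cockerham (1984)
#' method-of-moments FST estimator from diploid dosages. The single-site
#' estimate is `theta = a / (a + b + c)`; windowed estimates sum the
#' components first ([windowed_fst()]).
#'
#' @param pop_a,pop_b Dosage vectors (0/1/2, `NA` missing) for the two
#'   populations at one site.
#' @return A list with elements `a`, `b`, `c` and `theta` (`NaN` when the
#'   site is monomorphic so all components vanish).
#' @export
wc_fst_site <- function(pop_a, pop_b) {
  counts <- function(g) {
    g <- g[!is.na(g)]
    c(n = length(g), p = if (length(g)) sum(g) / (2 * length(g)) else NA,
      h = if (length(g)) mean(g == 1) else NA)
  }
  ca <- counts(pop_a); cb <- counts(pop_b)
  if (ca[["n"]] < 2 || cb[["n"]] < 2) {
    abort("wc_fst_site: both populations need >= 2 genotyped diploids",
          class = "divscan_fst_insufficient")
  }
  comp <- wc_components(
    n1 = ca[["n"]], n2 = cb[["n"]],
    p1 = ca[["p"]], p2 = cb[["p"]],
    h1 = ca[["h"]], h2 = cb[["h"]]
  )
  comp$theta <- with(comp, a / (a + b + c))
  comp
}

## vectorized Weir-Cockerham (1984) components for r = 2 populations;
## n = diploid sample sizes, p = alt allele freqs, h = observed het fractions
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed diversity, FST and log2 pi-ratio over a genotype matrix
#'
#' Cuts each chromosome into windows of `window_size` bp (0-based half-open,
#' advancing by `step`; the default makes them non-overlapping) and computes,
#' per window: variant-site count, per-population nucleotide diversity
#' (sum of [site_pi()] over variant sites divided by the full window size, so
#' monomorphic positions contribute zero), the ratio-of-sums Weir-Cockerham
#' FST, and `log2` of the diversity ratio in the requested direction.
#'
#' A window is `usable` for quantile ranking when it has at least `min_sites`
#' variant sites, both diversities are positive (so the ratio is finite) and
#' its FST is defined. Negative FST estimates are reported as computed.
#'
#' @param gm A [geno_matrix()] with exactly two population labels.
#' @param window_size Window width in bp. Default 5000.
#' @param step Window step in bp; default `window_size` (non-overlapping).
#' @param direction Length-2 character vector `c(numerator, denominator)` of
#'   population labels for the pi ratio. Default: the two labels in sorted
#'   order, i.e. `log2(pi_first / pi_second)`.
#' @param min_sites Minimum variant sites for a window to be `usable`.
#'   Default 3.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites`, `n_fst_sites`, `pi_a`, `pi_b` (diversity of the first and
#'   second sorted population label; the mapping is recorded in attribute
#'   `pops_ab`), `fst`, `log2_pi_ratio` and `usable`.
#' @export
window_stats <- function(gm, window_size = 5000, step = window_size,
                         direction = NULL, min_sites = 3) {
  stopifnot(window_size > 0, step > 0, step <= window_size)
  labs <- pop_labels(gm)
  if (length(labs) != 2) abort("window_stats needs exactly two population labels")
  direction <- direction %||% labs
  if (!all(direction %in% labs) || length(direction) != 2 ||
      direction[1] == direction[2]) {
    abort("`direction` must name the two population labels (numerator, denominator)")
  }
  ia <- pop_index(gm, labs[1]); ib <- pop_index(gm, labs[2])

  persite <- site_components(gm$dosage, ia, ib)
  pos0 <- gm$pos - 1L

  out <- purrr::map_dfr(unique(gm$chrom), function(ch) {
    on_ch <- which(gm$chrom == ch)
    p0 <- pos0[on_ch]
    starts <- seq(0L, max(p0), by = step)
    purrr::map_dfr(starts, function(s) {
      idx <- on_ch[p0 >= s & p0 < s + window_size]
      summarize_window(ch, s, s + window_size, idx, persite, window_size)
    })
  })

  num <- if (direction[1] == labs[1]) out$pi_a else out$pi_b
  den <- if (direction[2] == labs[2]) out$pi_b else out$pi_a
  out$log2_pi_ratio <- log2_pi_ratio(num, den)
  out$usable <- out$n_sites >= min_sites & !is.na(out$log2_pi_ratio) &
    !is.na(out$fst)
  attr(out, "pops_ab") <- setNames(labs, c("pi_a", "pi_b"))
  attr(out, "direction") <- direction
  attr(out, "window_size") <- window_size
  out
}

## per-site pi for each population and WC components, vectorized over sites
site_components <- function(dosage, ia, ib) {
  stat_pop <- function(idx) {
    d <- dosage[, idx, drop = FALSE]
    n <- rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    list(
      n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
      h = ifelse(n > 0, rowSums(d == 1, na.rm = TRUE) / n, NA_real_),
      pi = ifelse(n >= 1, site_pi(alt, 2 * n), NA_real_)
    )
  }
  sa <- stat_pop(ia); sb <- stat_pop(ib)
  ok <- sa$n >= 2 & sb$n >= 2
  comp <- wc_components(sa$n, sb$n, sa$p, sb$p, sa$h, sb$h)
  comp$a[!ok] <- NA_real_; comp$b[!ok] <- NA_real_; comp$c[!ok] <- NA_real_
  variant <- rowSums(dosage, na.rm = TRUE) > 0 &
    rowSums(dosage, na.rm = TRUE) < 2 * rowSums(!is.na(dosage))
  list(pi_a = sa$pi, pi_b = sb$pi, a = comp$a, b = comp$b, c = comp$c,
       fst_ok = ok, variant = variant)
}

summarize_window <- function(ch, s, e, idx, ps, window_size) {
  v <- idx[ps$variant[idx]]
  f <- idx[ps$fst_ok[idx]]
  denom <- sum(ps$a[f] + ps$b[f] + ps$c[f], na.rm = TRUE)
  tibble(
    chrom = ch, start = s, end = e,
    n_sites = length(v), n_fst_sites = length(f),
    pi_a = sum(ps$pi_a[v], na.rm = TRUE) / window_size,
    pi_b = sum(ps$pi_b[v], na.rm = TRUE) / window_size,
    fst = if (length(f) > 0 && denom > 0) sum(ps$a[f], na.rm = TRUE) / denom
          else NA_real_
  )
}

#' Windowed nucleotide diversity for one population
#'
#' Convenience wrapper around the [window_stats()] machinery returning the
#' per-window diversity of a single population.
#'
#' @param gm A [geno_matrix()].
#' @param population Population label to keep.
#' @inheritParams window_stats
#' @return A tibble `chrom`, `start`, `end`, `n_sites`, `pi`.
#' @export
windowed_pi <- function(gm, population, window_size = 5000, step = window_size) {
  idx <- pop_index(gm, population)
  if (length(idx) == 0) abort(paste0("no samples labeled ", population))
  d <- gm$dosage[, idx, drop = FALSE]
  n <- rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  pi <- ifelse(n >= 1, site_pi(alt, 2 * n), NA_real_)
  variant <- alt > 0 & alt < 2 * n
  pos0 <- gm$pos - 1L
  purrr::map_dfr(unique(gm$chrom), function(ch) {
    on_ch <- which(gm$chrom == ch)
    p0 <- pos0[on_ch]
    starts <- seq(0L, max(p0), by = step)
    purrr::map_dfr(starts, function(s) {
      idx2 <- on_ch[p0 >= s & p0 < s + window_size]
      v <- idx2[variant[idx2]]
      tibble(chrom = ch, start = s, end = s + window_size,
             n_sites = length(v),
             pi = sum(pi[v], na.rm = TRUE) / window_size)
    })
  })
}

#' Windowed Weir-Cockerham FST
#'
#' Ratio-of-sums (weighted) windowed FST: per window,
#' `sum(a) / sum(a + b + c)` over sites where both populations have at least
#' two genotyped diploids. Windows with no usable sites are `NA`.
#'
#' @inheritParams window_stats
#' @return A tibble `chrom`, `start`, `end`, `n_fst_sites`, `fst`.
#' @export
windowed_fst <- function(gm, window_size = 5000, step = window_size) {
  dplyr::select(
    window_stats(gm, window_size = window_size, step = step, min_sites = 0),
    "chrom", "start", "end", "n_fst_sites", "fst"
  )
}

#' log2 ratio of windowed diversities
#'
#' @param pi_num,pi_den Per-window diversity vectors (numerator and
#'   denominator populations).
#' @return `log2(pi_num / pi_den)`; `NA` (unusable) where either diversity is
#'   zero or missing.
#' @export
log2_pi_ratio <- function(pi_num, pi_den) {
  out <- ifelse(!is.na(pi_num) & !is.na(pi_den) & pi_num > 0 & pi_den > 0,
                log2(pi_num / pi_den), NA_real_)
  out
}
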