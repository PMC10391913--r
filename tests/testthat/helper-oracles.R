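# Independent re-implementation of the Weir & Cockerham (1984) two-population
# variance components, written as literal sums over populations (r = 2) so it
# shares no code with the package's vectorized version.
wc_oracle <- function(geno_a, geno_b) {
  gs <- list(geno_a[!is.na(geno_a)], geno_b[!is.na(geno_b)])
  r <- 2
  n <- vapply(gs, length, numeric(1))
  p <- vapply(gs, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(gs, function(g) sum(g == 1) / length(g), numeric(1))
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  list(a = a, b = b, c = hbar / 2)
}

# per-site diversity by enumerating all chromosome pairs
pi_enum <- function(alt_count, n_chrom) {
  alleles <- c(rep(1, alt_count), rep(0, n_chrom - alt_count))
  pr <- utils::combn(n_chrom, 2)
  mean(alleles[pr[1, ]] != alleles[pr[2, ]])
}

# least-squares best topology by enumerating every unrooted topology
# (feasible for <= 6 leaves); returns the winning phylo
best_topology_enum <- function(dm) {
  labels <- rownames(dm)
  stopifnot(length(labels) <= 6)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
  rss <- vapply(trees, function(tr) {
    f <- phangorn::nnls.tree(as.dist(dm), tr, method = "unrooted")
    sum((as.matrix(stats::cophenetic(f))[labels, labels] - dm)^2)
  }, numeric(1))
  trees[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
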