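#' Per-site allele-sharing distance between two genotypes
#'
#' The four printed genotype-pair cases at a biallelic site (say A/C):
#' identical homozygotes 0; homozygote vs heterozygote 0.5; both
#' heterozygous 0.5; opposite homozygotes 1. For dosage-coded genotypes this
#' is `|g_i - g_j| / 2` for the homozygote cases and 0.5 whenever either
#' genotype is heterozygous — the unique consistent extension of the case
#' table (AC vs AC shares one allele on average, hence 0.5 rather than 0).
#'
#' @param g_i,g_j Alt-allele dosages (0, 1, 2 or `NA`), vectorized.
#' @return Contribution in `{0, 0.5, 1}`; `NA` where either input is missing
#'   (the site is excluded for the pair).
#' @export
site_distance <- function(g_i, g_j) {
  out <- ifelse(g_i == 1 | g_j == 1, 0.5, abs(g_i - g_j) / 2)
  out[is.na(g_i) | is.na(g_j)] <- NA_real_
  out
}

#' Mean allele-sharing distance between two samples
#'
#' Mean of [site_distance()] over pairwise-complete sites (sites where both
#' samples are genotyped); the divisor is the number of shared genotyped
#' sites, so the distance lies in `[0, 1]` regardless of missingness.
#'
#' @param gm A [geno_matrix()].
#' @param i,j Sample identifiers or column indices.
#' @return The mean per-site distance.
#' @export
pairwise_distance <- function(gm, i, j) {
  if (is.character(i)) i <- match(i, gm$samples)
  if (is.character(j)) j <- match(j, gm$samples)
  d <- site_distance(gm$dosage[, i], gm$dosage[, j])
  if (all(is.na(d))) {
    abort(sprintf("no shared genotyped sites for pair (%s, %s)",
                  gm$samples[i], gm$samples[j]))
  }
  mean(d, na.rm = TRUE)
}

#' Allele-sharing distance matrix
#'
#' All-pairs [pairwise_distance()]. Since the per-site contribution is
#' `|g_i - g_j| / 2` except that heterozygote-involving pairs are fixed at
#' 0.5 — and `|g_i - g_j| / 2` already equals 0.5 whenever exactly one
#' genotype is heterozygous, while two heterozygotes contribute 0 under the
#' plain difference — the matrix is computed as a Manhattan distance plus a
#' shared-heterozygote correction, both pairwise-complete.
#'
#' @param gm A [geno_matrix()].
#' @return A symmetric numeric matrix with sample dimnames; the per-pair
#'   count of shared genotyped sites is attached as attribute `n_shared`.
#' @export
allele_sharing_dist <- function(gm) {
  x <- t(gm$dosage)
  # dist() rescales the sum by m / m_used under NAs, so dividing by 2m gives
  # the pairwise-complete mean of |diff| / 2 directly
  m <- n_sites(gm)
  base <- as.matrix(dist(x, method = "manhattan")) / (2 * m)
  base[is.na(base)] <- 0
  # add 0.5 per site where both are het (|diff|/2 contributed 0 there)
  het <- t(ifelse(is.na(gm$dosage), NA, as.numeric(gm$dosage == 1)))
  both_het <- as.matrix(dist(het, method = "manhattan"))
  # manhattan on het indicators counts discordant-het sites; shared-het count
  # = (het_i + het_j - discordant) / 2, computed pairwise-complete below
  ok <- !is.na(x)
  n_shared <- ok %*% t(ok)
  het0 <- het; het0[is.na(het0)] <- 0
  het_i_shared <- het0 %*% t(ok)          # het sites of i shared with j
  shared_het <- (het_i_shared + t(het_i_shared) -
                   both_het * n_shared / m) / 2
  if (any(n_shared == 0)) abort("sample pair(s) with no shared genotyped sites")
  d <- base + 0.5 * shared_het / n_shared
  diag(d) <- 0
  dimnames(d) <- list(gm$samples, gm$samples)
  attr(d, "n_shared") <- n_shared
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. By default, negative branch
#' lengths (an artifact of the least-squares step) are clamped to zero with
#' the deficit transferred to the adjacent branch so that tip-to-tip path
#' lengths are approximately preserved; pass `clamp_negative = FALSE` for the
#' raw estimator.
#'
#' @param dm Symmetric distance matrix (or `dist`) with labels.
#' @param clamp_negative Clamp negative branch lengths? Default `TRUE`.
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(dm, clamp_negative = TRUE) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) abort("nj_tree needs at least 3 labels")
  tr <- ape::nj(as.dist(dm))
  if (clamp_negative) tr <- clamp_negative_edges(tr)
  tr
}

clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    child <- tr$edge[e, 2]
    adj <- setdiff(which(tr$edge[, 1] == child | tr$edge[, 2] == child), e)
    if (length(adj) == 0) {  # tip edge: transfer through the parent node
      parent <- tr$edge[e, 1]
      adj <- setdiff(which(tr$edge[, 1] == parent | tr$edge[, 2] == parent), e)
    }
    if (length(adj) > 0) {
      tr$edge.length[adj] <- tr$edge.length[adj] + tr$edge.length[e] / length(adj)
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## canonical internal splits of an unrooted tree: each split is the sorted
## tip-label set on the side NOT containing the first tip, pasted with "|"
tree_splits <- function(tr) {
  tr <- ape::unroot(tr)
  n <- length(tr$tip.label)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  anchor <- tr$tip.label[1]
  out <- unique(unlist(lapply(parts, function(p) {
    tips <- labs[p]
    if (length(tips) <= 1 || length(tips) >= n - 1) return(NULL)
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    paste(sort(side), collapse = "|")
  })))
  out %||% character(0)
}

#' Does a tree contain a given bipartition?
#'
#' @param tr An [ape::phylo] tree.
#' @param tips Character vector of tip labels forming one side of the split.
#' @return `TRUE` if the unrooted tree has an internal edge separating `tips`
#'   from the rest.
#' @export
has_split <- function(tr, tips) {
  n <- length(tr$tip.label)
  other <- setdiff(tr$tip.label, tips)
  if (length(tips) < 2 || length(other) < 2) return(TRUE)  # trivial split
  anchor <- tr$tip.label[1]
  side <- if (anchor %in% tips) other else tips
  paste(sort(side), collapse = "|") %in% tree_splits(tr)
}

#' Bootstrapped neighbor-joining tree from genotypes
#'
#' Builds the allele-sharing NJ tree, then resamples SNP sites (columns)
#' with replacement `n_reps` times, recomputing distances and the NJ tree
#' each time, and counts for each internal split of the original tree the
#' number of replicates containing it.
#'
#' @param gm A [geno_matrix()].
#' @param n_reps Number of bootstrap replicates (>= 1). Default 1000.
#' @param seed Integer seed; replicate site draws are reproducible given it.
#' @param clamp_negative Passed to [nj_tree()].
#' @return An object of class `div_tree`: list with `tree` (the original
#'   [ape::phylo], `node.label` carrying support counts), `splits` (tibble
#'   `split`, `support`), `n_reps`, and `dist` (the original distance
#'   matrix).
#' @export
bootstrap_support <- function(gm, n_reps = 1000, seed = 1,
                              clamp_negative = TRUE) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  d0 <- allele_sharing_dist(gm)
  tr0 <- nj_tree(d0, clamp_negative = clamp_negative)
  splits0 <- tree_splits(tr0)
  support <- setNames(integer(length(splits0)), splits0)
  m <- n_sites(gm)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    gm_b <- subset_geno_unordered(gm, idx)
    tr_b <- nj_tree(allele_sharing_dist(gm_b), clamp_negative = FALSE)
    found <- tree_splits(tr_b)
    hit <- splits0 %in% found
    support[hit] <- support[hit] + 1L
  }
  tr0$node.label <- node_support_labels(tr0, support)
  structure(
    list(tree = tr0,
         splits = tibble(split = splits0, support = unname(support)),
         n_reps = n_reps, dist = d0),
    class = "div_tree"
  )
}

## bootstrap resampling duplicates sites and breaks position ordering, so
## bypass the strict-ordering validator; distances never look at positions
subset_geno_unordered <- function(gm, idx) {
  out <- gm
  out$chrom <- gm$chrom[idx]
  out$pos <- gm$pos[idx]
  out$ref <- gm$ref[idx]
  out$alt <- gm$alt[idx]
  out$dosage <- gm$dosage[idx, , drop = FALSE]
  out$dp <- NULL
  out
}

## map split support counts onto internal node labels for Newick export
node_support_labels <- function(tr, support) {
  n <- length(tr$tip.label)
  labs <- character(tr$Nnode)
  parts <- ape::prop.part(tr)
  plabs <- attr(parts, "labels")
  anchor <- tr$tip.label[1]
  for (k in seq_along(parts)) {
    tips <- plabs[parts[[k]]]
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    side <- if (anchor %in% tips) setdiff(plabs, tips) else tips
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) labs[k] <- as.character(support[[key]])
  }
  labs
}

#' @export
print.div_tree <- function(x, ...) {
  cat(sprintf("<div_tree> %d tips, %d internal splits, %d bootstrap replicates\n",
              length(x$tree$tip.label), nrow(x$splits), x$n_reps))
  top <- dplyr::arrange(x$splits, dplyr::desc(.data$support))
  print(head(top, 5))
  invisible(x)
}

#' Write a bootstrapped tree as Newick
#'
#' Internal-node labels carry bootstrap support counts.
#'
#' @param x A `div_tree` from [bootstrap_support()] or an [ape::phylo].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(x, path) {
  tr <- if (inherits(x, "div_tree")) x$tree else x
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' @method tidy div_tree
#' @export
tidy.div_tree <- function(x, ...) {
  dplyr::mutate(x$splits,
                n_reps = x$n_reps,
                frequency = .data$support / x$n_reps)
}
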