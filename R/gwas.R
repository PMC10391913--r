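#' Genomic relationship (kinship) matrix
#'
#' `K = (1/m) * sum_sites (x - xbar)(x - xbar)'` over the `m` polymorphic
#' sites, with `x` the dosage vector of a site and `xbar` its sample mean.
#' Missing dosages are mean-imputed per site. The result is symmetric
#' positive semi-definite by construction.
#'
#' @param gm A [geno_matrix()].
#' @return A samples-by-samples numeric matrix with sample dimnames.
#' @export
kinship_matrix <- function(gm) {
  Z <- impute_center(gm$dosage)
  poly <- rowSums(Z != 0) > 0
  if (!any(poly)) abort("kinship_matrix: no polymorphic sites")
  Z <- Z[poly, , drop = FALSE]
  K <- crossprod(Z) / nrow(Z)
  dimnames(K) <- list(gm$samples, gm$samples)
  K
}

## mean-impute missing per site (row), then center rows
impute_center <- function(dosage) {
  mu <- rowMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx) > 0) dosage[idx] <- mu[idx[, 1]]
  dosage - rowMeans(dosage)
}

#' Population-structure covariates from the kinship matrix
#'
#' The top `n_pc` eigenvectors of `K` appended to an intercept column.
#' Eigenvector signs are fixed (largest-magnitude entry positive) so
#' repeated runs are identical.
#'
#' @param K A kinship matrix ([kinship_matrix()]) or a [geno_matrix()] (the
#'   kinship is then computed internally).
#' @param n_pc Number of eigenvectors. Default 2. Must be < number of
#'   samples.
#' @return A design matrix with columns `intercept`, `PC1`, ..., `PCn`.
#' @export
structure_covariates <- function(K, n_pc = 2) {
  if (inherits(K, "geno_matrix")) K <- kinship_matrix(K)
  n <- nrow(K)
  if (n_pc >= n) abort("n_pc must be smaller than the sample count")
  X <- matrix(1, n, 1, dimnames = list(rownames(K), "intercept"))
  if (n_pc > 0) {
    ev <- eigen(K, symmetric = TRUE)
    U <- ev$vectors[, seq_len(n_pc), drop = FALSE]
    for (k in seq_len(n_pc)) {
      if (U[which.max(abs(U[, k])), k] < 0) U[, k] <- -U[, k]
    }
    colnames(U) <- paste0("PC", seq_len(n_pc))
    X <- cbind(X, U)
  }
  X
}

#' REML fit of the null mixed model
#'
#' Fits `y = X alpha + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, profiling
#' everything but the variance ratio `lambda = sigma_e^2 / sigma_g^2`.
#' A single eigendecomposition of `K` reduces the problem to a 1-D search
#' over `log10(lambda)` on `[-5, 5]` (grid then local refinement), which is
#' deterministic.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effect design matrix (full column rank; e.g. from
#'   [structure_covariates()]).
#' @param K Kinship matrix aligned with `y` and `X`.
#' @return An object of class `null_lmm`: `lambda`, `sigma_g2`, `sigma_e2`,
#'   `h2` (`sigma_g2 / (sigma_g2 + sigma_e2)`), `loglik` (restricted),
#'   `beta` (covariate effects), plus the cached rotation used by
#'   [assoc_scan()]. Supports [tidy()] and [glance()].
#' @export
fit_null_lmm <- function(y, X, K) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  q <- ncol(X)
  if (qr(X)$rank < q) {
    abort("fit_null_lmm: X is rank deficient; drop linearly dependent columns")
  }
  ev <- eigen(K, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  negrll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (d + delta)
    A <- crossprod(Xt, Xt * w)
    b <- solve(A, crossprod(Xt, yt * w))
    r <- yt - drop(Xt %*% b)
    rss <- sum(w * r^2)
    sg2 <- rss / (n - q)
    0.5 * ((n - q) * (log(2 * pi * sg2) + 1) + sum(log(d + delta)) +
             determinant(A, logarithm = TRUE)$modulus -
             determinant(crossprod(X), logarithm = TRUE)$modulus)
  }
  grid <- seq(-5, 5, length.out = 81)
  vals <- vapply(grid, negrll, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(negrll, c(lo, hi))
  delta <- 10^opt$minimum

  w <- 1 / (d + delta)
  A <- crossprod(Xt, Xt * w)
  beta <- solve(A, crossprod(Xt, yt * w))
  r <- yt - drop(Xt %*% beta)
  sg2 <- sum(w * r^2) / (n - q)
  structure(
    list(
      lambda = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
      h2 = 1 / (1 + delta), loglik = -opt$objective,
      beta = setNames(drop(beta), colnames(X)),
      n = n, q = q,
      rotation = list(U = U, d = d, yt = yt, Xt = Xt)
    ),
    class = "null_lmm"
  )
}

#' @export
print.null_lmm <- function(x, ...) {
  cat(sprintf(
    "<null_lmm> n = %d, q = %d | lambda = %.4g, sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
    x$n, x$q, x$lambda, x$sigma_g2, x$sigma_e2, x$h2
  ))
  invisible(x)
}

#' @method tidy null_lmm
#' @export
tidy.null_lmm <- function(x, ...) {
  tibble(
    term = c(names(x$beta), "sigma_g2", "sigma_e2"),
    estimate = c(unname(x$beta), x$sigma_g2, x$sigma_e2),
    type = c(rep("fixed", length(x$beta)), "variance", "variance")
  )
}

#' @method glance null_lmm
#' @export
glance.null_lmm <- function(x, ...) {
  tibble(lambda = x$lambda, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
         h2 = x$h2, logLik = x$loglik, nobs = x$n)
}

#' Mixed-model association scan
#'
#' Per-SNP generalized least squares of `y` on `[X | dosage]` under the
#' covariance `sigma_g2 (K + lambda I)` with `lambda` estimated once on the
#' null model and fixed across SNPs (the EMMAX approximation). The Wald
#' statistic `beta^2 / se^2` is referred to chi-square(1) for a two-sided
#' p-value. Missing genotypes at a tested SNP are mean-imputed; SNPs
#' monomorphic among the phenotyped samples are skipped and counted
#' (attribute `n_skipped`).
#'
#' @param gm A [geno_matrix()].
#' @param y Phenotype: a numeric vector named by sample, or a two-column
#'   data frame (sample, value). Samples with missing phenotype are dropped
#'   from the scan.
#' @param X Fixed-effect design; default [structure_covariates()] with
#'   `n_pc` eigenvectors.
#' @param K Kinship; default [kinship_matrix()] on the phenotyped samples.
#' @param n_pc Eigenvectors for the default `X`. Default 2.
#' @param refit_per_snp Re-estimate `lambda` for every SNP (exact
#'   single-marker REML; slow, intended for cross-checks on small scans).
#'   Default `FALSE`.
#' @return A tibble with one row per tested SNP: `chrom`, `pos`, `ref`,
#'   `alt`, `beta`, `se`, `wald_p`, `neg_log10_p`, `significant`
#'   (`-log10(p) > 4`). The fitted null model is attached as attribute
#'   `null_fit`.
#' @export
assoc_scan <- function(gm, y, X = NULL, K = NULL, n_pc = 2,
                       refit_per_snp = FALSE) {
  ph <- as_phenotype(y, gm$samples)
  keep <- names(ph)
  gm <- subset_geno(gm, samples = keep)
  if (is.null(K)) K <- kinship_matrix(gm)
  K <- K[keep, keep]
  if (is.null(X)) X <- structure_covariates(K, n_pc = n_pc)
  X <- as.matrix(X)

  null_fit <- fit_null_lmm(ph, X, K)
  rot <- null_fit$rotation
  w <- 1 / (rot$d + null_fit$lambda)
  sw <- sqrt(w)
  n <- null_fit$n; q <- null_fit$q

  G <- impute_center(gm$dosage)            # sites x samples, centered
  mono <- apply(G, 1, function(z) all(z == 0))
  Gt <- tcrossprod(G, t(rot$U))            # rotate: G %*% U

  # whiten, then residualize against the covariates
  Y2 <- sw * rot$yt
  X2 <- sw * rot$Xt
  Qx <- qr(X2)
  yr <- qr.resid(Qx, Y2)
  S2 <- t(Gt) * sw                         # samples x sites, whitened
  Sr <- qr.resid(Qx, S2)

  ss <- colSums(Sr^2)
  sy <- colSums(Sr * yr)
  beta <- sy / ss
  rss <- sum(yr^2) - beta^2 * ss
  dfr <- n - q - 1
  se <- sqrt(pmax(rss, 0) / dfr / ss)
  chi <- (beta / se)^2
  p <- pchisq(chi, df = 1, lower.tail = FALSE)

  out <- tibble(
    chrom = gm$chrom, pos = gm$pos, ref = gm$ref, alt = gm$alt,
    beta = beta, se = se, wald_p = p
  )
  out$beta[mono] <- NA_real_; out$se[mono] <- NA_real_; out$wald_p[mono] <- NA_real_

  if (refit_per_snp) {
    for (s in which(!mono)) {
      f <- fit_null_lmm(ph, cbind(X, snp = G[s, ]), K)
      b <- f$beta[["snp"]]
      # Wald se from the GLS information at the per-SNP lambda
      ws <- 1 / (rot$d + f$lambda)
      Xs <- cbind(rot$Xt, drop(Gt[s, ]))
      Ainv <- solve(crossprod(Xs, Xs * ws))
      out$beta[s] <- b
      out$se[s] <- sqrt(f$sigma_g2 * Ainv[q + 1, q + 1])
      out$wald_p[s] <- pchisq((b / out$se[s])^2, 1, lower.tail = FALSE)
    }
  }

  out$neg_log10_p <- -log10(out$wald_p)
  out$significant <- !is.na(out$neg_log10_p) & out$neg_log10_p > 4
  out <- out[!mono, ]
  if (any(mono)) {
    inform(sprintf("assoc_scan: skipped %d SNP(s) monomorphic among phenotyped samples",
                   sum(mono)))
  }
  attr(out, "null_fit") <- null_fit
  attr(out, "n_skipped") <- sum(mono)
  out
}

## phenotype input -> named numeric vector restricted to genotyped samples,
## NA phenotypes dropped
as_phenotype <- function(y, samples) {
  if (is.data.frame(y)) {
    y <- setNames(as.numeric(y[[2]]), as.character(y[[1]]))
  }
  if (is.null(names(y))) {
    if (length(y) != length(samples)) {
      abort("unnamed phenotype vector must match the sample count")
    }
    names(y) <- samples
  }
  y <- y[names(y) %in% samples]
  y <- y[!is.na(y)]
  if (length(y) < 3) abort("fewer than 3 phenotyped samples")
  y
}

#' Keep significant associations
#'
#' Retains SNPs with `-log10(p)` strictly greater than `threshold`; a SNP at
#' exactly the threshold is dropped.
#'
#' @param res An [assoc_scan()] tibble.
#' @param threshold Significance threshold on `-log10(p)`. Default 4.
#' @return The filtered tibble.
#' @export
significant_snps <- function(res, threshold = 4) {
  dplyr::filter(res, !is.na(.data$neg_log10_p), .data$neg_log10_p > threshold)
}

#' Annotate association hits with genes
#'
#' Each SNP is assigned every gene whose (optionally flank-extended)
#' half-open interval contains its 0-based position; SNPs with no gene get
#' an empty assignment.
#'
#' @param res An association tibble (typically [significant_snps()] output).
#' @param genes A [read_genes()] tibble.
#' @param flank Extension of each gene interval on both sides, bp. Default 0.
#' @return `res` with a `genes` list-column.
#' @export
annotate_hits <- function(res, genes, flank = 0) {
  pos0 <- res$pos - 1L
  res$genes <- purrr::map2(res$chrom, pos0, function(ch, p) {
    hit <- genes$chrom == ch & genes$start - flank <= p & p < genes$end + flank
    genes$gene_id[hit]
  })
  res
}

#' Manhattan plot of an association scan
#'
#' @param res An [assoc_scan()] tibble.
#' @param threshold Significance line on `-log10(p)`. Default 4.
#' @return A ggplot.
#' @export
plot_manhattan <- function(res, threshold = 4) {
  d <- dplyr::filter(res, !is.na(.data$neg_log10_p))
  ggplot2::ggplot(d, ggplot2::aes(.data$pos / 1e6, .data$neg_log10_p,
                                  color = .data$chrom)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "red3") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)))
}

#' Read a phenotype table
#'
#' TSV with a header: a sample-identifier column followed by one or more
#' numeric trait columns; missing values allowed.
#'
#' @param path TSV path.
#' @return A tibble; first column named `sample`.
#' @export
read_phenotypes <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample"
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) abort("duplicate sample ids in phenotype table")
  if (ncol(x) < 2) abort("phenotype table needs at least one trait column")
  x
}
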