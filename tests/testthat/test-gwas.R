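test_that("kinship is the averaged centered outer product", {
  gm <- make_gm(rbind(c(0, 2)))
  K <- kinship_matrix(gm)
  expect_equal(unname(K), matrix(c(1, -1, -1, 1), 2))
  # identical samples give identical rows; K is exactly symmetric
  set.seed(14)
  d <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
  d[, 6] <- d[, 5]
  K2 <- kinship_matrix(make_gm(d))
  expect_equal(K2[5, ], K2[6, ], ignore_attr = TRUE)
  expect_identical(K2, t(K2))
  expect_gte(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(kinship_matrix(make_gm(matrix(1, 5, 4))), "no polymorphic")
})

test_that("structure covariates separate simulated populations on PC1", {
  cfg <- sim_config(seed = 23, n_pop_a = 12, n_pop_b = 12, n_chrom_sim = 1,
                    chrom_length = 2e5, snp_density = 0.002, F_background = 0.2)
  gm <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  X <- structure_covariates(kinship_matrix(gm), n_pc = 2)
  pc1 <- X[, "PC1"]
  grp <- unname(gm$pops)
  expect_true(all(pc1[grp == "A"] > 0) != all(pc1[grp == "A"] < 0))
  expect_true(max(pc1[grp == "A"]) < min(pc1[grp == "B"]) ||
                min(pc1[grp == "A"]) > max(pc1[grp == "B"]))
  # determinism of the sign convention
  expect_identical(X, structure_covariates(kinship_matrix(gm), n_pc = 2))
  # n_pc = 0 gives the bare intercept
  expect_equal(colnames(structure_covariates(kinship_matrix(gm), 0)), "intercept")
  expect_error(structure_covariates(kinship_matrix(gm), 24), "smaller")
})

test_that("the null REML fit collapses to OLS when K is the identity", {
  set.seed(15)
  n <- 60
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  fit <- fit_null_lmm(y, X, diag(n))
  ols <- lm(y ~ 0 + X)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  # with K = I only the total variance is identified; check it matches OLS REML
  expect_equal(fit$sigma_g2 * (1 + fit$lambda),
               sum(resid(ols)^2) / (n - 2), tolerance = 1e-6)
  expect_error(fit_null_lmm(y, cbind(X, X[, 2]), diag(n)), "rank deficient")
})

test_that("variance components are recovered from their generating model", {
  n <- 400
  inside <- 0
  low <- 0
  for (seed in 1:10) {
    set.seed(400 + seed)
    A <- matrix(rnorm(n * 50), n, 50)
    K <- tcrossprod(A) / 50
    L <- t(chol(K + 1e-8 * diag(n)))
    u <- drop(L %*% rnorm(n))
    # equal variances: heritable fraction 0.5
    y <- u + rnorm(n)
    f <- fit_null_lmm(y, matrix(1, n, 1), K)
    if (f$h2 >= 0.3 && f$h2 <= 0.7) inside <- inside + 1
    # pure noise: heritable fraction near zero
    f0 <- fit_null_lmm(rnorm(n), matrix(1, n, 1), K)
    if (f0$h2 <= 0.1) low <- low + 1
  }
  expect_gte(inside, 8)
  expect_gte(low, 8)
})

test_that("tidy and glance summarize the null fit", {
  set.seed(16)
  n <- 40
  f <- fit_null_lmm(rnorm(n), matrix(1, n, 1, dimnames = list(NULL, "intercept")),
                    diag(n))
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "sigma_g2", "sigma_e2"))
  gl <- glance(f)
  expect_equal(gl$nobs, n)
  expect_equal(gl$h2, f$sigma_g2 / (f$sigma_g2 + f$sigma_e2))
})

test_that("the scan matches OLS Wald p-values when K is the identity", {
  set.seed(17)
  n <- 80
  g <- matrix(rbinom(n * 40, 2, 0.4), 40, n)
  gm <- make_gm(g)
  y <- setNames(rnorm(n), gm$samples)
  K <- diag(n); dimnames(K) <- list(gm$samples, gm$samples)
  res <- assoc_scan(gm, y, X = matrix(1, n, 1), K = K)
  for (k in c(1, 10, 25)) {
    s <- summary(lm(y ~ g[k, ]))$coefficients
    p_ols <- pchisq((s[2, 1] / s[2, 2])^2, 1, lower.tail = FALSE)
    expect_equal(res$wald_p[k], p_ols, tolerance = 1e-6)
  }
})

test_that("beta is scale-equivariant in the dosage coding", {
  set.seed(18)
  n <- 50
  # 0/1 dosages so the doubled coding 0/2 is still a valid genotype matrix
  g <- matrix(rbinom(n * 10, 1, 0.3), 10, n)
  gm <- make_gm(g)
  y <- setNames(rnorm(n) + 0.5 * g[4, ], gm$samples)
  K <- diag(n); dimnames(K) <- list(gm$samples, gm$samples)
  res1 <- assoc_scan(gm, y, X = matrix(1, n, 1), K = K)
  res2 <- suppressMessages(assoc_scan(make_gm(2 * g), y,
                                      X = matrix(1, n, 1), K = K))
  expect_equal(res2$beta, res1$beta / 2)
  expect_equal(res2$wald_p, res1$wald_p)
})

test_that("mixed model controls structure-driven inflation where OLS does not", {
  med_mm <- med_ols <- numeric(5)
  for (seed in 1:5) {
    cfg <- sim_config(seed = 500 + seed, n_pop_a = 32, n_pop_b = 32,
                      n_chrom_sim = 1, chrom_length = 5e5, snp_density = 0.002,
                      F_background = 0.2, ld_decay_length = 5000)
    gm <- simulate_genotypes(simulate_frequencies(cfg), cfg)
    set.seed(1000 + seed)
    y <- setNames(rnorm(n_samples(gm)) + 2 * (unname(gm$pops) == "B"), gm$samples)
    mm <- suppressMessages(assoc_scan(gm, y))
    In <- diag(n_samples(gm)); dimnames(In) <- list(gm$samples, gm$samples)
    naive <- suppressMessages(
      assoc_scan(gm, y, X = matrix(1, n_samples(gm), 1), K = In)
    )
    med_mm[seed] <- median(qchisq(mm$wald_p, 1, lower.tail = FALSE))
    med_ols[seed] <- median(qchisq(naive$wald_p, 1, lower.tail = FALSE))
  }
  expect_true(all(med_mm >= qchisq(0.3, 1) & med_mm <= qchisq(0.7, 1)))
  expect_true(all(med_ols > qchisq(0.7, 1)))
})

test_that("permuting the phenotype destroys a planted association", {
  cfg <- sim_config(seed = 27, n_pop_a = 60, n_pop_b = 60, n_chrom_sim = 1,
                    chrom_length = 2e5, snp_density = 0.002, F_background = 0.05,
                    ld_decay_length = 5000, h2_causal = 0.3, h2_background = 0.1,
                    causal_snps = data.frame(site = 150, weight = 1))
  truth <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(truth, cfg)
  ph <- simulate_phenotypes(gm, truth, cfg)
  res <- suppressMessages(assoc_scan(gm, ph))
  causal_row <- which(res$pos == gm$pos[150])
  expect_gt(res$neg_log10_p[causal_row], 3)
  set.seed(28)
  perm_p <- replicate(20, {
    yp <- setNames(sample(ph$trait), ph$sample)
    rp <- suppressMessages(assoc_scan(gm, yp))
    rp$neg_log10_p[which(rp$pos == gm$pos[150])]
  })
  expect_lt(median(perm_p), 2)
})

test_that("the significance rule is strict at the boundary", {
  res <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "C",
                        beta = 1, se = 1,
                        wald_p = 10^(-c(4.2, 4, 3.9)),
                        neg_log10_p = c(4.2, 4, 3.9),
                        significant = NA)
  kept <- significant_snps(res)
  expect_equal(kept$pos, 1L)
  expect_equal(nrow(significant_snps(res[0, ])), 0)
})

test_that("hits are annotated by gene containment with optional flank", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1000, 10000), end = c(2000, 11000),
                          strand = "+")
  res <- tibble::tibble(chrom = "chr1", pos = c(1500, 2000, 2001, 7100),
                        neg_log10_p = 5)
  ann <- annotate_hits(res, genes)
  expect_equal(ann$genes[[1]], "g1")
  # 1-based pos 2000 is 0-based 1999: still inside [1000, 2000)
  expect_equal(ann$genes[[2]], "g1")
  expect_equal(ann$genes[[3]], character(0))
  # a 5-kb flank captures a gene ~3 kb away
  ann2 <- annotate_hits(res, genes, flank = 5000)
  expect_true("g2" %in% ann2$genes[[4]])
})
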