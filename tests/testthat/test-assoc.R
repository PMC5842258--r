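test_that("MAF filter applies a strict < threshold over non-missing calls", {
  # 20 accessions; marker 1: minor allele count 2 of 40 (MAF exactly 0.05);
  # marker 2: MAF 0.04 after missing exclusion; marker 3: all missing
  g1 <- c(rep(0L, 18), 1L, 1L)            # MAF = 2/40 = 0.05 -> retained
  geno <- cbind(m1 = g1,
                m2 = c(rep(0L, 19), 1L),  # MAF = 1/40 = 0.025 -> removed
                m3 = rep(NA_integer_, 20))
  snps <- toy_snps(geno)
  f <- maf_filter(snps, 0.05)
  info <- attr(f, "maf_filter")
  expect_equal(colnames(f$geno), "m1")
  expect_equal(info$n_in, 3)
  expect_equal(info$n_out, 1)
  expect_equal(info$n_all_missing, 1)

  # idempotence
  f2 <- maf_filter(f, 0.05)
  expect_identical(f2$geno, f$geno)
  expect_error(maf_filter(snps, 0.6), "threshold")
})

test_that("kinship matches a brute-force centred cross-product and is PSD", {
  set.seed(14)
  geno <- matrix(sample(0:2, 50, replace = TRUE), 5, 10)
  snps <- toy_snps(geno)
  K <- kinship_matrix(snps)

  # independent two-loop oracle (PSD shift on the diagonal removed first)
  p <- colMeans(geno) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(geno[, keep, drop = FALSE], 2, 2 * p[keep])
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  K_oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    K_oracle[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  }
  K_plain <- matrix(K, 5, 5) - diag(attr(K, "psd_shift"), 5)
  expect_equal(K_plain, K_oracle, tolerance = 1e-10)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-12)

  # identical accessions: off-diagonal equals the diagonals up to the shift
  geno_dup <- rbind(geno, geno[1, ])
  K2 <- kinship_matrix(toy_snps(geno_dup))
  expect_equal(K2[1, 6], K2[1, 1] - attr(K2, "psd_shift"), tolerance = 1e-10)

  # permutation conjugation
  perm <- c(3, 1, 5, 2, 4)
  K3 <- kinship_matrix(toy_snps(geno[perm, ]))
  K3_plain <- matrix(K3, 5, 5) - diag(attr(K3, "psd_shift"), 5)
  expect_equal(K3_plain, K_plain[perm, perm], tolerance = 1e-9)
})

test_that("trait effect percent follows its definition", {
  trait <- c(10, 20, 30, 15, 25, 12, 28, 18)
  names(trait) <- sprintf("a%d", 1:8)
  geno <- c(0, 2, 0, 2, 0, 2, 1, NA)
  # class means: 0 -> (10+30+25)/3 ; 2 -> (20+15+12)/3; range 20
  m0 <- mean(c(10, 30, 25)); m2 <- mean(c(20, 15, 12))
  expect_equal(trait_effect_percent(trait, geno), abs(m2 - m0) / 20 * 100)

  expect_equal(trait_effect_percent(c(a = 10, b = 20, c = 30),
                                    c(0, 1, 2)),
               (30 - 10) / 20 * 100) # 100%
  expect_equal(trait_effect_percent(c(a = 10, b = 10, c = 30, d = 30),
                                    c(0, 2, 0, 2)), 0)
  expect_error(trait_effect_percent(rep(5, 4), c(0, 0, 2, 2)), "zero trait range")
})

test_that("REML null fit matches a dense-matrix evaluation and finds interior optima", {
  # 30-accession toy with a genuinely interior delta
  set.seed(30)
  n <- 30
  geno <- matrix(rbinom(n * 300, 2, runif(n * 300, 0.1, 0.9)), n, 300)
  snps <- toy_snps(geno)
  K <- kinship_matrix(snps)
  Q <- cbind(runif(n)); Q <- cbind(Q, 1 - Q)
  rownames(Q) <- rownames(snps$geno)
  g <- as.numeric(MASS::mvrnorm(1, rep(0, n), K))
  y <- g + rnorm(n, 0, sd(g)) # delta ~ 1
  names(y) <- rownames(snps$geno)

  nf <- fit_null_model(y, K, Q)
  expect_gt(nf$delta, 1e-4)
  expect_lt(nf$delta, 1e4)

  # brute-force REML log-likelihood with explicit determinants/inverses
  X <- cbind(1, Q[, 1])
  q <- ncol(X)
  dense <- function(delta) {
    H <- K + delta * diag(n)
    Hi <- solve(H)
    XHX <- t(X) %*% Hi %*% X
    P <- Hi - Hi %*% X %*% solve(XHX, t(X) %*% Hi)
    ypy <- drop(t(y) %*% P %*% y)
    sg2 <- ypy / (n - q)
    -0.5 * ((n - q) * log(2 * pi * sg2) +
              c(determinant(H)$modulus) + c(determinant(XHX)$modulus) -
              c(determinant(crossprod(X))$modulus) + ypy / sg2)
  }
  expect_equal(nf$reml_loglik, dense(nf$delta), tolerance = 1e-6)
  # and it is the maximum along delta
  expect_gte(nf$reml_loglik, dense(nf$delta * 1.3) - 1e-8)
  expect_gte(nf$reml_loglik, dense(nf$delta / 1.3) - 1e-8)

  # no genetic signal on a genuinely structured kinship: delta runs toward
  # the residual-dominated bound and the genetic variance collapses
  p_struct <- default_test_panel()
  K_s <- kinship_matrix(maf_filter(p_struct$snps))
  set.seed(31)
  y_null <- rnorm(nrow(K_s)); names(y_null) <- rownames(K_s)
  nf0 <- fit_null_model(y_null, K_s, p_struct$q_matrix)
  expect_gt(nf0$delta, 10)
  expect_lt(nf0$sigma_g2, 0.1 * var(y_null))
})

test_that("delta is recovered within a factor of 2 from K-structured traits", {
  set.seed(77)
  n <- 200
  geno <- matrix(rbinom(n * 400, 2, rep(runif(400, 0.1, 0.9), each = n)), n, 400)
  snps <- toy_snps(geno)
  K <- kinship_matrix(snps)
  deltas <- replicate(20, {
    g <- as.numeric(MASS::mvrnorm(1, rep(0, n), K))
    y <- g + rnorm(n, 0, 1) # sigma_e2 = 1, sigma_g2 = 1 -> delta = 1
    names(y) <- rownames(snps$geno)
    fit_null_model(y, K)$delta
  })
  expect_gt(median(deltas), 0.5)
  expect_lt(median(deltas), 2)
})

test_that("with identity kinship the mixed-model scan reduces to OLS F-tests", {
  p <- default_test_panel()
  f <- maf_filter(p$snps)
  y <- trait_vec(p)
  I_n <- diag(length(y)); dimnames(I_n) <- list(names(y), names(y))
  res <- mlm_scan(y, f, Q = NULL, K = I_n)

  G <- f$geno
  mu <- colMeans(G, na.rm = TRUE)
  ols_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g[is.na(g)] <- mu[j]
    if (var(g) == 0) return(NA_real_)
    anova(lm(y ~ g))$`Pr(>F)`[1]
  }, 0)
  ord <- match(res$marker, colnames(G))
  expect_lt(max(abs(res$P - ols_p[ord]), na.rm = TRUE), 1e-8)
})

test_that("scan P-values are invariant to affine trait rescaling and uniform under permutation", {
  p <- default_test_panel()
  f <- maf_filter(p$snps)
  K <- kinship_matrix(f)
  y <- trait_vec(p)
  r1 <- mlm_scan(y, f, Q = p$q_matrix, K = K)
  r2 <- mlm_scan(3.7 * y - 12, f, Q = p$q_matrix, K = K)
  expect_lt(max(abs(r1$P - r2$P), na.rm = TRUE), 1e-8)

  set.seed(55)
  y_perm <- setNames(sample(as.numeric(y)), names(y))
  rp <- mlm_scan(y_perm, f, Q = p$q_matrix, K = K)
  expect_gt(suppressWarnings(ks.test(rp$P[!is.na(rp$P)], "punif"))$p.value, 0.01)
})

test_that("GLS converges to OLS in the residual-dominated limit", {
  p <- default_test_panel()
  f <- maf_filter(p$snps)
  K <- kinship_matrix(f)
  y <- trait_vec(p)
  nf_inf <- structure(list(delta = 1e5), class = "mlm_null")
  r_gls <- mlm_scan(y, f, Q = p$q_matrix, K = K, null_fit = nf_inf)
  I_n <- diag(length(y)); dimnames(I_n) <- list(names(y), names(y))
  r_ols <- mlm_scan(y, f, Q = p$q_matrix, K = I_n,
                    null_fit = structure(list(delta = 1), class = "mlm_null"))
  expect_lt(max(abs(r_gls$P - r_ols$P), na.rm = TRUE), 1e-4)
  expect_lt(max(abs(r_gls$beta - r_ols$beta), na.rm = TRUE), 1e-4)
})

test_that("a planted causal marker dominates the scan and the MLM controls inflation", {
  p <- default_test_panel()
  f <- maf_filter(p$snps)
  K <- kinship_matrix(f)
  y <- trait_vec(p)
  res <- mlm_scan(y, f, Q = p$q_matrix, K = K)
  cid <- p$truth$causal_snps$marker_id
  expect_equal(res$marker[which.min(res$P)], cid)
  expect_gt(res$trait_effect_pct[res$marker == cid], 10)
  lam <- genomic_inflation(res$P)
  expect_lt(lam, 1.3) # planted effect plus mediator inflate slightly
})

test_that("GEM scan flags planted mediators, trivial predictors and null genes correctly", {
  p <- default_test_panel()
  y <- trait_vec(p)
  g <- gem_scan(y, p$expr, Q = p$q_matrix)
  expect_equal(g$unigene[which.min(g$P)], p$truth$mediator_genes$gene_id)
  # mediator has positive trait_effect in truth -> positive coefficient
  expect_equal(g$sign[g$unigene == p$truth$mediator_genes$gene_id], "+")

  # a GEM equal to the trait itself: P at floor, partial R2 ~ 1
  rpkm <- p$expr$rpkm
  rpkm["G00001", ] <- 2^as.numeric(y) # so log2(rpkm + 1) ~ y
  expr2 <- expression_matrix(rpkm, p$expr$map)
  g2 <- gem_scan(y, expr2, Q = p$q_matrix)
  expect_lt(g2$P[g2$unigene == "G00001"], 1e-30)
  expect_gt(g2$partial_r2[g2$unigene == "G00001"], 0.95)

  # pure-noise GEMs give uniform P
  set.seed(99)
  rpkm_null <- matrix(2^rnorm(500 * length(y), 5, 1), 500,
                      dimnames = list(sprintf("N%04d", 1:500), names(y)))
  gn <- gem_scan(y, expression_matrix(rpkm_null), Q = p$q_matrix)
  expect_gt(suppressWarnings(ks.test(gn$P, "punif"))$p.value, 0.01)

  # zero-variance unigene skipped with flag
  rpkm_zv <- rpkm_null[1:5, ]
  rpkm_zv[1, ] <- 3
  gz <- gem_scan(y, expression_matrix(rpkm_zv), Q = p$q_matrix)
  expect_true(is.na(gz$P[gz$unigene == "N0001"]))
  expect_equal(attr(gz, "n_skipped"), 1)
})

test_that("expression-as-trait is the composition of extraction and mlm_scan", {
  p <- default_test_panel()
  f <- maf_filter(p$snps)
  K <- kinship_matrix(f)
  ug <- p$truth$mediator_genes$gene_id
  r1 <- expression_as_trait(ug, p$expr, f, Q = p$q_matrix, K = K)
  y_manual <- log2(p$expr$rpkm[ug, ] + 1)
  r2 <- mlm_scan(y_manual, f, Q = p$q_matrix, K = K)
  expect_equal(r1$P, r2$P)
  expect_equal(r1$beta, r2$beta)
  expect_equal(attr(r1, "scan_pass"), "expression_as_trait")
  # the planted cis marker attains the minimum P
  expect_equal(r1$marker[which.min(r1$P)], p$truth$mediator_genes$cis_marker_id)
})

test_that("monomorphic markers are skipped and results stay in genome order", {
  set.seed(4)
  geno <- cbind(matrix(sample(0:2, 60, TRUE), 12, 5), mono = rep(2L, 12))
  snps <- toy_snps(geno)
  y <- setNames(rnorm(12), rownames(snps$geno))
  I_n <- diag(12); dimnames(I_n) <- list(names(y), names(y))
  res <- mlm_scan(y, snps, K = I_n)
  expect_true(is.na(res$P[res$marker == "mono"]))
  expect_gte(attr(res, "n_skipped"), 1)
  expect_false(is.unsorted(res$pos[res$chrom == "A1"]))
})
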