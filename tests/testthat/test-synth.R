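test_that("panel generation is deterministic for a fixed config and seed", {
  cfg <- panel_config(n_accessions = 25, n_markers = 300, n_genes = 40, seed = 9)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(serialize(p1$snps$geno, NULL), serialize(p2$snps$geno, NULL))
  expect_identical(serialize(p1$expr$rpkm, NULL), serialize(p2$expr$rpkm, NULL))
  expect_identical(serialize(p1$traits, NULL), serialize(p2$traits, NULL))
  expect_identical(p1$q_matrix, p2$q_matrix)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(panel_config(fst = 1), "fst")
  expect_error(panel_config(n_accessions = 0), "positive")
  expect_error(panel_config(heritability = 1.2), "heritability")
  expect_error(panel_config(n_markers = 100,
                            causal_snps = data.frame(marker = 200, effect = 1)),
               "out of range")
  expect_error(panel_config(n_genes = 10,
                            mediator_genes = data.frame(gene = 11, cis_marker = 1,
                                                        cis_effect = 1, trait_effect = 1)),
               "out of range")
})

test_that("Q rows sum to one and genotypes are valid codes", {
  p <- default_test_panel()
  expect_true(all(abs(rowSums(p$q_matrix) - 1) < 1e-12))
  expect_true(all(p$snps$geno %in% c(0L, 1L, 2L) | is.na(p$snps$geno)))
  expect_gt(mean(is.na(p$snps$geno)), 0.005) # missing calls injected
})

test_that("subpopulation differentiation matches the configured Fst", {
  # Hudson-type estimator applied directly to the simulated subpopulation
  # frequencies (the generator's own truth), ratio-of-means form
  hudson <- function(p1, p2) {
    num <- (p1 - p2)^2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    mean(num) / mean(den)
  }
  cfg <- panel_config(n_accessions = 20, n_markers = 5000, fst = 0.2, seed = 31)
  sim <- simulate_genotypes(cfg)
  fst_hat <- hudson(sim$truth$p_sub[1, ], sim$truth$p_sub[2, ])
  expect_lt(abs(fst_hat - 0.2), 0.03)

  # fst = 0: subpopulation frequencies collapse onto the ancestral ones
  cfg0 <- panel_config(n_accessions = 20, n_markers = 1000, fst = 0, seed = 32)
  sim0 <- simulate_genotypes(cfg0)
  expect_equal(sim0$truth$p_sub[1, ], sim0$truth$p_sub[2, ])
  expect_equal(sim0$truth$p_sub[1, ], sim0$truth$p_anc)
})

test_that("homoeologous duplicates are correlated with their source markers", {
  cfg <- panel_config(n_accessions = 60, n_markers = 800, seed = 42)
  sim <- simulate_genotypes(cfg)
  n_base <- 800 - length(sim$truth$dup_src)
  expect_gt(length(sim$truth$dup_src), 0)
  cors <- vapply(seq_along(sim$truth$dup_src), function(j) {
    dup_id <- colnames(sim$snps$geno)[match(n_base + j, sim$truth$gen_index)]
    src_id <- colnames(sim$snps$geno)[match(sim$truth$dup_src[j], sim$truth$gen_index)]
    suppressWarnings(cor(sim$snps$geno[, dup_id], sim$snps$geno[, src_id],
                         use = "pairwise.complete.obs"))
  }, 0)
  expect_gt(median(cors, na.rm = TRUE), 0.6)
  # duplicates live on the C-genome partner chromosome
  dup_ids <- colnames(sim$snps$geno)[match(n_base + seq_along(sim$truth$dup_src),
                                           sim$truth$gen_index)]
  expect_true(all(startsWith(sim$snps$map$chrom[match(dup_ids, sim$snps$map$marker)], "C")))
})

test_that("expression carries the planted cis effect and respects the noise-free limit", {
  probe <- simulate_genotypes(panel_config(n_accessions = 50, n_markers = 200,
                                           n_genes = 30, missing_rate = 0,
                                           seed = 8))
  cis_idx <- choose_causal_marker(probe)
  cfg <- panel_config(n_accessions = 50, n_markers = 200, n_genes = 30,
                      mediator_genes = data.frame(gene = 5, cis_marker = cis_idx,
                                                  cis_effect = 0.9,
                                                  trait_effect = 0),
                      expr_noise_sd = 0, missing_rate = 0, seed = 8)
  sim <- simulate_genotypes(cfg)
  expr <- simulate_expression(cfg, sim)
  expect_true(all(expr$rpkm >= 0))
  cid <- colnames(sim$snps$geno)[match(cis_idx, sim$truth$gen_index)]
  g <- sim$snps$geno[, cid]
  l2 <- log2(expr$rpkm[5, ])
  # noise-free: log2 difference between homozygote classes is exactly 2e
  expect_equal(mean(l2[g == 2]) - mean(l2[g == 0]), 2 * 0.9, tolerance = 1e-12)

  # with noise, OLS recovers the cis effect within 2 SE; a cis effect of 0
  # gives a slope near 0
  probe2 <- simulate_genotypes(panel_config(n_accessions = 79, n_markers = 200,
                                            n_genes = 30, seed = 9))
  idx_a <- choose_causal_marker(probe2, rank = 1)
  idx_b <- choose_causal_marker(probe2, rank = 2)
  cfg2 <- panel_config(n_accessions = 79, n_markers = 200, n_genes = 30,
                       mediator_genes = data.frame(gene = c(5, 6),
                                                   cis_marker = c(idx_a, idx_b),
                                                   cis_effect = c(0.9, 0),
                                                   trait_effect = c(0, 0)),
                       seed = 9)
  sim2 <- simulate_genotypes(cfg2)
  expr2 <- simulate_expression(cfg2, sim2)
  for (row in 1:2) {
    cid2 <- colnames(sim2$snps$geno)[match(c(idx_a, idx_b)[row], sim2$truth$gen_index)]
    g2 <- sim2$snps$geno[, cid2]
    fit <- summary(lm(log2(expr2$rpkm[c(5, 6)[row], ]) ~ g2))
    est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
    expect_lt(abs(est - c(0.9, 0)[row]), 2 * se + 1e-9)
  }
})

test_that("trait architecture honours heritability, planted effects and the SLR target", {
  # heritability 1 with no causal/polygenic effects: replicates are exact copies
  cfg1 <- panel_config(n_accessions = 15, n_markers = 100, heritability = 1,
                       polygenic_sd = 0, seed = 5)
  sim1 <- simulate_genotypes(cfg1)
  tr1 <- simulate_traits(cfg1, sim1)
  wvar <- tapply(tr1$traits$fmax, tr1$traits$accession, var)
  expect_true(all(wvar < 1e-20))

  # planted causal effect recovered by OLS of accession means on genotype
  cfg2 <- panel_config(n_accessions = 79, n_markers = 400,
                       causal_snps = data.frame(marker = 10, effect = 1.3),
                       polygenic_sd = 0.5, seed = 6)
  sim2 <- simulate_genotypes(cfg2)
  tr2 <- simulate_traits(cfg2, sim2)
  cid <- tr2$truth$causal_snps$marker_id
  g <- sim2$snps$geno[, cid]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  y <- trait_vec(tr2)
  fit <- summary(lm(y ~ g))
  expect_lt(abs(fit$coefficients[2, 1] - 1.3), 2 * fit$coefficients[2, 2])

  # SLR correlation lands within the Fisher-z sampling band around 0.4
  cfg3 <- panel_config(n_accessions = 79, n_markers = 300,
                       slr_correlation = 0.4, seed = 7)
  sim3 <- simulate_genotypes(cfg3)
  tr3 <- simulate_traits(cfg3, sim3)
  r <- cor(tr3$accession_means$SLR, tr3$accession_means$fmax)
  expect_lt(abs(r - 0.4), 0.2)
})

test_that("simulated bend curves hit their generating parameters in the noise-free limit", {
  cur <- simulate_bend_curve(24.2, 19.9, noise_sd = 0)
  expect_equal(max(cur$force), 24.2)
  f <- extract_curve_features(cur)
  expect_equal(f$fmax, 24.2)
  expect_equal(f$f_over_v, 19.9, tolerance = 1e-9)
  expect_error(simulate_bend_curve(-1, 5), "fmax")
  expect_error(simulate_bend_curve(5, 0), "slope")
})

test_that("spectra respond linearly to esterification level and are seed-stable", {
  s_same1 <- simulate_spectra(0.5, n_replicates = 2, seed = 77)
  s_same2 <- simulate_spectra(0.5, n_replicates = 2, seed = 77)
  expect_identical(serialize(s_same1, NULL), serialize(s_same2, NULL))

  s0 <- simulate_spectra(0, n_replicates = 1, noise_sd = 0)[[1]]
  s1 <- simulate_spectra(1, n_replicates = 1, noise_sd = 0)[[1]]
  at <- function(s, wn) s$absorbance[s$wavenumber == wn]
  # ester band amplitude is proportional to ester_level (zero at level 0)
  expect_equal(at(s1, 1740) - at(s0, 1740), 0.45 * (1 - 0),
               tolerance = 1e-6)
  expect_equal(at(s0, 1624) - at(s1, 1624), 0.45, tolerance = 1e-6)
  expect_error(simulate_spectra(1.5), "ester_level")
})

test_that("null panels produce uniform downstream P-values", {
  cfg <- panel_config(n_accessions = 79, n_markers = 5000, polygenic_sd = 0,
                      heritability = 0, seed = 13)
  p <- simulate_panel(cfg)
  f <- maf_filter(p$snps)
  K <- kinship_matrix(f)
  res <- mlm_scan(trait_vec(p), f, Q = p$q_matrix, K = K)
  ks <- suppressWarnings(ks.test(res$P[!is.na(res$P)], "punif"))
  expect_gt(ks$p.value, 0.01)
})
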