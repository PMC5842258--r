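#' SNP genotype matrix with marker map
#'
#' Container for a transcriptome-derived SNP panel: additive genotype codes
#' 0/1/2 (copies of the alternate allele, NA = missing) per accession and
#' marker, plus a marker map giving each marker's pseudochromosome and
#' ordinal position along the pseudomolecule.
#'
#' @param geno Integer/numeric matrix, accessions in rows (rownames = ids),
#'   markers in columns (colnames = marker ids); values in {0,1,2,NA}.
#' @param map Data.frame with columns `marker`, `chrom`, `pos` covering
#'   every marker, positions non-decreasing within a chromosome.
#' @param alleles Optional data.frame `marker`, `allele0`, `allele1`.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(geno, map, alleles = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("geno needs accession rownames and marker colnames")
  }
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("genotype codes must be in {0,1,2,NA}")
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    stop("map needs columns marker, chrom, pos")
  }
  if (!setequal(map$marker, colnames(geno))) {
    stop("marker map must cover exactly the markers in geno")
  }
  map <- map[match(colnames(geno), map$marker), ]
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$pos[map$chrom == ch])) {
      stop("positions must be non-decreasing within chromosome ", ch)
    }
  }
  if (is.null(alleles)) {
    alleles <- data.frame(marker = colnames(geno), allele0 = "A", allele1 = "B")
  }
  structure(list(geno = geno, map = map, alleles = alleles),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d accessions x %d markers on %d pseudochromosomes (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Minor allele frequencies of a SNP panel
#'
#' @param snps A [snp_matrix()].
#' @return Named vector of per-marker minor allele frequencies computed over
#'   non-missing calls (NaN where all calls are missing).
#' @export
minor_allele_freq <- function(snps) {
  p <- colMeans(snps$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  stats::setNames(maf, colnames(snps$geno))
}

#' Remove markers with minor allele frequency below a threshold
#'
#' Markers whose MAF (over non-missing calls) is strictly below `threshold`
#' are removed: the published filter is "minor alleles present at < 5%", so
#' a marker sitting exactly on the threshold is retained. Markers with all
#' calls missing are removed and counted separately.
#'
#' @param snps A [snp_matrix()].
#' @param threshold MAF threshold in (0, 0.5], default 0.05.
#' @return The filtered `snp_matrix`, with an attribute `maf_filter` holding
#'   `n_in`, `n_out`, `n_removed`, `n_all_missing`, `threshold`.
#' @export
maf_filter <- function(snps, threshold = 0.05) {
  stopifnot(inherits(snps, "snp_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 0.5) {
    stop("threshold must be in (0, 0.5]")
  }
  maf <- minor_allele_freq(snps)
  all_missing <- !is.finite(maf)
  keep <- !all_missing & maf >= threshold
  out <- snp_matrix(snps$geno[, keep, drop = FALSE],
                    snps$map[keep, , drop = FALSE],
                    snps$alleles[keep, , drop = FALSE])
  attr(out, "maf_filter") <- list(
    n_in = ncol(snps$geno), n_out = sum(keep),
    n_removed = sum(!keep), n_all_missing = sum(all_missing),
    threshold = threshold)
  out
}

#' Genome-wide kinship matrix (VanRaden centred cross-product)
#'
#' Relatedness among accessions estimated from the filtered marker panel:
#' genotypes are mean-imputed per marker, centred at twice the allele
#' frequency, and the cross-product scaled by the total expected marker
#' variance `2 * sum(p * (1 - p))`. If numerical noise (e.g. from
#' imputation) produces negative eigenvalues, the matrix is shifted by
#' `(|min eigenvalue| + 1e-10) * I` so the result is positive semi-definite;
#' the shift applied is recorded as an attribute.
#'
#' @param snps A [snp_matrix()] (typically after [maf_filter()]).
#' @return Symmetric PSD matrix of class `matrix` with accession dimnames
#'   and attribute `psd_shift`.
#' @export
kinship_matrix <- function(snps) {
  stopifnot(inherits(snps, "snp_matrix"))
  G <- snps$geno
  if (nrow(G) < 2L) stop("kinship needs >= 2 accessions")
  p <- colMeans(G, na.rm = TRUE) / 2
  ok <- is.finite(p) & p > 0 & p < 1
  G <- G[, ok, drop = FALSE]
  p <- p[ok]
  if (ncol(G) == 0L) stop("no polymorphic markers for kinship")
  Z <- sweep(G, 2, 2 * p)
  Z[is.na(Z)] <- 0 # mean imputation after centring
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  shift <- 0
  if (ev_min < 0) {
    shift <- abs(ev_min) + 1e-10
    K <- K + diag(shift, nrow(K))
  }
  dimnames(K) <- list(rownames(snps$geno), rownames(snps$geno))
  attr(K, "psd_shift") <- shift
  K
}

#' Percentage trait effect of a marker's homozygote classes
#'
#' The absolute difference between the mean trait of the two homozygote
#' genotype classes, expressed as a percentage of the trait range across
#' all accessions.
#'
#' @param trait Named numeric vector of accession trait means.
#' @param genotypes Vector of genotype codes {0,1,2,NA} aligned to `trait`.
#' @return Percentage in [0, 100] (NA when a homozygote class is empty).
#' @export
trait_effect_percent <- function(trait, genotypes) {
  ok <- is.finite(trait)
  trait <- trait[ok]; genotypes <- genotypes[ok]
  rng <- diff(range(trait))
  if (rng == 0) stop("zero trait range across accessions")
  m0 <- mean(trait[which(genotypes == 0)])
  m2 <- mean(trait[which(genotypes == 2)])
  if (!is.finite(m0) || !is.finite(m2)) return(NA_real_)
  abs(m2 - m0) / rng * 100
}

# Fixed-effect design: intercept plus Q with the last ancestry column
# dropped (rows of Q sum to 1, so keeping all columns with an intercept
# would be singular).
build_fixed_design <- function(n, Q = NULL) {
  X <- matrix(1, n, 1)
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (nrow(Q) != n) stop("Q has wrong number of rows")
    if (ncol(Q) > 1L) X <- cbind(X, Q[, -ncol(Q), drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular fixed-effect design (Q collinear)")
  X
}

#' REML variance components of the polygenic null model
#'
#' Fits the null mixed model `y = X beta + u + e` with `u ~ N(0, sg2 K)`
#' and `e ~ N(0, se2 I)`, fixed effects X = intercept + Q (last ancestry
#' column dropped). The variance ratio `delta = se2 / sg2` is estimated by
#' REML: the kinship matrix is spectrally decomposed on the orthogonal
#' complement of the fixed effects and the profiled restricted
#' log-likelihood maximised in log(delta) over [1e-5, 1e5] (coarse grid
#' followed by local refinement, so a secondary mode is not missed).
#'
#' @param trait Named numeric vector of accession trait means.
#' @param K Kinship matrix aligned to `trait` (same order).
#' @param Q Optional ancestry matrix (rows sum to 1).
#' @param delta_range Search range for delta, default `c(1e-5, 1e5)`.
#' @return A list of class `mlm_null` with `delta`, `sigma_g2`, `sigma_e2`,
#'   `reml_loglik`, plus the decomposition pieces reused by [mlm_scan()].
#' @export
fit_null_model <- function(trait, K, Q = NULL, delta_range = c(1e-5, 1e5)) {
  y <- as.numeric(trait)
  if (any(!is.finite(y))) stop("trait contains non-finite values")
  n <- length(y)
  K <- as.matrix(K)
  if (nrow(K) != n) stop("K dimension does not match trait length")
  X <- build_fixed_design(n, Q)
  q <- ncol(X)

  # eigen of K restricted to the null space of X
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  eig <- eigen(S %*% K %*% S, symmetric = TRUE)
  xi <- pmax(eig$values[seq_len(n - q)], 0)
  U <- eig$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- as.numeric(crossprod(U, y))^2

  reml_ll <- function(log_delta) {
    d <- exp(log_delta)
    R <- sum(eta2 / (xi + d))
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(R)) -
             sum(log(xi + d)))
  }
  grid <- seq(log(delta_range[1]), log(delta_range[2]), length.out = 80)
  ll <- vapply(grid, reml_ll, 0)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  # keep the boundary if the grid end wins
  if (ll[i] > opt$objective) {
    opt <- list(maximum = grid[i], objective = ll[i])
  }
  delta <- exp(opt$maximum)
  sigma_g2 <- sum(eta2 / (xi + delta)) / (n - q)
  structure(list(delta = delta, sigma_g2 = sigma_g2,
                 sigma_e2 = delta * sigma_g2,
                 reml_loglik = opt$objective,
                 n = n, q = q, X = X, K = K, y = y),
            class = "mlm_null")
}

# Whitening transform for V = K + delta I: returns function(M) solve-sqrt
gls_rotation <- function(K, delta) {
  eig <- eigen(K, symmetric = TRUE)
  w <- pmax(eig$values, 0) + delta
  t(eig$vectors / rep(sqrt(w), each = nrow(K)))
}

#' Mixed-linear-model association scan over a SNP panel
#'
#' Per-trait structured association scan in the P3D/EMMAX style: the
#' variance ratio `delta` is estimated once under the null model
#' ([fit_null_model()]) and reused for every marker, whose additive 0/1/2
#' genotype is appended to the fixed effects (intercept + Q) and tested by
#' generalised least squares under `V = sigma_g2 (K + delta I)`. The
#' per-marker test is an F test with `n - p` residual degrees of freedom
#' (p = number of fixed effects including the marker). Missing genotypes
#' are mean-imputed per marker, consistent with kinship construction, and
#' the number imputed is recorded. Set `method = "ols"` for the naive
#' unstructured scan (no kinship; Q still included if supplied), used as
#' the comparison arm when demonstrating structure control.
#'
#' @param trait Named numeric vector of accession trait means, names
#'   matching `rownames(snps$geno)`.
#' @param snps A [snp_matrix()] (MAF-filtered).
#' @param Q Optional ancestry matrix.
#' @param K Kinship matrix (required for `method = "mlm"`).
#' @param null_fit Optional pre-fitted [fit_null_model()] result.
#' @param method `"mlm"` (default) or `"ols"`.
#' @return A data.frame of class `assoc_result`, one row per tested marker,
#'   in genome order: `marker`, `chrom`, `pos`, `maf`, `n_imputed`, `beta`,
#'   `se`, `stat` (F), `P`, `trait_effect_pct`, `bonferroni`, `fdr_bh`,
#'   and attributes `delta`, `method`, `n_skipped`.
#' @export
mlm_scan <- function(trait, snps, Q = NULL, K = NULL, null_fit = NULL,
                     method = c("mlm", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(snps, "snp_matrix"))
  acc <- rownames(snps$geno)
  if (!is.null(names(trait))) {
    if (!all(acc %in% names(trait))) stop("trait missing some accessions")
    trait <- trait[acc]
  } else if (length(trait) != length(acc)) {
    stop("trait length does not match accession count")
  }
  y <- as.numeric(trait)
  if (any(!is.finite(y))) stop("trait contains non-finite values")
  n <- length(y)
  X <- build_fixed_design(n, Q)

  delta <- NA_real_
  if (method == "mlm") {
    if (is.null(K)) stop("K is required for the mixed-model scan")
    if (is.null(null_fit)) null_fit <- fit_null_model(y, K, Q)
    delta <- null_fit$delta
    Tr <- gls_rotation(as.matrix(K), delta)
    ys <- as.numeric(Tr %*% y)
    Xs <- Tr %*% X
  } else {
    ys <- y
    Xs <- X
    Tr <- NULL
  }

  G <- snps$geno
  maf <- minor_allele_freq(snps)
  n_imputed <- colSums(is.na(G))
  mu <- colMeans(G, na.rm = TRUE)
  Gi <- G
  idx <- which(is.na(Gi), arr.ind = TRUE)
  if (nrow(idx)) Gi[idx] <- mu[idx[, 2]]
  vars <- apply(Gi, 2, stats::var)
  mono <- !is.finite(vars) | vars == 0 | !is.finite(maf)
  Gi[, !is.finite(vars)] <- 0 # keep all-missing columns numerically inert

  Gs <- if (is.null(Tr)) Gi else Tr %*% Gi
  qrX <- qr(Xs)
  yr <- qr.resid(qrX, ys)
  Gr <- qr.resid(qrX, Gs)
  gg <- colSums(Gr^2)
  gy <- colSums(Gr * yr)
  p_fixed <- ncol(X) + 1L
  df2 <- n - p_fixed
  rss0 <- sum(yr^2)
  beta <- gy / gg
  rss1 <- pmax(rss0 - gy^2 / gg, 0)
  Fstat <- (rss0 - rss1) / (rss1 / df2)
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  se <- sqrt(rss1 / df2 / gg)

  # percentage effect of homozygote classes on the raw scale
  te <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    if (mono[j]) return(NA_real_)
    tryCatch(trait_effect_percent(y, g), error = function(e) NA_real_)
  }, 0)

  out <- data.frame(
    marker = colnames(G), chrom = snps$map$chrom, pos = snps$map$pos,
    maf = unname(maf), n_imputed = unname(n_imputed),
    beta = unname(beta), se = unname(se), stat = unname(Fstat),
    P = pmin(pmax(unname(pval), .Machine$double.xmin), 1),
    trait_effect_pct = te,
    stringsAsFactors = FALSE
  )
  out$P[mono] <- NA_real_
  out$beta[mono] <- NA_real_
  out$stat[mono] <- NA_real_
  out$se[mono] <- NA_real_
  out <- out[order(out$chrom, out$pos), ]
  tested <- !is.na(out$P)
  out$bonferroni <- pmin(out$P * sum(tested), 1)
  out$fdr_bh <- NA_real_
  out$fdr_bh[tested] <- stats::p.adjust(out$P[tested], method = "BH")
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "delta") <- delta
  attr(out, "method") <- method
  attr(out, "n_skipped") <- sum(mono)
  out
}

#' Gene expression marker (GEM) association scan
#'
#' Tests each unigene's transcript abundance as a predictor of the trait in
#' a fixed-effect linear model `trait ~ intercept + Q + log2(RPKM + 1)`,
#' with an F test on the expression term. The log2(x+1) transformation
#' stabilises the heavy-tailed RPKM scale. The sign of the expression
#' coefficient and the partial R^2 of the expression term are reported.
#' Set `K` to also whiten by a kinship matrix (off by default: the GEM
#' model is structure-corrected through Q only).
#'
#' @param trait Named numeric vector of accession trait means.
#' @param expr An [expression_matrix()] (unigenes x accessions, RPKM).
#' @param Q Optional ancestry matrix.
#' @param K Optional kinship matrix; when supplied, `delta` is estimated
#'   under the null and the model whitened as in [mlm_scan()].
#' @return A data.frame of class `assoc_result`: `unigene`, `chrom`, `pos`,
#'   `mean_rpkm`, `beta`, `sign`, `stat`, `P`, `partial_r2`, `bonferroni`,
#'   `fdr_bh`.
#' @export
gem_scan <- function(trait, expr, Q = NULL, K = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  acc <- colnames(expr$rpkm)
  if (!is.null(names(trait))) {
    if (!all(acc %in% names(trait))) stop("trait missing some accessions")
    trait <- trait[acc]
  }
  y <- as.numeric(trait)
  n <- length(y)
  X <- build_fixed_design(n, Q)
  E <- t(log2(expr$rpkm + 1)) # accessions x unigenes

  if (!is.null(K)) {
    nf <- fit_null_model(y, K, Q)
    Tr <- gls_rotation(as.matrix(K), nf$delta)
    y <- as.numeric(Tr %*% y)
    X <- Tr %*% X
    E <- Tr %*% E
  }
  zero_var <- apply(E, 2, function(x) stats::var(x) == 0)
  qrX <- qr(X)
  yr <- qr.resid(qrX, y)
  Er <- qr.resid(qrX, E)
  gg <- colSums(Er^2)
  gy <- colSums(Er * yr)
  df2 <- n - ncol(X) - 1L
  rss0 <- sum(yr^2)
  beta <- gy / gg
  rss1 <- pmax(rss0 - gy^2 / gg, 0)
  Fstat <- (rss0 - rss1) / (rss1 / df2)
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)

  out <- data.frame(
    unigene = rownames(expr$rpkm),
    chrom = expr$map$chrom, pos = expr$map$pos,
    mean_rpkm = rowMeans(expr$rpkm),
    beta = unname(beta),
    sign = ifelse(beta > 0, "+", "-"),
    stat = unname(Fstat),
    P = pmin(pmax(unname(pval), .Machine$double.xmin), 1),
    partial_r2 = unname((rss0 - rss1) / rss0),
    stringsAsFactors = FALSE
  )
  out$P[zero_var] <- NA_real_
  out$beta[zero_var] <- NA_real_
  out$stat[zero_var] <- NA_real_
  out$sign[zero_var] <- NA_character_
  out <- out[order(out$chrom, out$pos), ]
  tested <- !is.na(out$P)
  out$bonferroni <- pmin(out$P * sum(tested), 1)
  out$fdr_bh <- NA_real_
  out$fdr_bh[tested] <- stats::p.adjust(out$P[tested], method = "BH")
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "method") <- if (is.null(K)) "gem_q" else "gem_qk"
  attr(out, "n_skipped") <- sum(zero_var)
  out
}

#' Map a unigene's expression back onto the SNP panel as a trait
#'
#' Second-pass scan used on highly associated GEMs: the unigene's
#' log2(RPKM + 1) values become the trait in a full kinship-corrected
#' mixed-model SNP scan, revealing the loci (e.g. cis regulators) that
#' control its expression.
#'
#' @param unigene Unigene id present in `expr`.
#' @param expr An [expression_matrix()].
#' @param snps A [snp_matrix()].
#' @param Q,K As in [mlm_scan()].
#' @return An `assoc_result` data.frame (see [mlm_scan()]) with attribute
#'   `scan_pass = "expression_as_trait"` and `unigene`.
#' @export
expression_as_trait <- function(unigene, expr, snps, Q = NULL, K = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!unigene %in% rownames(expr$rpkm)) {
    stop("unigene '", unigene, "' not present in expression matrix")
  }
  y <- log2(expr$rpkm[unigene, ] + 1)
  names(y) <- colnames(expr$rpkm)
  out <- mlm_scan(y, snps, Q = Q, K = K)
  attr(out, "scan_pass") <- "expression_as_trait"
  attr(out, "unigene") <- unigene
  out
}

#' Genomic inflation factor of a scan
#'
#' Median observed 1-df chi-square statistic (from the P-values) divided by
#' the median of the null chi-square distribution. Values near 1 indicate
#' adequate structure control; well-calibrated structured scans should sit
#' in [0.9, 1.1] while naive scans on structured panels inflate above 1.2.
#'
#' @param p Vector of P-values (NAs dropped).
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) stop("no P-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
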