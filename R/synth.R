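#' Configuration for a synthetic diversity panel
#'
#' Describes the ground-truth architecture of a simulated association
#' panel: an admixed population (two subpopulations by default, matching
#' the structure typically detected in winter/spring oilseed rape panels),
#' Balding-Nichols-differentiated biallelic markers in pseudomolecule
#' order with a configurable fraction of correlated homoeologous
#' duplicates, log-scale expression with cis-eQTL, and a trait driven by
#' planted SNP effects, expression-mediated effects and a
#' kinship-structured polygenic background.
#'
#' @param n_accessions Number of accessions (default 79, a realistic
#'   Associative Transcriptomics panel size).
#' @param n_subpops Number of ancestral subpopulations K (default 2).
#' @param fst Subpopulation differentiation in [0, 1) (default 0.2).
#' @param n_markers Total number of biallelic markers (default 5000).
#' @param n_genes Number of unigenes with expression (default 1000).
#' @param causal_snps Data.frame `marker` (column index), `effect` (trait
#'   units per allele copy); NULL for a null panel.
#' @param mediator_genes Data.frame `gene`, `cis_marker`, `cis_effect`
#'   (log2-RPKM per allele copy), `trait_effect` (trait units per log2-RPKM
#'   unit); NULL for none.
#' @param heritability Fraction of accession-mean trait variance that is
#'   genetic, in [0, 1] (default 0.7).
#' @param slr_correlation Target Pearson r between the simulated stem
#'   lodging risk score and Fmax accession means (default 0.65).
#' @param polygenic_sd SD (trait units) of the kinship-structured polygenic
#'   term (default 1).
#' @param het_rate Probability an accession is heterozygous at a marker
#'   (default 0.05; the panels emulated are near-inbred).
#' @param missing_rate Fraction of genotype calls set missing (default 0.02).
#' @param dup_fraction Fraction of markers that are homoeologous duplicates
#'   of another marker (default 0.1).
#' @param dup_cor Per-call retention probability between a duplicate and its
#'   source marker (default 0.9).
#' @param expr_noise_sd SD of log2-RPKM noise (default 0.5).
#' @param n_replicates Plant replicates per accession (default 3).
#' @param seed Integer RNG seed.
#' @return An object of class `panel_config` (a validated list).
#' @export
panel_config <- function(n_accessions = 79, n_subpops = 2, fst = 0.2,
                         n_markers = 5000, n_genes = 1000,
                         causal_snps = NULL, mediator_genes = NULL,
                         heritability = 0.7, slr_correlation = 0.65,
                         polygenic_sd = 1, het_rate = 0.05,
                         missing_rate = 0.02, dup_fraction = 0.1,
                         dup_cor = 0.9, expr_noise_sd = 0.5,
                         n_replicates = 3, seed = 1L) {
  counts <- c(n_accessions = n_accessions, n_subpops = n_subpops,
              n_markers = n_markers, n_genes = n_genes,
              n_replicates = n_replicates)
  if (any(counts < 1)) stop("all counts must be positive")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (heritability < 0 || heritability > 1) stop("heritability must be in [0, 1]")
  if (abs(slr_correlation) > 1) stop("slr_correlation must be in [-1, 1]")
  if (!is.null(causal_snps)) {
    causal_snps <- as.data.frame(causal_snps)
    stopifnot(all(c("marker", "effect") %in% names(causal_snps)))
    if (any(causal_snps$marker < 1 | causal_snps$marker > n_markers)) {
      stop("causal marker index out of range")
    }
  }
  if (!is.null(mediator_genes)) {
    mediator_genes <- as.data.frame(mediator_genes)
    stopifnot(all(c("gene", "cis_marker", "cis_effect", "trait_effect") %in%
                    names(mediator_genes)))
    if (any(mediator_genes$gene < 1 | mediator_genes$gene > n_genes)) {
      stop("mediator gene index out of range")
    }
    if (any(mediator_genes$cis_marker < 1 | mediator_genes$cis_marker > n_markers)) {
      stop("cis marker index out of range")
    }
  }
  structure(list(n_accessions = n_accessions, n_subpops = n_subpops,
                 fst = fst, n_markers = n_markers, n_genes = n_genes,
                 causal_snps = causal_snps, mediator_genes = mediator_genes,
                 heritability = heritability,
                 slr_correlation = slr_correlation,
                 polygenic_sd = polygenic_sd, het_rate = het_rate,
                 missing_rate = missing_rate, dup_fraction = dup_fraction,
                 dup_cor = dup_cor, expr_noise_sd = expr_noise_sd,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "panel_config")
}

# Dirichlet admixture proportions concentrated on each accession's home
# cluster (median home-ancestry ~0.96 with an admixed tail, as in
# STRUCTURE plots of rapeseed diversity panels).
r_admixture <- function(n, K, home) {
  alpha <- matrix(0.4, n, K)
  alpha[cbind(seq_len(n), home)] <- 10
  g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
  g / rowSums(g)
}

#' Simulate an admixed SNP panel with known subpopulation frequencies
#'
#' Ancestral allele frequencies are drawn per marker; subpopulation
#' frequencies follow a Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` at the configured Fst; each accession's
#' genotype is sampled from its admixture-weighted frequency, mostly as a
#' doubled single allele draw (near-inbred) with heterozygotes at a low
#' rate. The final `dup_fraction` of markers are correlated homoeologous
#' copies of earlier markers placed on the partner (C-genome)
#' pseudochromosome; markers carry ordered positions on four
#' pseudochromosomes (A1, A2, C1, C2). Missing calls are injected at
#' `missing_rate`.
#'
#' @param config A [panel_config()].
#' @return A list with `snps` (a [snp_matrix()]), `q_matrix` (accessions x
#'   subpopulations, rows summing to 1) and `truth` (ancestral and
#'   subpopulation allele frequencies, duplicate source map).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  K <- config$n_subpops
  m <- config$n_markers
  n_dup <- round(m * config$dup_fraction)
  n_base <- m - n_dup
  if (n_base < 1) stop("dup_fraction leaves no base markers")

  acc <- sprintf("ACC%03d", seq_len(n))
  home <- rep_len(seq_len(K), n)
  Q <- r_admixture(n, K, home)
  rownames(Q) <- acc
  colnames(Q) <- sprintf("POP%d", seq_len(K))

  p_anc <- stats::runif(n_base, 0.1, 0.9)
  if (config$fst > 0) {
    f <- config$fst
    p_sub <- matrix(stats::rbeta(K * n_base,
                                 rep(p_anc, each = K) * (1 - f) / f,
                                 rep(1 - p_anc, each = K) * (1 - f) / f),
                    nrow = K)
  } else {
    p_sub <- matrix(rep(p_anc, each = K), nrow = K)
  }

  freq <- Q %*% p_sub # n x n_base accession-level allele frequency
  het <- matrix(stats::runif(n * n_base) < config$het_rate, n, n_base)
  a1 <- matrix(stats::runif(n * n_base), n, n_base) < freq
  a2 <- matrix(stats::runif(n * n_base), n, n_base) < freq
  geno <- ifelse(het, a1 + a2, 2L * a1)

  # homoeologous duplicates: copy with per-call redraw at rate 1 - dup_cor
  dup_src <- integer(0)
  if (n_dup > 0) {
    dup_src <- sample.int(n_base, n_dup, replace = n_dup > n_base)
    gd <- geno[, dup_src, drop = FALSE]
    redraw <- matrix(stats::runif(n * n_dup) > config$dup_cor, n, n_dup)
    fresh <- 2L * (matrix(stats::runif(n * n_dup), n, n_dup) <
                     freq[, dup_src, drop = FALSE])
    gd[redraw] <- fresh[redraw]
    geno <- cbind(geno, gd)
  }

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    geno[miss] <- NA
  }
  storage.mode(geno) <- "integer"

  # map: base markers on A1/A2, duplicates on the partner C chromosome
  half <- ceiling(n_base / 2)
  chrom_base <- rep(c("A1", "A2"), times = c(half, n_base - half))
  pos_base <- c(seq_len(half), seq_len(n_base - half))
  chrom_dup <- sub("^A", "C", chrom_base[dup_src])
  pos_dup <- pos_base[dup_src]
  ord_dup <- order(chrom_dup, pos_dup)

  marker <- sprintf("M%05d", seq_len(m))
  col_order <- c(seq_len(n_base), n_base + ord_dup)
  geno <- geno[, col_order, drop = FALSE]
  colnames(geno) <- marker
  rownames(geno) <- acc
  map <- data.frame(marker = marker,
                    chrom = c(chrom_base, chrom_dup[ord_dup]),
                    pos = c(pos_base, pos_dup[ord_dup]))
  # original (pre-ordering) column index of each marker, so that causal
  # indices in the config refer to generation order
  gen_index <- col_order

  snps <- snp_matrix(geno, map)
  list(snps = snps, q_matrix = Q,
       truth = list(p_anc = p_anc, p_sub = p_sub, dup_src = dup_src,
                    gen_index = gen_index))
}

# Translate a generation-order marker index into the column name of the
# simulated snp_matrix.
marker_id_for_index <- function(sim, index) {
  colnames(sim$snps$geno)[match(index, sim$truth$gen_index)]
}

#' Pick a common marker to carry a planted causal effect
#'
#' Deterministic rule for recovery studies: the first base (A-genome)
#' marker, in generation order, whose minor allele frequency is at least
#' `min_maf`. Returns its generation-order index, suitable for the
#' `causal_snps`/`cis_marker` fields of [panel_config()].
#'
#' @param sim Result of [simulate_genotypes()].
#' @param min_maf Minimum MAF (default 0.2).
#' @param rank Which qualifying marker to return, in generation order
#'   (default 1 = the first).
#' @return Generation-order marker index.
#' @export
choose_causal_marker <- function(sim, min_maf = 0.2, rank = 1) {
  maf <- minor_allele_freq(sim$snps)
  n_base <- ncol(sim$snps$geno) - length(sim$truth$dup_src)
  gi <- sim$truth$gen_index # generation-order index of each column
  cand <- gi[which(maf >= min_maf)]
  cand <- sort(cand[cand <= n_base])
  if (length(cand) < rank) stop("fewer than ", rank, " base markers with MAF >= ", min_maf)
  cand[rank]
}

#' Homoeologous partner(s) of a simulated marker
#'
#' @param sim Result of [simulate_genotypes()].
#' @param marker_id Marker column name.
#' @return Character vector of partner marker ids (empty if none).
#' @export
homoeologue_of <- function(sim, marker_id) {
  gi <- sim$truth$gen_index
  g <- gi[match(marker_id, colnames(sim$snps$geno))]
  n_base <- ncol(sim$snps$geno) - length(sim$truth$dup_src)
  partners <- if (g <= n_base) {
    n_base + which(sim$truth$dup_src == g)
  } else {
    sim$truth$dup_src[g - n_base]
  }
  marker_id_for_index(sim, partners)
}

#' Simulate unigene RPKM expression with planted cis-eQTL
#'
#' Log2 expression of each unigene is a gene-specific baseline plus
#' Gaussian noise; mediator genes additionally gain `cis_effect` log2 units
#' per alternate-allele copy of their cis marker (missing genotypes take
#' the marker mean). Values are exponentiated to the non-negative RPKM
#' scale.
#'
#' @param config A [panel_config()].
#' @param sim Result of [simulate_genotypes()] for the same config.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(config, sim) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed + 1L)
  n <- config$n_accessions
  ng <- config$n_genes
  baseline <- stats::runif(ng, 2, 8)
  log2r <- matrix(baseline, ng, n) +
    matrix(stats::rnorm(ng * n, 0, config$expr_noise_sd), ng, n)
  if (!is.null(config$mediator_genes)) {
    for (i in seq_len(nrow(config$mediator_genes))) {
      med <- config$mediator_genes[i, ]
      id <- marker_id_for_index(sim, med$cis_marker)
      g <- sim$snps$geno[, id]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      log2r[med$gene, ] <- log2r[med$gene, ] + med$cis_effect * g
    }
  }
  rpkm <- 2^log2r
  rownames(rpkm) <- sprintf("G%05d", seq_len(ng))
  colnames(rpkm) <- rownames(sim$snps$geno)
  half <- ceiling(ng / 2)
  map <- data.frame(unigene = rownames(rpkm),
                    chrom = rep(c("A1", "A2"), times = c(half, ng - half)),
                    pos = c(seq_len(half), seq_len(ng - half)))
  expression_matrix(rpkm, map)
}

# z-construction of a trait with target correlation r to a reference
# z-score, on a given mean/sd scale
corr_trait <- function(z_ref, r, mean, sd) {
  e <- stats::rnorm(length(z_ref))
  z <- r * z_ref + sqrt(max(0, 1 - r^2)) * scale_safe(e)
  mean + sd * z
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate lodging-related traits with known genetic architecture
#'
#' Accession-mean Fmax is an intercept plus planted causal-SNP effects,
#' expression-mediated effects (`trait_effect` x log2 RPKM of each mediator
#' gene), a polygenic term drawn from `N(0, polygenic_sd^2 K)` with K the
#' realised kinship of the simulated panel, and the genetic variance is
#' balanced against replicate-level environmental noise so that the
#' accession-level heritability matches the configuration. Correlated
#' companion traits (F/V, stem diameter, second moment of area, parenchyma
#' area, cortex thickness, hollow area, plant height, stem weight, SLR) are
#' generated around Fmax with realistic means and the configured SLR-Fmax
#' correlation; MOR and MOE are computed from the generated mechanics
#' quantities (span 70 mm).
#'
#' @param config A [panel_config()].
#' @param sim Result of [simulate_genotypes()].
#' @param expr Result of [simulate_expression()] (may be NULL if the config
#'   has no mediator genes).
#' @return A list with `traits` (per-replicate trait table), `accession_means`,
#'   and `truth` (a ground-truth ledger: Q, planted effects, per-accession
#'   genetic values, noise SDs).
#' @export
simulate_traits <- function(config, sim, expr = NULL) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed + 2L)
  n <- config$n_accessions
  acc <- rownames(sim$snps$geno)

  gval <- rep(0, n)
  if (!is.null(config$causal_snps)) {
    for (i in seq_len(nrow(config$causal_snps))) {
      cs <- config$causal_snps[i, ]
      id <- marker_id_for_index(sim, cs$marker)
      g <- sim$snps$geno[, id]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      gval <- gval + cs$effect * g
    }
  }
  if (!is.null(config$mediator_genes)) {
    if (is.null(expr)) stop("mediator genes configured but no expression matrix given")
    for (i in seq_len(nrow(config$mediator_genes))) {
      med <- config$mediator_genes[i, ]
      gval <- gval + med$trait_effect * log2(expr$rpkm[med$gene, ])
    }
  }
  if (config$polygenic_sd > 0) {
    K <- kinship_matrix(sim$snps)
    gval <- gval + as.numeric(MASS::mvrnorm(1, rep(0, n),
                                            config$polygenic_sd^2 * K))
  }

  var_g <- stats::var(gval)
  h2 <- config$heritability
  sigma_env <- if (h2 >= 1) 0
  else if (var_g > 0 && h2 > 0) sqrt(var_g * (1 - h2) / h2)
  else 1 # pure-noise panel default (trait units)

  intercept <- 15 # kg/s scale typical of dried rapeseed stem sections
  fmax_acc <- intercept + gval
  z <- scale_safe(fmax_acc)
  if (all(z == 0)) z <- rep(0, n)

  diam_acc <- pmax(corr_trait(z, 0.69, 9, 1.3), 3)
  hollow_frac <- pmin(pmax(stats::runif(n, 0.05, 0.45), 0), 0.9)
  whole_area <- pi * (diam_acc / 2)^2
  hollow_area <- hollow_frac * whole_area
  d1a <- diameter_from_area(hollow_area)
  I_acc <- second_moment_of_area(diam_acc, d1a)
  f_over_v_acc <- pmax(corr_trait(z, 0.88, 14, 5), 0.5)
  L <- 70; a <- L / 2
  mor_acc <- modulus_of_rupture(fmax_acc, a, diam_acc, I_acc)
  moe_acc <- modulus_of_elasticity(f_over_v_acc, L, I_acc)
  parenchyma_acc <- pmax(corr_trait(z, 0.52, 30, 8), 1)
  cortex_acc <- pmax(corr_trait(z, 0.46, 1.2, 0.3), 0.1)
  height_acc <- pmax(corr_trait(z, 0.39, 150, 20), 40)
  weight_acc <- pmax(corr_trait(z, 0.61, 40, 10), 5)
  slr_acc <- pmax(corr_trait(z, config$slr_correlation, 3, 0.8), 0.2)

  rep_cv <- if (sigma_env == 0) 0 else 0.05
  nr <- config$n_replicates
  rep_noise <- function(mu, sd_abs) {
    rep(mu, each = nr) + stats::rnorm(n * nr, 0, sd_abs)
  }
  traits <- data.frame(
    accession = rep(acc, each = nr),
    replicate = rep(seq_len(nr), times = n),
    fmax = rep_noise(fmax_acc, sigma_env),
    f_over_v = rep_noise(f_over_v_acc, rep_cv * mean(f_over_v_acc)),
    MOR = rep_noise(mor_acc, rep_cv * mean(mor_acc)),
    MOE = rep_noise(moe_acc, rep_cv * mean(moe_acc)),
    stem_diameter = rep_noise(diam_acc, rep_cv * mean(diam_acc)),
    second_moment = rep_noise(I_acc, rep_cv * mean(I_acc)),
    parenchyma_area = rep_noise(parenchyma_acc, rep_cv * mean(parenchyma_acc)),
    cortex_thickness = rep_noise(cortex_acc, rep_cv * mean(cortex_acc)),
    hollow_area = rep_noise(hollow_area, rep_cv * mean(hollow_area)),
    plant_height = rep_noise(height_acc, rep_cv * mean(height_acc)),
    stem_weight = rep_noise(weight_acc, rep_cv * mean(weight_acc)),
    SLR = rep_noise(slr_acc, rep_cv * mean(slr_acc)),
    stringsAsFactors = FALSE
  )
  num <- names(traits)[vapply(traits, is.numeric, TRUE)]
  num <- setdiff(num, "replicate")
  means <- stats::aggregate(traits[num], by = list(accession = traits$accession),
                            FUN = mean)
  means <- means[match(acc, means$accession), ]
  rownames(means) <- NULL

  truth <- list(
    q_matrix = sim$q_matrix,
    causal_snps = if (is.null(config$causal_snps)) NULL else
      cbind(config$causal_snps,
            marker_id = marker_id_for_index(sim, config$causal_snps$marker)),
    mediator_genes = if (is.null(config$mediator_genes)) NULL else
      cbind(config$mediator_genes,
            gene_id = rownames(expr$rpkm)[config$mediator_genes$gene],
            cis_marker_id = marker_id_for_index(sim, config$mediator_genes$cis_marker)),
    genetic_values = stats::setNames(gval, acc),
    sigma_env = sigma_env, heritability = h2,
    slr_correlation = config$slr_correlation,
    whole_area = stats::setNames(whole_area, acc),
    hollow_area = stats::setNames(hollow_area, acc)
  )
  list(traits = traits, accession_means = means, truth = truth)
}

#' Simulate a three-point bend force-displacement curve
#'
#' Force rises linearly at `slope` from zero to `fmax` (the elastic and
#' pre-failure regime collapsed to one linear ramp), then decays
#' exponentially past the failure point; additive Gaussian noise of the
#' given SD is applied when `noise_sd > 0`. With `noise_sd = 0` the peak
#' force equals `fmax` and the pre-failure slope equals `slope` exactly.
#'
#' @param fmax Peak force (> 0), instrument units.
#' @param slope Elastic slope (> 0), force per mm.
#' @param noise_sd Additive noise SD (default 0).
#' @param seed Optional RNG seed.
#' @param step Displacement sampling step (mm). The default 0.004 mm
#'   corresponds to 500 samples/s at the standard 2 mm/s probe speed.
#' @return A [bend_curve()].
#' @export
simulate_bend_curve <- function(fmax, slope, noise_sd = 0, seed = NULL,
                                step = 0.004) {
  if (!is.finite(fmax) || fmax <= 0) stop("fmax must be > 0")
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0")
  if (!is.null(seed)) set.seed(seed)
  d_break <- fmax / slope
  n_rise <- max(10L, ceiling(d_break / step))
  d_rise <- seq(0, d_break, length.out = n_rise + 1L)
  dt <- d_rise[2] - d_rise[1]
  d_tail <- d_break + seq_len(15L) * dt
  force <- c(slope * d_rise, fmax * exp(-5 * (d_tail - d_break) / d_break))
  disp <- c(d_rise, d_tail)
  if (noise_sd > 0) force <- force + stats::rnorm(length(force), 0, noise_sd)
  bend_curve(disp, force)
}

# Gaussian peak helper on a wavenumber grid
gauss_peak <- function(wn, centre, amp, width) {
  amp * exp(-0.5 * ((wn - centre) / width)^2)
}

#' Simulate replicate FTIR spectra at a given pectin esterification level
#'
#' Spectra cover 800-4000 cm^-1 on a 2 cm^-1 grid and combine fixed
#' cell-wall background bands (polysaccharide backbone around 1050/1160,
#' aromatic 1515, CH stretch 2925, broad OH 3350 cm^-1) with the two
#' esterification-state marker bands: the ester carbonyl at 1740 cm^-1,
#' amplitude `ester_amp * ester_level`, and the de-esterified carboxylate
#' at 1624 cm^-1, amplitude `ester_amp * (1 - ester_level)`; Gaussian
#' noise is added per replicate.
#'
#' @param ester_level Methylesterification fraction in [0, 1].
#' @param n_replicates Number of replicate spectra (default 6: two spectra
#'   per sample, three plants per genotype).
#' @param seed Optional RNG seed.
#' @param noise_sd Noise SD (absorbance units, default 0.003).
#' @param ester_amp Full-scale amplitude of the two marker bands (default 0.45).
#' @return A list of raw [ftir_spectrum()] objects.
#' @export
simulate_spectra <- function(ester_level, n_replicates = 6, seed = NULL,
                             noise_sd = 0.003, ester_amp = 0.45) {
  if (!is.finite(ester_level) || ester_level < 0 || ester_level > 1) {
    stop("ester_level must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  wn <- seq(800, 4000, by = 2)
  base <- 0.02 +
    gauss_peak(wn, 1050, 1.00, 40) +
    gauss_peak(wn, 1160, 0.35, 20) +
    gauss_peak(wn, 1515, 0.15, 12) +
    gauss_peak(wn, 2925, 0.25, 30) +
    gauss_peak(wn, 3350, 0.50, 120) +
    gauss_peak(wn, 1740, ester_amp * ester_level, 14) +
    gauss_peak(wn, 1624, ester_amp * (1 - ester_level), 16)
  lapply(seq_len(n_replicates), function(i) {
    ab <- base + if (noise_sd > 0) stats::rnorm(length(wn), 0, noise_sd) else 0
    ftir_spectrum(wn, ab)
  })
}

#' Simulate a complete panel and optionally write it to disk
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_expression()] and [simulate_traits()]; with `outdir` set, the
#' panel is written in the tab-delimited/CSV formats consumed by the
#' pipeline readers, together with per-sample bend-curve CSVs, a geometry
#' table and a `truth.json` ground-truth ledger.
#'
#' @param config A [panel_config()] (or a YAML/JSON file path of its fields).
#' @param outdir Optional output directory.
#' @return A list `snps`, `q_matrix`, `expr`, `traits`, `accession_means`,
#'   `truth` (and `paths` when written).
#' @export
simulate_panel <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_panel_config(config)
  sim <- simulate_genotypes(config)
  expr <- simulate_expression(config, sim)
  tr <- simulate_traits(config, sim, expr)
  out <- list(snps = sim$snps, q_matrix = sim$q_matrix, expr = expr,
              traits = tr$traits, accession_means = tr$accession_means,
              truth = c(tr$truth, list(p_sub = sim$truth$p_sub,
                                       dup_src = sim$truth$dup_src,
                                       gen_index = sim$truth$gen_index)))
  if (!is.null(outdir)) {
    out$paths <- write_panel(out, config, outdir)
  }
  out
}

#' Read a panel configuration from a YAML or JSON file
#'
#' @param path File with [panel_config()] fields as top-level keys;
#'   `causal_snps` and `mediator_genes` as lists of records.
#' @return A `panel_config` object.
#' @export
read_panel_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  for (fld in c("causal_snps", "mediator_genes")) {
    if (!is.null(cfg[[fld]])) cfg[[fld]] <- as.data.frame(cfg[[fld]])
  }
  do.call(panel_config, cfg)
}
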