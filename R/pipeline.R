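#' Write an association-scan result table (tab-delimited, with provenance)
#'
#' @param results An `assoc_result` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assoc_results <- function(results, path) {
  write_tsv_prov(as.data.frame(results), path, "association_scan",
                 list(method = attr(results, "method"),
                      delta = attr(results, "delta"),
                      n_skipped = attr(results, "n_skipped")))
}

#' Manhattan plot of an association scan
#'
#' Plots -log10(P) against cumulative marker index, with alternating
#' colour blocks per pseudochromosome along the x axis. Results must be in
#' genome order (as emitted by the scans). Rendering is deterministic for
#' fixed inputs.
#'
#' @param results An `assoc_result` data.frame (from [mlm_scan()],
#'   [gem_scan()] or [expression_as_trait()]).
#' @param threshold Optional horizontal significance line (raw P).
#' @param title Plot title.
#' @return A ggplot object. Chromosome block boundaries (cumulative marker
#'   counts) are attached as attribute `block_boundaries`.
#' @export
make_manhattan <- function(results, threshold = NULL, title = "Association scan") {
  df <- as.data.frame(results)
  df <- df[!is.na(df$P), ]
  if (nrow(df) == 0L) stop("no scored markers to plot")
  df$index <- seq_len(nrow(df))
  df$neglogp <- -log10(df$P)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  bounds <- cumsum(table(df$chrom)[levels(df$chrom)])
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$neglogp,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "marker (pseudomolecule order)",
                  y = expression(-log[10](italic(P))),
                  colour = "linkage group", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    g <- g + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  attr(g, "block_boundaries") <- bounds
  g
}

#' Run configuration for the end-to-end pipeline
#'
#' @param genotypes,expression,q_matrix Paths to the genotype/RPKM/Q inputs.
#' @param traits Path to a per-replicate trait CSV (optional when curves
#'   and geometry are given).
#' @param curves_dir,geometry Paths to the bend-curve directory and
#'   geometry CSV (optional when `traits` is given).
#' @param outdir Output directory.
#' @param span_L Bend-test support span (mm, default 70).
#' @param maf_threshold MAF filter threshold (default 0.05).
#' @param scan_traits Trait columns to scan (default `"fmax"`).
#' @param n_top_gems Number of top GEMs to remap as expression traits
#'   (default 1).
#' @param seed Integer seed used for every stochastic step.
#' @return A validated `run_config` list.
#' @export
run_config <- function(genotypes, expression = NULL, q_matrix = NULL,
                       traits = NULL, curves_dir = NULL, geometry = NULL,
                       outdir = "lodgeAT_out", span_L = 70,
                       maf_threshold = 0.05, scan_traits = "fmax",
                       n_top_gems = 1, seed = 1L) {
  if (is.null(traits) && (is.null(curves_dir) || is.null(geometry))) {
    stop("config must provide either a trait table or curves + geometry")
  }
  if (maf_threshold <= 0 || maf_threshold > 0.5) {
    stop("maf_threshold must be in (0, 0.5]")
  }
  if (span_L <= 0) stop("span_L must be > 0")
  cfg <- list(genotypes = genotypes, expression = expression,
              q_matrix = q_matrix, traits = traits, curves_dir = curves_dir,
              geometry = geometry, outdir = outdir, span_L = span_L,
              maf_threshold = maf_threshold, scan_traits = scan_traits,
              n_top_gems = n_top_gems, seed = as.integer(seed))
  for (f in c("genotypes", "expression", "q_matrix", "traits", "curves_dir",
              "geometry")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config path does not exist: ", f, " = ", cfg[[f]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full lodging-resistance analysis pipeline
#'
#' Chains the stages in analysis order: mechanics (when curves and geometry
#' are supplied) -> trait descriptive statistics -> MAF filter -> kinship ->
#' mixed-model SNP scan per trait -> GEM scan -> expression-as-trait remap
#' of the top GEMs. Every stage's outputs are written under the configured
#' output directory as tab-delimited/CSV files with provenance headers;
#' rerunning with the same config and seed reproduces them byte-identically
#' apart from the timestamp line.
#'
#' @param config A [run_config()] or the path of a YAML/JSON file of its
#'   fields.
#' @return A report list: stage outputs (`trait_table`, `anova`,
#'   `correlations`, `snp_scans`, `gem_scan`, `expression_trait_scans`),
#'   `top_associations`, `maf_counts`, and `paths` of everything written.
#' @export
run_full <- function(config) {
  if (is.character(config)) {
    cfg <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
    config <- do.call(run_config, cfg)
  }
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  report <- list()

  # mechanics stage
  if (!is.null(config$curves_dir)) {
    geom <- utils::read.csv(config$geometry, stringsAsFactors = FALSE)
    curves <- lapply(stats::setNames(nm = as.character(geom$sample)), function(id) {
      read_bend_curve(file.path(config$curves_dir, paste0(id, ".csv")))
    })
    mech <- derive_stem_traits_batch(curves, geom, L = config$span_L)
    trait_table <- data.frame(
      accession = mech$samples$accession,
      replicate = stats::ave(seq_len(nrow(mech$samples)),
                             mech$samples$accession, FUN = seq_along),
      mech$samples[c("fmax", "f_over_v", "I", "MOR", "MOE", "D2")])
    names(trait_table)[names(trait_table) == "I"] <- "second_moment"
    names(trait_table)[names(trait_table) == "D2"] <- "stem_diameter"
    paths$mechanics <- file.path(config$outdir, "mechanics_traits.csv")
    write_traits(mech$samples, paths$mechanics)
  } else {
    trait_table <- read_traits(config$traits)
  }
  report$trait_table <- trait_table

  # descriptive statistics
  scan_traits <- intersect(config$scan_traits, names(trait_table))
  if (!length(scan_traits)) stop("none of the scan_traits are in the trait table")
  report$anova <- lapply(stats::setNames(nm = scan_traits), function(tr) {
    genotype_anova(trait_table, tr)
  })
  num <- setdiff(names(trait_table)[vapply(trait_table, is.numeric, TRUE)],
                 "replicate")
  acc_means <- stats::aggregate(trait_table[num],
                                by = list(accession = trait_table$accession),
                                FUN = mean)
  if (length(num) >= 2 && nrow(acc_means) >= 3) {
    report$correlations <- correlation_matrix(acc_means)
    paths$correlations <- file.path(config$outdir, "trait_correlations.csv")
    write_correlation_table(report$correlations, paths$correlations)
  }

  # association stage
  snps <- read_genotypes(config$genotypes)
  common <- intersect(rownames(snps$geno), acc_means$accession)
  if (length(common) < 3) stop("fewer than 3 accessions shared between genotypes and traits")
  snps <- snp_matrix(snps$geno[common, , drop = FALSE], snps$map, snps$alleles)
  acc_means <- acc_means[match(common, acc_means$accession), ]
  Q <- if (!is.null(config$q_matrix)) {
    read_q_matrix(config$q_matrix)[common, , drop = FALSE]
  } else NULL

  filtered <- maf_filter(snps, config$maf_threshold)
  report$maf_counts <- attr(filtered, "maf_filter")
  K <- kinship_matrix(filtered)
  report$snp_scans <- list()
  top <- list()
  for (tr in scan_traits) {
    y <- stats::setNames(acc_means[[tr]], acc_means$accession)
    res <- mlm_scan(y, filtered, Q = Q, K = K)
    report$snp_scans[[tr]] <- res
    paths[[paste0("snp_scan_", tr)]] <- file.path(
      config$outdir, sprintf("snp_scan_%s.tsv", tr))
    write_assoc_results(res, paths[[paste0("snp_scan_", tr)]])
    pl <- make_manhattan(res, title = sprintf("SNP scan: %s", tr))
    paths[[paste0("manhattan_", tr)]] <- file.path(
      config$outdir, sprintf("manhattan_%s.png", tr))
    ggplot2::ggsave(paths[[paste0("manhattan_", tr)]], pl,
                    width = 8, height = 3.5, dpi = 150)
    best <- res[which.min(res$P), ]
    top[[paste0("snp_", tr)]] <- best
  }

  # GEM stage
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression)
    expr <- expression_matrix(expr$rpkm[, common, drop = FALSE], expr$map)
    y <- stats::setNames(acc_means[[scan_traits[1]]], acc_means$accession)
    gres <- gem_scan(y, expr, Q = Q)
    report$gem_scan <- gres
    paths$gem_scan <- file.path(config$outdir, "gem_scan.tsv")
    write_assoc_results(gres, paths$gem_scan)
    top$gem <- gres[which.min(gres$P), ]

    n_top <- min(config$n_top_gems, sum(!is.na(gres$P)))
    top_gems <- gres$unigene[order(gres$P)][seq_len(n_top)]
    report$expression_trait_scans <- lapply(
      stats::setNames(nm = top_gems), function(ug) {
        res2 <- expression_as_trait(ug, expr, filtered, Q = Q, K = K)
        paths[[paste0("expr_trait_", ug)]] <<- file.path(
          config$outdir, sprintf("expr_trait_%s.tsv", ug))
        write_assoc_results(res2, paths[[paste0("expr_trait_", ug)]])
        res2
      })
    top$expression_trait <- lapply(report$expression_trait_scans,
                                   function(r) r[which.min(r$P), ])
  }

  report$top_associations <- top
  report$paths <- paths
  report$config <- unclass(config)
  invisible(report)
}
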