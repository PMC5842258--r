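# Shared small fixtures, built once per test run.

# A small structured panel with one planted causal SNP and one
# expression-mediated effect; reused by assoc and pipeline tests.
default_test_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # plant effects on common markers (MAF >= 0.2): same seed, so the
      # genotype draw is identical between the probe and the final panel
      cfg0 <- panel_config(n_accessions = 60, n_markers = 800, n_genes = 150,
                           seed = 42)
      sim0 <- simulate_genotypes(cfg0)
      causal_idx <- choose_causal_marker(sim0, rank = 1)
      cis_idx <- choose_causal_marker(sim0, rank = 10)
      cfg <- panel_config(
        n_accessions = 60, n_markers = 800, n_genes = 150,
        causal_snps = data.frame(marker = causal_idx, effect = 2.5),
        mediator_genes = data.frame(gene = 10, cis_marker = cis_idx,
                                    cis_effect = 1, trait_effect = 1),
        seed = 42)
      cache <<- simulate_panel(cfg)
    }
    cache
  }
})

# tiny hand-built snp_matrix from an explicit genotype matrix
toy_snps <- function(geno, chrom = "A1") {
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("ACC%02d", seq_len(nrow(geno)))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("M%03d", seq_len(ncol(geno)))
  }
  snp_matrix(geno, data.frame(marker = colnames(geno),
                              chrom = chrom, pos = seq_len(ncol(geno))))
}

# named trait vector from accession means
trait_vec <- function(panel, trait = "fmax") {
  stats::setNames(panel$accession_means[[trait]],
                  panel$accession_means$accession)
}
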