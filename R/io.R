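# Tabular IO: every writer emits UTF-8 tab-delimited text with
# '#'-prefixed provenance header lines; readers skip such lines.

provenance_header <- function(what, params = list()) {
  c(sprintf("# lodgeAT %s", what),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    if (length(params)) sprintf("# %s = %s", names(params),
                                vapply(params, function(x) paste(format(x), collapse = ","), "")))
}

write_tsv_prov <- function(df, path, what, params = list(), digits = 6) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) {
    x <- df[[j]]
    df[[j]] <- ifelse(is.na(x), NA,
                      ifelse(abs(x) < 1e-3 & x != 0,
                             formatC(x, digits = 3, format = "e"),
                             signif(x, digits)))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(what, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SNP panel in the package's tab-delimited genotype format
#'
#' One row per marker: `marker`, `chrom`, `pos`, `allele0`, `allele1`,
#' then one column per accession with calls in {0,1,2,NA}.
#'
#' @param snps A [snp_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(snps, path) {
  stopifnot(inherits(snps, "snp_matrix"))
  df <- cbind(snps$map[c("marker", "chrom", "pos")],
              snps$alleles[c("allele0", "allele1")],
              as.data.frame(t(snps$geno)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header("genotypes",
                               list(n_accessions = nrow(snps$geno),
                                    n_markers = ncol(snps$geno))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

# Convert one HapMap-dialect call column against the marker's allele pair
decode_hapmap_calls <- function(calls, allele0, allele1) {
  out <- rep(NA_integer_, length(calls))
  out[calls == allele0] <- 0L
  out[calls == allele1] <- 2L
  het <- iupac_het[calls]
  pair <- paste0(pmin(allele0, allele1), pmax(allele0, allele1))
  out[!is.na(het) & het == pair] <- 1L
  out
}

#' Read a SNP genotype file (native or HapMap dialect, auto-detected)
#'
#' The native format is the one written by [write_genotypes()]. The HapMap
#' dialect (as distributed for transcriptome SNP panels) is detected from
#' its `rs#`/`alleles` header: calls are single IUPAC letters, homozygotes
#' as the base, heterozygotes as the two-base ambiguity code, `N` missing;
#' the `alleles` column (e.g. `A/G`) fixes the 0/2 coding, with allele0 the
#' first listed.
#'
#' @param path Genotype file path.
#' @return A [snp_matrix()].
#' @export
read_genotypes <- function(path) {
  head_lines <- readLines(path, n = 50L)
  header <- head_lines[!startsWith(head_lines, "#")][1]
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          skip = sum(startsWith(head_lines, "#")),
                          na.strings = c("NA", ""))
  if (startsWith(header, "rs#") || all(c("rs#", "alleles") %in% names(dt)) ||
      all(c("rs", "alleles") %in% names(dt))) {
    # HapMap dialect: rs# alleles chrom pos strand assembly# center
    # protLSID assayLSID panelLSID QCcode acc1 ... accN
    id_col <- if ("rs#" %in% names(dt)) "rs#" else "rs"
    meta <- intersect(c(id_col, "alleles", "chrom", "pos", "strand",
                        "assembly#", "center", "protLSID", "assayLSID",
                        "panelLSID", "QCcode"), names(dt))
    acc_cols <- setdiff(names(dt), meta)
    al <- strsplit(as.character(dt$alleles), "/", fixed = TRUE)
    allele0 <- toupper(vapply(al, `[`, "", 1))
    allele1 <- toupper(vapply(al, function(x) if (length(x) > 1) x[2] else NA_character_, ""))
    geno <- vapply(seq_len(nrow(dt)), function(i) {
      decode_hapmap_calls(toupper(as.character(dt[i, acc_cols])),
                          allele0[i], allele1[i])
    }, integer(length(acc_cols)))
    rownames(geno) <- acc_cols
    colnames(geno) <- as.character(dt[[id_col]])
    map <- data.frame(marker = colnames(geno), chrom = dt$chrom, pos = dt$pos)
    alleles <- data.frame(marker = colnames(geno),
                          allele0 = allele0, allele1 = allele1)
  } else {
    meta <- c("marker", "chrom", "pos", "allele0", "allele1")
    if (!all(meta %in% names(dt))) {
      stop("unrecognised genotype format: expected native or HapMap header")
    }
    acc_cols <- setdiff(names(dt), meta)
    geno <- t(as.matrix(dt[acc_cols]))
    colnames(geno) <- dt$marker
    map <- dt[c("marker", "chrom", "pos")]
    alleles <- dt[c("marker", "allele0", "allele1")]
  }
  ord <- order(map$chrom, map$pos)
  snp_matrix(geno[, ord, drop = FALSE], map[ord, ], alleles[ord, ])
}

#' Write an expression matrix as tab-delimited unigene x accession RPKM
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- cbind(expr$map[c("unigene", "chrom", "pos")],
              as.data.frame(expr$rpkm))
  write_tsv_prov(df, path, "expression_rpkm",
                 list(n_unigenes = nrow(expr$rpkm),
                      n_accessions = ncol(expr$rpkm)))
}

#' Read a tab-delimited unigene x accession RPKM matrix
#'
#' Accepts the format written by [write_expression()]; `chrom`/`pos`
#' columns are optional.
#'
#' @param path Input path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  meta <- intersect(c("unigene", "chrom", "pos"), names(dt))
  acc_cols <- setdiff(names(dt), meta)
  rpkm <- as.matrix(dt[acc_cols])
  rownames(rpkm) <- as.character(dt$unigene)
  map <- if (all(c("chrom", "pos") %in% meta)) dt[c("unigene", "chrom", "pos")] else NULL
  expression_matrix(rpkm, map)
}

#' Write / read an accession x subpopulation Q matrix (CSV)
#'
#' @param q Matrix with accession rownames, columns = subpopulations.
#' @param path CSV path.
#' @return `write_q_matrix`: the path; `read_q_matrix`: a numeric matrix
#'   whose rows sum to 1.
#' @export
write_q_matrix <- function(q, path) {
  df <- data.frame(accession = rownames(q), as.data.frame(q))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_q_matrix
#' @export
read_q_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[setdiff(names(df), "accession")])
  rownames(m) <- df$accession
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("Q matrix rows must sum to 1")
  }
  m
}

#' Write / read the per-replicate trait table (CSV)
#'
#' @param traits Data.frame keyed by (accession, replicate).
#' @param path CSV path.
#' @return The path / the data.frame.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a per-sample bend-curve CSV (`displacement_mm,force`)
#'
#' @param path CSV path.
#' @return A [bend_curve()].
#' @export
read_bend_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("displacement_mm", "force") %in% names(df))) {
    stop("curve CSV needs columns displacement_mm, force")
  }
  bend_curve(df$displacement_mm, df$force)
}

#' Write a bend curve as CSV
#' @param curve A [bend_curve()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_bend_curve <- function(curve, path) {
  utils::write.csv(data.frame(displacement_mm = curve$displacement,
                              force = curve$force),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read FTIR spectra from CSV
#'
#' Either a single-spectrum file (`wavenumber_cm1,absorbance`) or a
#' long-format multi-spectrum table with additional `sample` (and
#' optionally `genotype`) columns.
#'
#' @param path CSV path.
#' @return A single [ftir_spectrum()], or a named list of them for
#'   long-format input (names = sample ids; genotype kept as an attribute).
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavenumber_cm1", "absorbance") %in% names(df))) {
    stop("spectra CSV needs columns wavenumber_cm1, absorbance")
  }
  if (!"sample" %in% names(df)) {
    return(ftir_spectrum(df$wavenumber_cm1, df$absorbance))
  }
  out <- lapply(split(df, df$sample), function(d) {
    s <- ftir_spectrum(d$wavenumber_cm1, d$absorbance)
    if ("genotype" %in% names(d)) attr(s, "genotype") <- d$genotype[1]
    s
  })
  out
}

#' Write FTIR spectra to a long-format CSV
#' @param spectra Named list of [ftir_spectrum()] objects.
#' @param path CSV path.
#' @param genotypes Optional character vector of genotype labels per spectrum.
#' @return The path, invisibly.
#' @export
write_spectra <- function(spectra, path, genotypes = NULL) {
  if (is.null(names(spectra))) names(spectra) <- sprintf("S%03d", seq_along(spectra))
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.frame(sample = names(spectra)[i],
               genotype = if (is.null(genotypes)) NA_character_ else genotypes[i],
               wavenumber_cm1 = s$wavenumber, absorbance = s$absorbance)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth ledger of a simulated panel as JSON
#'
#' @param truth Truth list from [simulate_traits()] / [simulate_panel()].
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  # keep the ledger focused on planted effects and noise levels
  tr[c("q_matrix", "p_sub", "gen_index", "dup_src")] <- NULL
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

# Write every component of a simulated panel under outdir
write_panel <- function(panel, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    genotypes = file.path(outdir, "genotypes.tsv"),
    expression = file.path(outdir, "expression.tsv"),
    q_matrix = file.path(outdir, "q_matrix.csv"),
    traits = file.path(outdir, "traits.csv"),
    geometry = file.path(outdir, "geometry.csv"),
    curves_dir = file.path(outdir, "curves"),
    truth = file.path(outdir, "truth.json")
  )
  write_genotypes(panel$snps, p$genotypes)
  write_expression(panel$expr, p$expression)
  write_q_matrix(panel$q_matrix, p$q_matrix)
  write_traits(panel$traits, p$traits)
  dir.create(p$curves_dir, showWarnings = FALSE)
  geom_rows <- list()
  set.seed(config$seed + 3L)
  for (i in seq_len(nrow(panel$traits))) {
    row <- panel$traits[i, ]
    id <- sprintf("%s_r%d", row$accession, row$replicate)
    cur <- simulate_bend_curve(max(row$fmax, 0.5), max(row$f_over_v, 0.5),
                               noise_sd = 0.01 * row$fmax)
    write_bend_curve(cur, file.path(p$curves_dir, paste0(id, ".csv")))
    acc <- as.character(row$accession)
    geom_rows[[i]] <- data.frame(
      sample = id, accession = acc,
      whole_area_mm2 = panel$truth$whole_area[acc],
      hollow_area_mm2 = panel$truth$hollow_area[acc],
      parenchyma_area_mm2 = row$parenchyma_area,
      cortex_thickness_mm = row$cortex_thickness)
  }
  geom <- do.call(rbind, geom_rows)
  rownames(geom) <- NULL
  utils::write.csv(geom, p$geometry, row.names = FALSE)
  write_truth(panel$truth, p$truth)
  p
}
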