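#' Allele-class t-test of a trait on a validation panel
#'
#' Tests whether trait values segregate with the scored allele classes of a
#' validation marker on an independent test panel. Replicate plant values
#' are collapsed to accession means before testing (so the test is on
#' genetically independent units); heterozygous calls are excluded from the
#' two-class comparison and reported separately. Welch's unequal-variance
#' t-test is the default; set `var_equal = TRUE` for the pooled form.
#'
#' @param panel Data.frame with columns `accession`, `allele_class`,
#'   `replicate`, and the trait column (default `fmax`). Missing allele
#'   calls (`NA`) are dropped.
#' @param classes Optional length-2 character vector naming the two
#'   homozygous classes to compare; by default the two most frequent
#'   single-allele classes. Classes containing two distinct allele letters
#'   (e.g. `"A/G"`, `"AG"`) are treated as heterozygous.
#' @param trait Trait column name, default `"fmax"`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param use_accession_means Collapse replicates to accession means first
#'   (default TRUE).
#' @return A list with `t`, `P`, `df`, `class_means`, `class_sizes`,
#'   `classes`, `n_het_excluded`, `method`.
#' @export
allele_ttest <- function(panel, classes = NULL, trait = "fmax",
                         var_equal = FALSE, use_accession_means = TRUE) {
  req <- c("accession", "allele_class", trait)
  if (!all(req %in% names(panel))) {
    stop("panel must have columns: ", paste(req, collapse = ", "))
  }
  panel <- panel[!is.na(panel$allele_class) & is.finite(panel[[trait]]), ]
  cls <- as.character(panel$allele_class)
  is_het <- vapply(cls, function(x) {
    a <- unique(strsplit(gsub("[^A-Za-z]", "", x), "")[[1]])
    length(a) > 1L
  }, TRUE)
  n_het <- length(unique(panel$accession[is_het]))
  homo <- panel[!is_het, ]
  if (is.null(classes)) {
    tab <- sort(table(homo$allele_class), decreasing = TRUE)
    if (length(tab) < 2L) stop("fewer than two homozygous allele classes present")
    classes <- names(tab)[1:2]
  }
  vals <- lapply(classes, function(cl) {
    d <- homo[homo$allele_class == cl, ]
    if (nrow(d) == 0L) stop("allele class '", cl, "' is empty")
    if (use_accession_means) {
      as.numeric(tapply(d[[trait]], d$accession, mean))
    } else {
      d[[trait]]
    }
  })
  if (any(lengths(vals) < 2L)) stop("each allele class needs >= 2 observations")
  tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = var_equal)
  list(t = unname(tt$statistic), P = tt$p.value, df = unname(tt$parameter),
       class_means = stats::setNames(vapply(vals, mean, 0), classes),
       class_sizes = stats::setNames(lengths(vals), classes),
       classes = classes, n_het_excluded = n_het,
       method = if (var_equal) "pooled" else "welch")
}

#' Allele frequencies by subpopulation, with an independence test
#'
#' Cross-tabulates the scored allele classes against hard subpopulation
#' assignments (argmax of each accession's ancestry row in Q) and tests
#' independence with a chi-square test (no continuity correction, so the
#' statistic matches the direct formula). Approximately equal class
#' frequencies across subpopulations indicate a marker-trait association
#' that is not merely an artefact of population structure.
#'
#' @param panel Data.frame with `accession` and `allele_class` (one row per
#'   accession is enough; duplicates are collapsed to the first call).
#' @param q_matrix Numeric matrix/data.frame of ancestry fractions with
#'   rownames (or an `accession` column) matching the panel.
#' @return A list with `counts` (class x subpop), `frequencies` (columns sum
#'   to 1), `chisq`, `df`, `P`.
#' @export
allele_frequency_by_subpop <- function(panel, q_matrix) {
  if (is.data.frame(q_matrix) && "accession" %in% names(q_matrix)) {
    rn <- q_matrix$accession
    q_matrix <- as.matrix(q_matrix[setdiff(names(q_matrix), "accession")])
    rownames(q_matrix) <- rn
  }
  q_matrix <- as.matrix(q_matrix)
  panel <- panel[!is.na(panel$allele_class), ]
  panel <- panel[!duplicated(panel$accession), ]
  common <- intersect(as.character(panel$accession), rownames(q_matrix))
  if (length(common) == 0L) stop("no accessions shared between panel and Q matrix")
  panel <- panel[match(common, panel$accession), ]
  assign <- max.col(q_matrix[common, , drop = FALSE], ties.method = "first")
  if (length(unique(assign)) < ncol(q_matrix)) {
    warning("subpopulation(s) with zero assigned accessions")
  }
  counts <- table(allele = as.character(panel$allele_class),
                  subpop = factor(assign, levels = seq_len(ncol(q_matrix))))
  freqs <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(counts = counts, frequencies = freqs,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       P = ct$p.value)
}
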