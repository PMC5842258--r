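#' One-way ANOVA of a trait across accessions, with log10 fallback
#'
#' Fits `trait ~ accession` by one-way ANOVA (Type-I sums of squares on the
#' single factor, valid for balanced and unbalanced designs alike). Residual
#' normality is checked with a Shapiro-Wilk test; if rejected at
#' `alpha_normality` the ANOVA is recomputed on log10-transformed values and
#' the result flagged. When zeros or negative values are present a small
#' positive offset (half the smallest positive spacing above the minimum,
#' floored at 1e-6) is added before the log and recorded in the output.
#'
#' @param table Trait table: data.frame with an `accession` column and one
#'   column per trait; one row per (accession, replicate).
#' @param trait Name of the trait column to analyse.
#' @param alpha_normality Shapiro-Wilk significance level triggering the
#'   log10 fallback (default 0.05).
#' @return A list with `F`, `P`, `df`, `used_log10`, `offset`, `shapiro_p`,
#'   `n_accessions`, `n_obs`.
#' @export
genotype_anova <- function(table, trait, alpha_normality = 0.05) {
  if (!trait %in% names(table)) stop("trait '", trait, "' not in table")
  if (!"accession" %in% names(table)) stop("table needs an 'accession' column")
  y <- table[[trait]]
  g <- factor(table$accession)
  ok <- is.finite(y)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("need >= 2 accessions with data for '", trait, "'")
  if (length(y) <= nlevels(g)) stop("need replication beyond one value per accession")

  fit_one <- function(yy) {
    av <- stats::anova(stats::lm(yy ~ g))
    list(F = av$`F value`[1], P = av$`Pr(>F)`[1],
         df = c(av$Df[1], av$Df[2]), resid = stats::lm(yy ~ g)$residuals)
  }
  res <- fit_one(y)
  sw_p <- NA_real_
  n <- length(y)
  if (n >= 3 && n <= 5000 && stats::sd(res$resid) > 0) {
    sw_p <- stats::shapiro.test(res$resid)$p.value
  }
  used_log10 <- FALSE
  offset <- 0
  if (is.finite(sw_p) && sw_p < alpha_normality) {
    if (min(y) <= 0) {
      pos <- y[y > 0]
      offset <- if (length(pos)) max(min(pos) / 2, 1e-6) else 1e-6
      offset <- offset - min(y, 0)
    }
    res <- fit_one(log10(y + offset))
    used_log10 <- TRUE
  }
  list(F = res$F, P = res$P, df = res$df, used_log10 = used_log10,
       offset = offset, shapiro_p = sw_p,
       n_accessions = nlevels(g), n_obs = n)
}

#' Pairwise Pearson correlation panel of accession-mean traits
#'
#' Computes the symmetric Pearson correlation matrix over accession means
#' with pairwise-complete handling of missing values, two-sided P-values of
#' each coefficient against zero, significance stars at the 0.05 / 0.01 /
#' 0.001 tiers, and the squared coefficients (reported alongside r because
#' published trait-correlation tables are labelled inconsistently between
#' r and R^2).
#'
#' @param accession_means Data.frame of accession-level trait means; any
#'   non-numeric columns (e.g. `accession`) are dropped.
#' @return A list of matrices `r`, `r_squared`, `P`, `n` plus a character
#'   matrix `stars` (`"***"` P <= 0.001, `"**"` P <= 0.01, `"*"` P <= 0.05).
#'   Constant columns yield NA entries with a warning.
#' @export
correlation_matrix <- function(accession_means) {
  num <- accession_means[vapply(accession_means, is.numeric, TRUE)]
  if (ncol(num) < 2L) stop("need >= 2 numeric trait columns")
  if (nrow(num) < 3L) stop("need >= 3 accessions")
  sds <- vapply(num, function(x) stats::sd(x, na.rm = TRUE), 0)
  if (any(!is.finite(sds) | sds == 0)) {
    warning("constant trait column(s): ",
            paste(names(num)[!is.finite(sds) | sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  p <- ncol(num)
  r <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(as.matrix(num)))
  # two-sided t test of r against zero, pairwise n
  tstat <- r * sqrt(pmax(nmat - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  P <- 2 * stats::pt(abs(tstat), df = pmax(nmat - 2, 1), lower.tail = FALSE)
  diag(P) <- 0
  stars <- matrix("", p, p, dimnames = dimnames(r))
  stars[!is.na(P) & P <= 0.05] <- "*"
  stars[!is.na(P) & P <= 0.01] <- "**"
  stars[!is.na(P) & P <= 0.001] <- "***"
  diag(stars) <- ""
  list(r = r, r_squared = r^2, P = P, n = nmat, stars = stars)
}

#' Write a correlation panel as a lower-triangle table
#'
#' Mirrors the conventional published layout: traits down the rows, the
#' lower triangle filled with star-annotated coefficients.
#'
#' @param cm Result of [correlation_matrix()].
#' @param path Output CSV path.
#' @param what Which coefficient to print, `"r"` (default) or `"r_squared"`.
#' @return Invisibly, the character matrix written.
#' @export
write_correlation_table <- function(cm, path, what = c("r", "r_squared")) {
  what <- match.arg(what)
  m <- cm[[what]]
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (j < i) out[i, j] <- paste0(cm$stars[i, j], formatC(m[i, j], digits = 2, format = "f"))
    }
  }
  utils::write.csv(out, path)
  invisible(out)
}
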