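#' Unigene expression matrix (RPKM)
#'
#' Transcript abundance per unigene and accession, as reads per kilobase
#' per million aligned reads, together with each unigene's pseudomolecule
#' position so that GEM-scan results can be plotted in genome order.
#'
#' @param rpkm Non-negative numeric matrix, unigenes in rows (rownames),
#'   accessions in columns (colnames).
#' @param map Data.frame `unigene`, `chrom`, `pos` covering every row of
#'   `rpkm`; generated as consecutive positions if omitted.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(rpkm, map = NULL) {
  rpkm <- as.matrix(rpkm)
  if (is.null(rownames(rpkm)) || is.null(colnames(rpkm))) {
    stop("rpkm needs unigene rownames and accession colnames")
  }
  if (anyNA(rpkm) || any(rpkm < 0)) stop("RPKM values must be non-negative")
  if (is.null(map)) {
    map <- data.frame(unigene = rownames(rpkm), chrom = "U1",
                      pos = seq_len(nrow(rpkm)))
  }
  if (!all(c("unigene", "chrom", "pos") %in% names(map))) {
    stop("map needs columns unigene, chrom, pos")
  }
  if (!setequal(map$unigene, rownames(rpkm))) {
    stop("unigene map must cover exactly the rows of rpkm")
  }
  map <- map[match(rownames(rpkm), map$unigene), ]
  structure(list(rpkm = rpkm, map = map), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d unigenes x %d accessions (RPKM)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}
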