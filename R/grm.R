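#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: with dosage matrix M (individuals x markers), observed
#' alt-allele frequencies p, and Z the column-centered matrix (M - 2p),
#' \deqn{G = \frac{ZZ'}{2\sum_j p_j(1-p_j)}.}
#' Missing dosages are mean-imputed per marker (so they contribute zero to
#' Z) and monomorphic markers are excluded before centering.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames = ids),
#'   markers in columns, values 0/1/2 with `NA` allowed.
#' @return An object of class `recomb_grm`: list with `ids`, `G`
#'   (symmetric p.s.d. matrix), `n_markers` used.
#' @export
#' @examples
#' M <- matrix(c(0, 1, 2, 1, 1, 0, 2, 0, 1, 0, 1, 2), nrow = 3)
#' rownames(M) <- c("a", "b", "c")
#' compute_grm(M)$G
compute_grm <- function(dosages) {
  stopifnot(is.matrix(dosages))
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dosages)))
  M <- apply(dosages, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  if (nrow(dosages) == 1) M <- matrix(M, nrow = 1)
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("all markers are monomorphic; GRM undefined", call. = FALSE)
  }
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(ids, ids)
  structure(list(ids = ids, G = G, n_markers = sum(poly)),
            class = "recomb_grm")
}

#' @export
print.recomb_grm <- function(x, ...) {
  cat(sprintf("<recomb_grm> %d individuals, %d markers, mean diag %.3f\n",
              length(x$ids), x$n_markers, mean(diag(x$G))))
  invisible(x)
}
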