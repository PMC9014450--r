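#' Quality-control filter for single-cell references
#'
#' Retains cells with a detected-gene count inside \code{[min_genes,
#' max_genes]} (bounds inclusive), a total UMI count strictly under
#' \code{max_umi}, and a mitochondrial read fraction strictly under
#' \code{max_mito_frac}. Mitochondrial genes are identified by prefix
#' (default \code{"Mt-"}, the rat convention) or an explicit gene list.
#' Column order is preserved and the filter is idempotent.
#'
#' @param x a \linkS4class{CountMatrix}.
#' @param mito_genes explicit mitochondrial gene identifiers, or NULL to use
#'   \code{mito_prefix}.
#' @param mito_prefix prefix marking mitochondrial genes.
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_umi exclusive upper bound on total UMIs per cell.
#' @param max_mito_frac exclusive upper bound on the mitochondrial fraction.
#' @return The filtered \linkS4class{CountMatrix}; a warning (not an error)
#'   is raised when no cell survives.
#' @examples
#' m <- matrix(rpois(300 * 4, 3), 300,
#'             dimnames = list(paste0("g", 1:300), paste0("c", 1:4)))
#' qcFilterCells(CountMatrix(m, "single_cell"))
#' @export
qcFilterCells <- function(x, mito_genes = NULL, mito_prefix = "Mt-",
                          min_genes = 200L, max_genes = 5000L,
                          max_umi = 30000, max_mito_frac = 0.40) {
  stopifnot(is(x, "CountMatrix"))
  if (min_genes >= max_genes)
    .stopf("min_genes (%d) must be below max_genes (%d)", min_genes, max_genes)
  m <- counts(x)
  if (is.null(mito_genes)) mito_genes <- rownames(x)[startsWith(rownames(x), mito_prefix)]
  detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito <- if (length(mito_genes))
    Matrix::colSums(m[rownames(x) %in% mito_genes, , drop = FALSE]) else
    rep(0, ncol(m))
  mito_frac <- ifelse(total > 0, mito / total, 0)
  keep <- detected >= min_genes & detected <= max_genes &
    total < max_umi & mito_frac < max_mito_frac
  if (!any(keep))
    .warnf("no cell passed QC (of %d)", ncol(m))
  x[, keep]
}
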