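#' Build a cell-type signature matrix from a labelled reference
#'
#' Scales every cell to 10,000 total counts (counts-per-10k) and averages
#' the scaled profiles within each cell-type label. The per-cell scaling
#' before averaging keeps the columns on a common scale and matches the
#' linear transcript-mixing model assumed by \code{\link{estimateFractions}}.
#'
#' @param x a \linkS4class{CountMatrix} of reference cells.
#' @param labels character vector of cell-type labels, either named by cell
#'   barcode or positional (one per column of \code{x}). Defaults to
#'   \code{colData(x)$cell_type}.
#' @param scale per-cell library-size target (default 10,000).
#' @return A \linkS4class{SignatureMatrix}; each column sums to at most
#'   \code{scale} (exactly \code{scale} when no gene was filtered out).
#' @examples
#' m <- matrix(c(1, 3, 1, 3), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' profiles(buildSignature(CountMatrix(m, "single_cell"), c("A", "A")))
#' @export
buildSignature <- function(x, labels = NULL, scale = 10000) {
  stopifnot(is(x, "CountMatrix"))
  if (is.null(labels)) labels <- colData(x)$cell_type
  if (is.null(labels)) stop("no labels given and colData lacks 'cell_type'")
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(x), names(labels))
    if (length(miss))
      .stopf("no cell-type label for barcode %s", miss[1L])
    labels <- labels[colnames(x)]
  }
  if (length(labels) != ncol(x))
    stop("labels must cover every cell")
  if (anyNA(labels)) .stopf("no cell-type label for barcode %s",
                            colnames(x)[which(is.na(labels))[1L]])
  m <- counts(x)
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    .stopf("all-zero cell(s) make a degenerate signature column: %s",
           colnames(x)[which(tot == 0)[1L]])
  cp10k <- sweep(as.matrix(m), 2L, tot, "/") * scale
  types <- sort(unique(labels))
  prof <- vapply(types,
                 function(t) rowMeans(cp10k[, labels == t, drop = FALSE]),
                 numeric(nrow(m)))
  dimnames(prof) <- list(rownames(x), types)
  SignatureMatrix(prof)
}

#' Rank cell-type marker genes by one-vs-rest differential expression
#'
#' For each cell type, compares counts-per-10k expression of its cells
#' against all remaining cells gene by gene with the Wilcoxon rank-sum test
#' (\code{\link{wilcoxonRankSum}}), adjusts p-values per type with
#' Benjamini-Hochberg, and ranks genes by descending log2 fold change of the
#' pseudocounted normalized means.
#'
#' @param x a \linkS4class{CountMatrix} of reference cells.
#' @param labels per-cell labels (see \code{\link{buildSignature}}).
#' @param scale per-cell library-size target.
#' @return data.frame with columns \code{cell_type}, \code{gene_id},
#'   \code{log2_fc}, \code{statistic}, \code{p_value}, \code{p_adjusted},
#'   sorted by fold change descending within type.
#' @export
rankMarkers <- function(x, labels = NULL, scale = 10000) {
  stopifnot(is(x, "CountMatrix"))
  if (is.null(labels)) labels <- colData(x)$cell_type
  if (is.null(labels)) stop("no labels given and colData lacks 'cell_type'")
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  if (length(unique(labels)) < 2L)
    stop("marker ranking needs at least two cell types")
  m <- as.matrix(counts(x))
  tot <- colSums(m)
  cp10k <- sweep(m, 2L, pmax(tot, 1), "/") * scale
  out <- lapply(sort(unique(labels)), function(t) {
    inT <- labels == t
    res <- t(vapply(seq_len(nrow(m)), function(g) {
      w <- wilcoxonRankSum(cp10k[g, inT], cp10k[g, !inT])
      c(w$statistic, w$p_value)
    }, numeric(2)))
    lfc <- log2((rowMeans(cp10k[, inT, drop = FALSE]) + 1) /
                (rowMeans(cp10k[, !inT, drop = FALSE]) + 1))
    d <- data.frame(cell_type = t, gene_id = rownames(m), log2_fc = lfc,
                    statistic = res[, 1L], p_value = res[, 2L],
                    p_adjusted = bhAdjust(res[, 2L]),
                    stringsAsFactors = FALSE)
    d[order(-d$log2_fc, d$gene_id), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
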