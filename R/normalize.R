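#' Cell-fraction-normalized expression
#'
#' Attributes spot expression to a target cell type by dividing each
#' retained spot's counts by that spot's estimated fraction of the type:
#' \deqn{NC_{ij} = C_{ij} / F_j}
#' where \eqn{C} is the genes x spots count matrix and \eqn{F_j} the
#' fraction of the target type in spot \eqn{j}. Only spots with
#' \eqn{F_j \ge} \code{min_fraction} are retained, which also removes the
#' noise floor of spots that barely contain the type. The division is
#' homogeneous: scaling a spot's counts scales its normalized column by the
#' same constant, so a subsequent total-count normalization
#' (\code{\link{lognormalizeTotal}}) cancels library-size differences.
#'
#' @param x a \linkS4class{CountMatrix} of spots (raw counts).
#' @param fr a \linkS4class{FractionMatrix} over the same spots.
#' @param cell_type target cell type (a column of \code{fr}).
#' @param min_fraction inclusive retention threshold on \eqn{F_j}.
#' @return A \linkS4class{NormalizedMatrix} restricted to retained spots;
#'   metadata records the target type and threshold.
#' @export
fractionNormalize <- function(x, fr, cell_type, min_fraction = 0.05) {
  stopifnot(is(x, "CountMatrix"), is(fr, "FractionMatrix"))
  if (!setequal(colnames(x), spotIds(fr)))
    stop("counts and fractions cover different spot sets")
  keep <- selectSpotsByFraction(fr, cell_type, min_fraction)
  f <- fractions(fr)[keep, cell_type]
  nc <- sweep(as.matrix(counts(x))[, keep, drop = FALSE], 2L, f, "/")
  NormalizedMatrix(nc, meta = list(
    cell_type = cell_type, min_fraction = min_fraction,
    counts = "raw", scale = NULL, log = FALSE))
}

#' Total-count scaling and log1p of normalized expression
#'
#' Rescales every spot column to a common library size
#' (\code{value * scale / colsum}) and, by default, applies the natural-log
#' \code{log1p} transform — the standard \code{NormalizeData}-style step
#' applied after fraction normalization. With \code{log = FALSE} the values
#' stay on the linear scaled axis (used by the skewness screen, which needs
#' the untransformed right tail).
#'
#' @param nc a \linkS4class{NormalizedMatrix}.
#' @param scale per-spot target total (default 10,000).
#' @param log apply \code{log1p} (default TRUE).
#' @return A \linkS4class{NormalizedMatrix} with updated metadata.
#' @examples
#' nc <- NormalizedMatrix(matrix(c(8, 12), 2,
#'   dimnames = list(c("g1", "g2"), "s1")))
#' normValues(lognormalizeTotal(nc))  # log(1 + 4000), log(1 + 6000)
#' @export
lognormalizeTotal <- function(nc, scale = 10000, log = TRUE) {
  stopifnot(is(nc, "NormalizedMatrix"))
  v <- normValues(nc)
  tot <- colSums(v)
  if (any(tot <= 0))
    .stopf("zero-total spot cannot be total-count normalized: %s",
           colnames(v)[which(tot <= 0)[1L]])
  v <- sweep(v, 2L, tot, "/") * scale
  if (log) v <- log1p(v)
  meta <- normMetadata(nc)
  meta$scale <- scale
  meta$log <- log
  NormalizedMatrix(v, meta = meta)
}
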