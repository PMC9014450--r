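#' Two-sided Wilcoxon rank-sum test
#'
#' Thin, contract-pinned front end to \code{stats::wilcox.test}: the exact
#' permutation distribution is used when the smaller group has at most 8
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return \code{list(statistic, p_value, exact)} where \code{statistic} is
#'   the Mann-Whitney W of \code{x}.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  res <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = exact)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (\code{stats::p.adjust} with validated input).
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between two spot groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two disjoint spot
#' groups of a normalized matrix, BH adjustment across genes, and log2
#' fold change of the pseudocounted group means (\code{log2((mA + 1) /
#' (mB + 1))}). Results are ranked by fold change descending, the ordering
#' used to report top response genes.
#'
#' @param nc a \linkS4class{NormalizedMatrix}.
#' @param group_a,group_b disjoint, non-empty sets of spot ids in \code{nc}.
#' @return data.frame: \code{gene_id}, \code{mean_a}, \code{mean_b},
#'   \code{log2_fc}, \code{statistic}, \code{p_value}, \code{p_adjusted}.
#' @export
deBetweenGroups <- function(nc, group_a, group_b) {
  stopifnot(is(nc, "NormalizedMatrix"))
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  v <- normValues(nc)
  miss <- setdiff(c(group_a, group_b), colnames(v))
  if (length(miss)) .stopf("spot '%s' not in the normalized matrix", miss[1L])
  va <- v[, group_a, drop = FALSE]
  vb <- v[, group_b, drop = FALSE]
  res <- t(vapply(seq_len(nrow(v)), function(g) {
    w <- wilcoxonRankSum(va[g, ], vb[g, ])
    c(w$statistic, w$p_value)
  }, numeric(2)))
  d <- data.frame(
    gene_id = rownames(v), mean_a = rowMeans(va), mean_b = rowMeans(vb),
    log2_fc = log2((rowMeans(va) + 1) / (rowMeans(vb) + 1)),
    statistic = res[, 1L], p_value = res[, 2L],
    p_adjusted = bhAdjust(res[, 2L]),
    stringsAsFactors = FALSE, row.names = NULL)
  d[order(-d$log2_fc, d$gene_id), ]
}

#' Cross-dataset correlation through a homolog map
#'
#' Maps gene identifiers of one mean-expression profile onto another
#' dataset's identifiers through a two-column homolog table, drops unmapped
#' genes and every ambiguous (one-to-many in either direction) pair, and
#' returns the Pearson correlation of the log1p profiles over the shared
#' mapped genes.
#'
#' @param expr_a named numeric vector (source dataset mean expression).
#' @param expr_b named numeric vector (target dataset mean expression).
#' @param map data.frame whose first two columns are source and target gene
#'   identifiers.
#' @return \code{list(r, n_genes)}.
#' @export
homologCorrelation <- function(expr_a, expr_b, map) {
  src <- as.character(map[[1L]]); tgt <- as.character(map[[2L]])
  amb <- src %in% src[duplicated(src)] | tgt %in% tgt[duplicated(tgt)]
  src <- src[!amb]; tgt <- tgt[!amb]
  keep <- src %in% names(expr_a) & tgt %in% names(expr_b)
  src <- src[keep]; tgt <- tgt[keep]
  if (length(src) < 10L)
    .stopf("only %d mapped genes shared between datasets (>= 10 required)",
           length(src))
  list(r = stats::cor(log1p(expr_a[src]), log1p(expr_b[tgt]),
                      method = "pearson"),
       n_genes = length(src))
}

#' Read a two-column homolog mapping table
#'
#' @param path TSV with a header and two identifier columns.
#' @return data.frame with columns \code{source}, \code{target}.
#' @export
readHomologMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character")
  if (ncol(d) < 2L) stop("homolog map needs two columns")
  data.frame(source = d[[1L]], target = d[[2L]], stringsAsFactors = FALSE)
}
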