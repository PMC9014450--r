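#' Hexagonal neighbours of a spot
#'
#' On the Visium array (0-based coordinates, column parity equal to row
#' parity) a spot's six hex neighbours sit at offsets (0, +/-2) and
#' (+/-1, +/-1). Only spots present in the lattice and belonging to the
#' same sample are returned, so a spot has at most six neighbours and
#' border spots have fewer.
#'
#' @param lattice a \linkS4class{SpotLattice}.
#' @param spot_id a spot identifier present in the lattice.
#' @return Character vector of neighbouring spot identifiers.
#' @export
hexNeighbors <- function(lattice, spot_id) {
  stopifnot(is(lattice, "SpotLattice"))
  d <- spotData(lattice)
  i <- match(spot_id, d$spot_id)
  if (is.na(i)) .stopf("unknown spot '%s'", spot_id)
  key <- paste(d$sample_id, d$array_row, d$array_col)
  nb <- paste(d$sample_id[i],
              d$array_row[i] + .hexOffsets[, "row"],
              d$array_col[i] + .hexOffsets[, "col"])
  d$spot_id[match(intersect(nb, key), key)]
}

#' Classify spots by dominant score
#'
#' Two-group dominant-score rule for competing cell-type scores (e.g.
#' TAL-1 vs TAL-2 fractions): a spot goes to group A only when its A score
#' is strictly higher than its B score, otherwise to group B; spots with
#' both scores zero are unclassified (ineligible).
#'
#' @param score_a,score_b non-negative numeric vectors of equal length.
#' @param labels group names, \code{c(a, b)}.
#' @return Character vector in \code{labels} or \code{"Unclassified"}.
#' @export
classifyDominant <- function(score_a, score_b,
                             labels = c("GroupA", "GroupB")) {
  stopifnot(length(score_a) == length(score_b), length(labels) == 2L)
  if (any(score_a < 0, na.rm = TRUE) || any(score_b < 0, na.rm = TRUE))
    stop("scores must be non-negative")
  out <- ifelse(score_a > score_b, labels[1L], labels[2L])
  out[score_a == 0 & score_b == 0] <- "Unclassified"
  out[is.na(score_a) | is.na(score_b)] <- "Unclassified"
  out
}

#' Glomerulus-adjacency contingency table of classified spots
#'
#' Cross-tabulates classified spots (glomerulus spots themselves excluded)
#' by whether they share a hex edge with at least one glomerulus spot of
#' the same sample. Rows are the two groups, columns are
#' adjacent / not adjacent.
#'
#' @param labels named character vector of group labels (names are spot
#'   ids); entries labelled \code{"Unclassified"} are dropped.
#' @param glomerulus_spots spot identifiers of glomerulus spots.
#' @param lattice a \linkS4class{SpotLattice} covering all spots involved.
#' @return A 2x2 integer matrix (groups x adjacent/not_adjacent).
#' @export
adjacencyContingency <- function(labels, glomerulus_spots, lattice) {
  stopifnot(is(lattice, "SpotLattice"))
  labels <- labels[labels != "Unclassified"]
  labels <- labels[!(names(labels) %in% glomerulus_spots)]
  if (!length(labels)) stop("no eligible classified spots")
  groups <- sort(unique(labels))
  if (length(groups) == 1L)
    groups <- c(groups, setdiff(c("GroupA", "GroupB"), groups)[1L])
  d <- spotData(lattice)
  key <- paste(d$sample_id, d$array_row, d$array_col)
  glom_keys <- key[d$spot_id %in% glomerulus_spots]
  idx <- match(names(labels), d$spot_id)
  if (anyNA(idx)) .stopf("spot '%s' not in lattice", names(labels)[which(is.na(idx))[1L]])
  adj <- vapply(idx, function(i) {
    nb <- paste(d$sample_id[i],
                d$array_row[i] + .hexOffsets[, "row"],
                d$array_col[i] + .hexOffsets[, "col"])
    any(nb %in% glom_keys)
  }, logical(1))
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(groups, c("adjacent", "not_adjacent")))
  for (g in groups) {
    tab[g, "adjacent"] <- sum(labels == g & adj)
    tab[g, "not_adjacent"] <- sum(labels == g & !adj)
  }
  tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the table margins, the two-sided p-value is the total
#' hypergeometric probability of all tables whose probability does not
#' exceed that of the observed table (with the conventional 1e-7 relative
#' slack for ties in floating point). The reported odds ratio is the
#' sample odds ratio \eqn{(ad)/(bc)}, not the conditional MLE.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return \code{list(p_value, odds_ratio, table)}. A zero row or column
#'   margin yields p = 1 with a warning.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2))$p_value  # 2 / choose(20, 10)
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; dd <- tab[2L, 2L]
  or <- (a * dd) / (b * cc)
  m <- a + cc          # first-column margin
  n <- b + dd          # second-column margin
  k <- a + b           # first-row margin
  if (m == 0 || n == 0 || k == 0 || cc + dd == 0) {
    .warnf("zero margin: p = 1 by convention")
    return(list(p_value = 1, odds_ratio = or, table = tab))
  }
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(p_value = p, odds_ratio = or, table = tab)
}
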