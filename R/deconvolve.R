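#' Estimate per-spot cell-type fractions by non-negative least squares
#'
#' Implements the linear transcript-mixing model behind spot deconvolution:
#' each spot's counts-per-10k profile over the genes shared with the
#' signature is decomposed as a non-negative combination of the signature
#' columns (Lawson-Hanson NNLS via \code{pracma::lsqnonneg}), and the
#' coefficients are renormalized to the probability simplex. Working in
#' linear counts-per-10k space makes the estimate invariant to per-spot
#' library size. Spots whose shared-gene counts are all zero are flagged
#' degenerate (NA row) rather than silently normalized.
#'
#' @param x a \linkS4class{CountMatrix} of spots.
#' @param signature a \linkS4class{SignatureMatrix}.
#' @param scale library-size target used for the per-spot scaling; must
#'   match the signature scale (default 10,000).
#' @return A \linkS4class{FractionMatrix} with per-spot NNLS residual norms.
#' @examples
#' genes <- paste0("g", 1:60)
#' sig <- SignatureMatrix(matrix(c(rep(c(250, 0), each = 30),
#'                                 rep(c(0, 250), each = 30)), 60,
#'   dimnames = list(genes, c("A", "B"))))
#' spot <- matrix(as.numeric(rep(c(3, 7), each = 30)), 60,
#'                dimnames = list(genes, "s1"))
#' fractions(estimateFractions(CountMatrix(spot, "spatial"), sig))
#' @export
estimateFractions <- function(x, signature, scale = 10000) {
  stopifnot(is(x, "CountMatrix"), is(signature, "SignatureMatrix"))
  S <- profiles(signature)
  shared <- intersect(rownames(x), rownames(S))
  if (length(shared) < 50L)
    .stopf("only %d genes shared between spots and signature (>= 50 required)",
           length(shared))
  if (length(shared) < 200L)
    .warnf("only %d genes shared between spots and signature; estimates may be unstable",
           length(shared))
  S <- S[shared, , drop = FALSE]
  m <- as.matrix(counts(x))[shared, , drop = FALSE]
  tot <- colSums(m)
  n_spot <- ncol(m); n_type <- ncol(S)
  fr <- matrix(NA_real_, n_spot, n_type,
               dimnames = list(colnames(m), colnames(S)))
  degen <- tot == 0
  resid <- rep(NA_real_, n_spot)
  names(degen) <- names(resid) <- colnames(m)
  for (j in which(!degen)) {
    y <- m[, j] / tot[j] * scale
    fit <- pracma::lsqnonneg(S, y)
    s <- sum(fit$x)
    if (s <= 0) { degen[j] <- TRUE; next }
    fr[j, ] <- fit$x / s
    resid[j] <- sqrt(max(fit$resid.norm, 0))
  }
  FractionMatrix(fr, degenerate = degen, residual = resid)
}

#' Select spots carrying a relevant fraction of a target cell type
#'
#' Returns the spots whose estimated fraction of \code{cell_type} is at
#' least \code{min_fraction} (inclusive), in the deterministic order of the
#' fraction matrix; degenerate spots never qualify.
#'
#' @param fr a \linkS4class{FractionMatrix}.
#' @param cell_type target cell-type name.
#' @param min_fraction inclusive threshold (default 0.05).
#' @return Character vector of selected spot identifiers.
#' @export
selectSpotsByFraction <- function(fr, cell_type, min_fraction = 0.05) {
  stopifnot(is(fr, "FractionMatrix"))
  f <- fractions(fr)
  if (!(cell_type %in% colnames(f)))
    .stopf("unknown cell type '%s'; available: %s", cell_type,
           paste(colnames(f), collapse = ", "))
  ok <- !degenerateSpots(fr) & f[, cell_type] >= min_fraction
  rownames(f)[which(ok)]
}
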