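#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t readMM writeMM
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.ZONES <- c("Cortex", "OMOS", "OMIS", "IM")
.CONDITIONS <- c("Ctrl", "Losa")
.MODALITIES <- c("single_cell", "spatial")

## ---------------------------------------------------------------------------
## CountMatrix: genes x (cells|spots) integer counts on top of a
## SummarizedExperiment, tagged with the assay modality.
## ---------------------------------------------------------------------------

#' CountMatrix: genes-by-samples integer counts
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"counts"} (sparse or dense, non-negative integral values) with
#' unique gene and sample (cell barcode or spot barcode) identifiers, plus a
#' modality tag distinguishing single-cell from spatial data.
#'
#' @slot modality character, \code{"single_cell"} or \code{"spatial"}.
#' @export
setClass("CountMatrix",
  contains = "SummarizedExperiment",
  representation(modality = "character")
)

.validCountMatrix <- function(object) {
  msg <- character()
  if (!("counts" %in% names(assays(object, withDimnames = FALSE))))
    msg <- c(msg, "assay 'counts' is required")
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    msg <- c(msg, sprintf("modality must be one of: %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(msg)) return(msg)
  m <- assay(object, "counts", withDimnames = FALSE)
  if (is.null(rownames(object)) && nrow(object) > 0L)
    msg <- c(msg, "gene identifiers (rownames) are required")
  if (is.null(colnames(object)) && ncol(object) > 0L)
    msg <- c(msg, "sample identifiers (colnames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  vals <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(vals)) {
    if (any(vals < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(vals != round(vals))) msg <- c(msg, "counts must be integral")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CountMatrix", .validCountMatrix)

#' Construct a CountMatrix
#'
#' @param counts genes x samples matrix (base or \pkg{Matrix} sparse) of
#'   non-negative integral counts with rownames (genes) and colnames
#'   (barcodes).
#' @param modality \code{"single_cell"} or \code{"spatial"}.
#' @param colData optional \code{DataFrame} of per-sample annotation
#'   (e.g. a \code{cell_type} column for a labelled reference).
#' @return A \linkS4class{CountMatrix}.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' CountMatrix(m, "single_cell")
#' @export
CountMatrix <- function(counts, modality = c("single_cell", "spatial"),
                        colData = NULL) {
  modality <- match.arg(modality)
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = colData)
  new("CountMatrix", se, modality = modality)
}

## ---------------------------------------------------------------------------
## SpotLattice: per-spot array coordinates and annotation.
## ---------------------------------------------------------------------------

#' SpotLattice: annotated hexagonal spot array
#'
#' Per-spot metadata for one or more Visium-style capture areas: 0-based
#' array coordinates on the hexagonally packed grid (column parity equals row
#' parity), histological zone, optional glomerulus membership, sample and
#' condition. Spots from different samples never interact spatially.
#'
#' @slot spots data.frame with columns \code{spot_id}, \code{array_row},
#'   \code{array_col}, \code{zone}, \code{glomerulus_id} (NA when the spot
#'   does not overlap a glomerulus), \code{sample_id}, \code{condition}.
#' @export
setClass("SpotLattice", representation(spots = "data.frame"))

.LATTICE_COLS <- c("spot_id", "array_row", "array_col", "zone",
                   "glomerulus_id", "sample_id", "condition")

.validSpotLattice <- function(object) {
  d <- object@spots
  msg <- character()
  miss <- setdiff(.LATTICE_COLS, names(d))
  if (length(miss))
    return(sprintf("missing lattice columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$spot_id))
    msg <- c(msg, "duplicate spot_id")
  key <- paste(d$sample_id, d$array_row, d$array_col)
  if (anyDuplicated(key))
    msg <- c(msg, sprintf("duplicate (sample, row, col) coordinates: %s",
                          key[anyDuplicated(key)]))
  if (any(d$array_row < 0 | d$array_col < 0))
    msg <- c(msg, "array coordinates must be non-negative")
  bad <- d$array_row %% 2L != d$array_col %% 2L
  if (any(bad))
    msg <- c(msg, sprintf(
      "row/column parity violated (Visium hex convention) for spot %s",
      d$spot_id[which(bad)[1L]]))
  if (!all(d$zone %in% .ZONES))
    msg <- c(msg, sprintf("unknown zone label(s) %s; allowed: %s",
                          paste(unique(setdiff(d$zone, .ZONES)), collapse = ", "),
                          paste(.ZONES, collapse = ", ")))
  if (!all(d$condition %in% .CONDITIONS))
    msg <- c(msg, sprintf("unknown condition label(s); allowed: %s",
                          paste(.CONDITIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("SpotLattice", .validSpotLattice)

#' Construct a SpotLattice from a spot annotation table
#'
#' @param spots data.frame with the columns documented in
#'   \linkS4class{SpotLattice}.
#' @return A \linkS4class{SpotLattice}.
#' @export
SpotLattice <- function(spots) {
  spots$array_row <- as.integer(spots$array_row)
  spots$array_col <- as.integer(spots$array_col)
  for (col in c("spot_id", "zone", "glomerulus_id", "sample_id", "condition"))
    spots[[col]] <- as.character(spots[[col]])
  rownames(spots) <- NULL
  new("SpotLattice", spots = spots)
}

## ---------------------------------------------------------------------------
## SignatureMatrix: reference cell-type expression profiles.
## ---------------------------------------------------------------------------

#' SignatureMatrix: genes-by-cell-types reference profiles
#'
#' Mean expression of each cell type on the counts-per-10k scale, built by
#' scaling each reference cell to 10,000 total counts and averaging within
#' its type. The columns are the basis vectors of the linear mixing model
#' used by \code{\link{estimateFractions}}.
#'
#' @slot profiles genes x types non-negative matrix; rownames are gene ids,
#'   colnames are cell-type names.
#' @export
setClass("SignatureMatrix", representation(profiles = "matrix"))

setValidity("SignatureMatrix", function(object) {
  p <- object@profiles
  msg <- character()
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("profiles must carry gene and cell-type names")
  if (anyDuplicated(rownames(p)) || anyDuplicated(colnames(p)))
    msg <- c(msg, "duplicate gene or cell-type names")
  if (any(p < 0)) msg <- c(msg, "profiles must be non-negative")
  zero <- colSums(p) == 0
  if (any(zero))
    msg <- c(msg, sprintf("all-zero signature column(s): %s",
                          paste(colnames(p)[zero], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname SignatureMatrix-class
#' @param profiles genes x types matrix of non-negative mean profiles.
#' @export
SignatureMatrix <- function(profiles) new("SignatureMatrix", profiles = profiles)

## ---------------------------------------------------------------------------
## FractionMatrix: per-spot cell-type composition on the simplex.
## ---------------------------------------------------------------------------

#' FractionMatrix: spots-by-cell-types composition estimates
#'
#' Each non-degenerate row lies on the probability simplex (entries in
#' [0, 1], summing to 1 within 1e-9). Spots whose counts could not be
#' decomposed (e.g. all-zero spots) are flagged degenerate and their rows are
#' NA rather than silently renormalized. For deconvolution output the
#' per-spot residual norm of the NNLS fit is retained.
#'
#' @slot fractions spots x types matrix; NA rows for degenerate spots.
#' @slot degenerate named logical vector, one entry per spot.
#' @slot residual named numeric vector of per-spot residual norms (NA when
#'   not applicable).
#' @export
setClass("FractionMatrix",
  representation(fractions = "matrix", degenerate = "logical",
                 residual = "numeric"))

setValidity("FractionMatrix", function(object) {
  f <- object@fractions
  msg <- character()
  if (is.null(rownames(f)) || is.null(colnames(f)))
    return("fractions must carry spot and cell-type names")
  if (length(object@degenerate) != nrow(f) ||
      length(object@residual) != nrow(f))
    return("degenerate/residual length must equal the number of spots")
  ok <- !object@degenerate
  if (any(ok)) {
    fv <- f[ok, , drop = FALSE]
    if (anyNA(fv)) msg <- c(msg, "NA fractions in non-degenerate rows")
    else {
      if (any(fv < 0 | fv > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
      if (any(abs(rowSums(fv) - 1) > 1e-9))
        msg <- c(msg, "non-degenerate fraction rows must sum to 1 (tol 1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FractionMatrix-class
#' @param fractions spots x types matrix with dimnames.
#' @param degenerate logical per-spot flag (default all FALSE).
#' @param residual numeric per-spot residual norm (default NA).
#' @export
FractionMatrix <- function(fractions,
                           degenerate = rep(FALSE, nrow(fractions)),
                           residual = rep(NA_real_, nrow(fractions))) {
  names(degenerate) <- rownames(fractions)
  names(residual) <- rownames(fractions)
  new("FractionMatrix", fractions = fractions,
      degenerate = degenerate, residual = residual)
}

## ---------------------------------------------------------------------------
## NormalizedMatrix: fraction-normalized (optionally log) expression.
## ---------------------------------------------------------------------------

#' NormalizedMatrix: cell-fraction-normalized expression values
#'
#' Genes x spots matrix of non-negative values produced by
#' \code{\link{fractionNormalize}} (counts divided by the target cell-type
#' fraction of each retained spot) and optionally rescaled by
#' \code{\link{lognormalizeTotal}}. The normalization provenance (target
#' cell type, fraction threshold, scale, log flag) travels in
#' \code{normMetadata}.
#'
#' @slot values genes x spots numeric matrix, finite entries.
#' @slot meta list of normalization metadata.
#' @export
setClass("NormalizedMatrix", representation(values = "matrix", meta = "list"))

setValidity("NormalizedMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry gene and spot names")
  if (length(v) && any(!is.finite(v)))
    return("normalized values must be finite")
  if (length(v) && any(v < 0))
    return("normalized values must be non-negative")
  TRUE
})

#' @rdname NormalizedMatrix-class
#' @param values genes x spots numeric matrix with dimnames.
#' @param meta list of normalization metadata.
#' @export
NormalizedMatrix <- function(values, meta = list())
  new("NormalizedMatrix", values = values, meta = meta)
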