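#' @importFrom BiocGenerics counts
NULL

#' Accessors for spothet classes
#'
#' Small accessor family: \code{counts} returns the integer count assay,
#' \code{modality} the single-cell/spatial tag, \code{spotData} the per-spot
#' annotation table, \code{spotIds} the spot identifiers, \code{profiles} the
#' signature profile matrix, \code{fractions} the spots x types composition
#' matrix, \code{degenerateSpots} the degenerate-spot flags,
#' \code{residualNorms} the per-spot NNLS residuals, \code{normValues} the
#' normalized expression matrix and \code{normMetadata} its provenance.
#'
#' @param object a spothet S4 object.
#' @return The slot content documented above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("spotData", function(object) standardGeneric("spotData"))
#' @rdname accessors
#' @export
setGeneric("spotIds", function(object) standardGeneric("spotIds"))
#' @rdname accessors
#' @export
setGeneric("profiles", function(object) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("degenerateSpots", function(object) standardGeneric("degenerateSpots"))
#' @rdname accessors
#' @export
setGeneric("residualNorms", function(object) standardGeneric("residualNorms"))
#' @rdname accessors
#' @export
setGeneric("normValues", function(object) standardGeneric("normValues"))
#' @rdname accessors
#' @export
setGeneric("normMetadata", function(object) standardGeneric("normMetadata"))

#' @rdname accessors
#' @export
setMethod("counts", "CountMatrix", function(object)
  assay(object, "counts"))
#' @rdname accessors
#' @export
setMethod("modality", "CountMatrix", function(object) object@modality)
#' @rdname accessors
#' @export
setMethod("spotData", "SpotLattice", function(object) object@spots)
#' @rdname accessors
#' @export
setMethod("spotIds", "SpotLattice", function(object) object@spots$spot_id)
#' @rdname accessors
#' @export
setMethod("profiles", "SignatureMatrix", function(object) object@profiles)
#' @rdname accessors
#' @export
setMethod("fractions", "FractionMatrix", function(object) object@fractions)
#' @rdname accessors
#' @export
setMethod("spotIds", "FractionMatrix", function(object) rownames(object@fractions))
#' @rdname accessors
#' @export
setMethod("degenerateSpots", "FractionMatrix", function(object) object@degenerate)
#' @rdname accessors
#' @export
setMethod("residualNorms", "FractionMatrix", function(object) object@residual)
#' @rdname accessors
#' @export
setMethod("normValues", "NormalizedMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("spotIds", "NormalizedMatrix", function(object) colnames(object@values))
#' @rdname accessors
#' @export
setMethod("normMetadata", "NormalizedMatrix", function(object) object@meta)

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix (%s): %d genes x %d %s\n",
              object@modality, nrow(object), ncol(object),
              if (object@modality == "spatial") "spots" else "cells"))
  callNextMethod()
})

setMethod("show", "SpotLattice", function(object) {
  d <- object@spots
  cat(sprintf("SpotLattice: %d spots, %d sample(s)\n",
              nrow(d), length(unique(d$sample_id))))
  cat(" zones:", paste(sprintf("%s=%d", names(table(d$zone)), table(d$zone)),
                       collapse = " "), "\n")
  cat(sprintf(" glomerulus spots: %d\n", sum(!is.na(d$glomerulus_id))))
})

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf("SignatureMatrix: %d genes x %d cell types (counts-per-10k)\n",
              nrow(object@profiles), ncol(object@profiles)))
  cat(" types:", paste(colnames(object@profiles), collapse = ", "), "\n")
})

setMethod("show", "FractionMatrix", function(object) {
  cat(sprintf("FractionMatrix: %d spots x %d cell types (%d degenerate)\n",
              nrow(object@fractions), ncol(object@fractions),
              sum(object@degenerate)))
})

setMethod("show", "NormalizedMatrix", function(object) {
  m <- object@meta
  cat(sprintf("NormalizedMatrix: %d genes x %d spots\n",
              nrow(object@values), ncol(object@values)))
  if (length(m))
    cat(sprintf(" target=%s min_fraction=%s scale=%s log=%s\n",
                m$cell_type %||% "?", m$min_fraction %||% "?",
                m$scale %||% "-", isTRUE(m$log)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
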