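#' Read a 10x-style count matrix triplet
#'
#' Reads a MatrixMarket coordinate file plus its companion gene and barcode
#' TSVs (first column used as identifier) into a \linkS4class{CountMatrix}.
#' Malformed input is rejected rather than coerced: the identifier files must
#' match the MatrixMarket header dimensions and the entries must be
#' non-negative integers.
#'
#' @param matrix_path path to the .mtx coordinate file.
#' @param genes_path path to the gene TSV (one row per matrix row).
#' @param barcodes_path path to the barcode TSV (one row per matrix column).
#' @param modality \code{"single_cell"} or \code{"spatial"}.
#' @return A \linkS4class{CountMatrix}.
#' @seealso \code{\link{writeCounts}}
#' @export
readCounts <- function(matrix_path, genes_path, barcodes_path,
                       modality = c("single_cell", "spatial")) {
  modality <- match.arg(modality)
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  firstField <- function(p)
    vapply(strsplit(readLines(p), "\t", fixed = TRUE),
           function(x) x[1L] %||% "", character(1))
  genes <- firstField(genes_path)
  barcodes <- firstField(barcodes_path)
  if (length(genes) != nrow(m))
    stop(sprintf(
      "gene file lists %d genes but matrix header declares %d rows",
      length(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf(
      "barcode file lists %d barcodes but matrix header declares %d columns",
      length(barcodes), ncol(m)))
  m <- as(m * 1, "CsparseMatrix")  # pattern matrices to numeric
  dimnames(m) <- list(genes, barcodes)
  CountMatrix(m, modality)
}

#' Write a CountMatrix as a MatrixMarket triplet
#'
#' Emits \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv} under
#' \code{out_dir}; the exact inverse of \code{\link{readCounts}}.
#'
#' @param x a \linkS4class{CountMatrix}.
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the three file paths.
#' @export
writeCounts <- function(x, out_dir) {
  stopifnot(is(x, "CountMatrix"))
  validObject(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  m <- as(as(counts(x), "dMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paths[1L])
  writeLines(as.character(rownames(x)), paths[2L])
  writeLines(as.character(colnames(x)), paths[3L])
  invisible(paths)
}

#' Read a spot-position table
#'
#' Reads a CSV in the Visium tissue-positions dialect extended with
#' histological annotation: columns \code{spot_id}, \code{array_row},
#' \code{array_col}, \code{zone}, \code{glomerulus_id}, \code{sample_id},
#' \code{condition}. Validation (coordinate parity, uniqueness, known zone
#' and condition labels) happens at construction and names the offending
#' spot.
#'
#' @param csv_path path to the CSV file (named header required).
#' @return A \linkS4class{SpotLattice}.
#' @seealso \code{\link{writeLattice}}
#' @export
readLattice <- function(csv_path) {
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  d <- utils::read.csv(csv_path, colClasses = "character")
  miss <- setdiff(.LATTICE_COLS, names(d))
  if (length(miss))
    stop("missing lattice columns: ", paste(miss, collapse = ", "))
  d$glomerulus_id[d$glomerulus_id == ""] <- NA_character_
  SpotLattice(d)
}

#' Write a SpotLattice as CSV
#'
#' @param lattice a \linkS4class{SpotLattice}.
#' @param csv_path output path.
#' @return Invisibly, \code{csv_path}.
#' @export
writeLattice <- function(lattice, csv_path) {
  stopifnot(is(lattice, "SpotLattice"))
  validObject(lattice)
  d <- spotData(lattice)
  d$glomerulus_id[is.na(d$glomerulus_id)] <- ""
  utils::write.csv(d, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}
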