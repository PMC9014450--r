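.NAMED_GENES <- c("Ren", "Ptgs2", "Rplp0", "Slc12a1", "Pappa2")
.MITO_GENES <- c("Mt-nd1", "Mt-co1", "Mt-cyb")

#' SimConfig: parameters of the synthetic-tissue simulator
#'
#' Bundles every knob of the synthetic study: gene and cell-type inventory,
#' lattice geometry and zonation, glomerulus and macula densa placement,
#' sequencing depth and count noise, and the planted treatment effects. The
#' defaults describe the scaled-down two-condition renal study the package
#' is built around (see the methods vignette): three samples per condition,
#' a 40x40 hex array zoned Cortex/OMOS/OMIS/IM, 40 single-spot glomeruli per
#' sample each with one adjacent macula densa spot, 5,000 UMIs per spot,
#' Cox-2 (\emph{Ptgs2}) induction in treated macula densa, and renin
#' (\emph{Ren}) induction in treated juxtaglomerular components that is
#' concentrated in a planted quarter of high-responder glomeruli.
#'
#' @slot n_genes number of genes (includes the named genes Ren, Ptgs2,
#'   Rplp0, Slc12a1, Pappa2, three mitochondrial genes, and
#'   \code{n_markers_per_type} exclusive marker genes per cell type).
#' @slot n_markers_per_type exclusive marker genes per cell type; the
#'   default (25) emulates a curated marker-rich deconvolution panel.
#' @slot cell_types cell-type names.
#' @slot zone_affinity named list, zone -> character vector of cell types
#'   mixed in that zone's ordinary spots.
#' @slot n_cells_per_type reference cells simulated per type.
#' @slot lattice_rows,lattice_cols array extent (0-based Visium coordinates;
#'   spots exist where column parity equals row parity).
#' @slot zone_layout the four zones in row-band order, top to bottom.
#' @slot n_glomeruli glomeruli per sample (single cortical spots).
#' @slot glomerulus_profile named fractions of the glomerular spot
#'   composition (podocyte/mesangial/juxtaglomerular); must sum to 1.
#' @slot macula_densa_type cell type planted adjacent to each glomerulus.
#' @slot md_fraction fraction of the macula densa type in its spot.
#' @slot md_adjacent logical; FALSE places the macula-densa-enriched spots
#'   uniformly at random in the cortex instead of adjacent to glomeruli
#'   (the spatial null layout).
#' @slot n_samples samples per condition (conditions are Ctrl and Losa).
#' @slot depth_mean_umi mean total UMIs per spot or cell.
#' @slot nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @slot dirichlet_conc concentration of the per-zone Dirichlet mixtures.
#' @slot effect_ptgs2_fold treated-sample fold induction of the macula densa
#'   response gene (Ptgs2) within the macula densa component.
#' @slot effect_ren_base_fold treated-sample fold induction of the JG
#'   response gene (Ren) within every JG component.
#' @slot effect_ren_fold additional fold induction of Ren in the JG
#'   component of planted high-responder glomeruli (applied on top of
#'   \code{effect_ren_base_fold}).
#' @slot high_responder_frac fraction of each treated sample's glomeruli
#'   planted as high-responders.
#' @slot response_cell_type the JG-like cell type carrying the Ren response.
#' @slot seed RNG seed; all outputs are deterministic given the config.
#' @export
setClass("SimConfig", representation(
  n_genes = "integer", n_markers_per_type = "integer",
  cell_types = "character", zone_affinity = "list",
  n_cells_per_type = "integer", lattice_rows = "integer",
  lattice_cols = "integer", zone_layout = "character",
  n_glomeruli = "integer", glomerulus_profile = "numeric",
  macula_densa_type = "character", md_fraction = "numeric",
  md_adjacent = "logical", n_samples = "integer",
  depth_mean_umi = "numeric", nb_dispersion = "numeric",
  dirichlet_conc = "numeric", effect_ptgs2_fold = "numeric",
  effect_ren_base_fold = "numeric", effect_ren_fold = "numeric",
  high_responder_frac = "numeric", response_cell_type = "character",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- function(name) {
    v <- slot(object, name)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msg <<- c(msg, sprintf("%s must be a positive count", name))
  }
  for (f in c("n_genes", "n_cells_per_type", "lattice_rows", "lattice_cols",
              "n_glomeruli", "n_samples", "depth_mean_umi"))
    pos(f)
  if (object@nb_dispersion < 0) msg <- c(msg, "nb_dispersion must be >= 0")
  if (object@dirichlet_conc <= 0) msg <- c(msg, "dirichlet_conc must be > 0")
  for (f in c("effect_ptgs2_fold", "effect_ren_base_fold", "effect_ren_fold"))
    if (slot(object, f) < 1) msg <- c(msg, sprintf("%s must be >= 1", f))
  if (object@high_responder_frac < 0 || object@high_responder_frac > 1)
    msg <- c(msg, "high_responder_frac must lie in [0, 1]")
  if (object@md_fraction <= 0 || object@md_fraction > 1)
    msg <- c(msg, "md_fraction must lie in (0, 1]")
  if (anyDuplicated(object@cell_types))
    msg <- c(msg, "cell_types must be unique")
  if (!setequal(object@zone_layout, .ZONES) ||
      length(object@zone_layout) != 4L)
    msg <- c(msg, sprintf("zone_layout must order the four zones %s",
                          paste(.ZONES, collapse = "/")))
  if (!all(names(object@zone_affinity) %in% .ZONES) ||
      !setequal(names(object@zone_affinity), .ZONES))
    msg <- c(msg, "zone_affinity must name all four zones")
  aff <- unlist(object@zone_affinity)
  if (!all(aff %in% object@cell_types))
    msg <- c(msg, "zone_affinity refers to unknown cell types")
  gp <- object@glomerulus_profile
  if (is.null(names(gp)) || !all(names(gp) %in% object@cell_types))
    msg <- c(msg, "glomerulus_profile must be named by known cell types")
  if (any(gp < 0) || abs(sum(gp) - 1) > 1e-9)
    msg <- c(msg, "glomerulus_profile must be non-negative and sum to 1")
  if (!(object@macula_densa_type %in% object@cell_types))
    msg <- c(msg, "macula_densa_type must be a known cell type")
  if (!(object@response_cell_type %in% object@cell_types))
    msg <- c(msg, "response_cell_type must be a known cell type")
  if (length(object@n_markers_per_type) != 1L ||
      object@n_markers_per_type < 1L)
    msg <- c(msg, "n_markers_per_type must be a positive count")
  nmin <- length(.NAMED_GENES) + length(.MITO_GENES) +
    object@n_markers_per_type * length(object@cell_types) + 10L
  if (length(object@n_genes) == 1L && !is.na(object@n_genes) &&
      object@n_genes < nmin)
    msg <- c(msg, sprintf("n_genes must be >= %d for %d cell types",
                          nmin, length(object@cell_types)))
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' All arguments default to the scaled-down renal study conditions
#' documented in \linkS4class{SimConfig}.
#'
#' @param n_genes,n_markers_per_type,cell_types,zone_affinity,n_cells_per_type
#'   see \linkS4class{SimConfig}.
#' @param lattice_rows,lattice_cols,zone_layout,n_glomeruli see
#'   \linkS4class{SimConfig}.
#' @param glomerulus_profile,macula_densa_type,md_fraction,md_adjacent see
#'   \linkS4class{SimConfig}.
#' @param n_samples,depth_mean_umi,nb_dispersion,dirichlet_conc see
#'   \linkS4class{SimConfig}.
#' @param effect_ptgs2_fold,effect_ren_base_fold,effect_ren_fold see
#'   \linkS4class{SimConfig}.
#' @param high_responder_frac,response_cell_type,seed see
#'   \linkS4class{SimConfig}.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(seed = 7)
#' cfg
#' @export
SimConfig <- function(
    n_genes = 500L,
    n_markers_per_type = 25L,
    cell_types = c("Podo", "PT", "TAL-1", "TAL-2", "DCT", "JG", "MC",
                   "CD-PC", "DTL", "CD-IM"),
    zone_affinity = list(
      Cortex = c("PT", "TAL-1", "DCT", "CD-PC"),
      OMOS = c("PT", "TAL-1", "DTL", "CD-PC"),
      OMIS = c("DTL", "TAL-1", "CD-PC", "CD-IM"),
      IM = c("DTL", "CD-IM")),
    n_cells_per_type = 100L,
    lattice_rows = 40L, lattice_cols = 40L,
    zone_layout = c("Cortex", "OMOS", "OMIS", "IM"),
    n_glomeruli = 40L,
    glomerulus_profile = c(Podo = 0.5, MC = 0.3, JG = 0.2),
    macula_densa_type = "TAL-2",
    md_fraction = 0.6,
    md_adjacent = TRUE,
    n_samples = 3L,
    depth_mean_umi = 5000,
    nb_dispersion = 0.1,
    dirichlet_conc = 1.0,
    effect_ptgs2_fold = 3,
    effect_ren_base_fold = 3,
    effect_ren_fold = 5,
    high_responder_frac = 0.25,
    response_cell_type = "JG",
    seed = 1L) {
  new("SimConfig",
      n_genes = as.integer(n_genes),
      n_markers_per_type = as.integer(n_markers_per_type),
      cell_types = cell_types,
      zone_affinity = zone_affinity,
      n_cells_per_type = as.integer(n_cells_per_type),
      lattice_rows = as.integer(lattice_rows),
      lattice_cols = as.integer(lattice_cols),
      zone_layout = zone_layout, n_glomeruli = as.integer(n_glomeruli),
      glomerulus_profile = glomerulus_profile,
      macula_densa_type = macula_densa_type, md_fraction = md_fraction,
      md_adjacent = md_adjacent, n_samples = as.integer(n_samples),
      depth_mean_umi = depth_mean_umi, nb_dispersion = nb_dispersion,
      dirichlet_conc = dirichlet_conc,
      effect_ptgs2_fold = effect_ptgs2_fold,
      effect_ren_base_fold = effect_ren_base_fold,
      effect_ren_fold = effect_ren_fold,
      high_responder_frac = high_responder_frac,
      response_cell_type = response_cell_type,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf(" %d genes, %d cell types, %d cells/type (reference)\n",
              object@n_genes, length(object@cell_types),
              object@n_cells_per_type))
  cat(sprintf(" lattice %dx%d, zones %s\n", object@lattice_rows,
              object@lattice_cols, paste(object@zone_layout, collapse = ">")))
  cat(sprintf(" %d glomeruli/sample, %d samples x {Ctrl, Losa}\n",
              object@n_glomeruli, object@n_samples))
  cat(sprintf(" depth %g UMI, dispersion %g\n", object@depth_mean_umi,
              object@nb_dispersion))
  cat(sprintf(" folds: Ptgs2 %g, Ren base %g, Ren high-responder x%g (top %g%%)\n",
              object@effect_ptgs2_fold, object@effect_ren_base_fold,
              object@effect_ren_fold, 100 * object@high_responder_frac))
  cat(sprintf(" seed %d\n", object@seed))
})

#' Read a SimConfig from a YAML or JSON file
#'
#' The file may set any subset of the \code{\link{SimConfig}} arguments;
#' unknown fields are an error.
#'
#' @param path YAML (or JSON, which YAML subsumes) file of config fields.
#' @return A validated \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(SimConfig))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    .stopf("unknown SimConfig field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(vals$zone_affinity))
    vals$zone_affinity <- lapply(vals$zone_affinity, as.character)
  if (!is.null(vals$glomerulus_profile))
    vals$glomerulus_profile <- unlist(vals$glomerulus_profile)
  do.call(SimConfig, vals)
}
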