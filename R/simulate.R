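#' SyntheticTruth: planted ground truth of a simulated tissue
#'
#' @slot fractions \linkS4class{FractionMatrix} of true per-spot composition.
#' @slot high_responders named list (one entry per treated sample) of
#'   glomerulus identifiers planted as high-responders.
#' @slot md_spots spot identifiers of the macula-densa-enriched spots.
#' @slot base_means genes x types matrix of per-type base expression means
#'   (arbitrary scale; columns are normalized to relative shares when
#'   expected counts are formed).
#' @export
setClass("SyntheticTruth", representation(
  fractions = "FractionMatrix", high_responders = "list",
  md_spots = "character", base_means = "matrix"))

setValidity("SyntheticTruth", function(object) {
  f <- fractions(object@fractions)
  if (any(abs(rowSums(f) - 1) > 1e-9))
    return("true fraction rows must sum to 1")
  TRUE
})

#' @rdname SyntheticTruth-class
#' @param object a \linkS4class{SyntheticTruth}.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d spots, %d macula densa spots\n",
              nrow(fractions(object@fractions)), length(object@md_spots)))
  hr <- vapply(object@high_responders, length, 1L)
  if (length(hr))
    cat(" planted high-responders:",
        paste(sprintf("%s=%d", names(hr), hr), collapse = " "), "\n")
})

## Gene inventory: named response/housekeeping/marker genes, three exclusive
## markers per type, lognormal filler genes. Deterministic given the config.
.geneNames <- function(config) {
  nmk <- config@n_markers_per_type
  markers <- as.vector(vapply(config@cell_types,
    function(t) paste0(t, ".mk", seq_len(nmk)), character(nmk)))
  n_fill <- config@n_genes - length(.NAMED_GENES) - length(.MITO_GENES) -
    length(markers)
  c(.NAMED_GENES, .MITO_GENES, markers, sprintf("gene%04d", seq_len(n_fill)))
}

## Base expression means per gene per type (arbitrary scale). The named
## genes encode the renal biology the pipeline must recover: Ren in JG,
## Ptgs2/Pappa2 in the macula densa type, Slc12a1 across TAL, Rplp0 flat.
.geneBaseMeans <- function(config) {
  .withSeed(config@seed * 13L + 7L, {
    types <- config@cell_types
    genes <- .geneNames(config)
    B <- matrix(0, length(genes), length(types),
                dimnames = list(genes, types))
    n_fill <- sum(startsWith(genes, "gene"))
    fill <- startsWith(genes, "gene")
    gene_level <- stats::rlnorm(n_fill, meanlog = log(5), sdlog = 1)
    B[fill, ] <- gene_level *
      matrix(stats::rlnorm(n_fill * length(types), 0, 0.3), n_fill)
    nmk <- config@n_markers_per_type
    for (t in types) {
      mk <- paste0(t, ".mk", seq_len(nmk))
      B[mk, t] <- 80 * stats::rlnorm(nmk, 0, 0.3)
    }
    B["Rplp0", ] <- 100
    B[.MITO_GENES, ] <- 40
    B["Slc12a1", c("TAL-1", "TAL-2")[c("TAL-1", "TAL-2") %in% types]] <- 30
    if (config@macula_densa_type %in% types) {
      B["Pappa2", config@macula_densa_type] <- 20
      B["Ptgs2", config@macula_densa_type] <- 1
    }
    B["Ren", config@response_cell_type] <- 3
    B
  })
}

## Column-normalize base means to per-type relative transcript shares.
.typeShares <- function(base_means) sweep(base_means, 2L, colSums(base_means), "/")

#' Simulate a labelled single-cell reference
#'
#' Draws \code{n_cells_per_type} cells per cell type, each negative-binomial
#' around the type's depth-scaled base-mean profile. The per-type base means
#' are stored in \code{metadata(x)$base_means} (raw scale) and
#' \code{metadata(x)$expected_profiles} (depth-scaled expectation actually
#' sampled from), so recovery can be checked against the generating truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{CountMatrix} (modality \code{single_cell}) whose
#'   \code{colData(x)$cell_type} carries the cell labels.
#' @examples
#' ref <- makeReference(SimConfig(n_cells_per_type = 5, seed = 1))
#' table(SummarizedExperiment::colData(ref)$cell_type)
#' @export
makeReference <- function(config) {
  validObject(config)
  B <- .geneBaseMeans(config)
  P <- .typeShares(B)
  .withSeed(config@seed * 13L + 11L, {
    types <- config@cell_types
    n <- config@n_cells_per_type
    mu <- config@depth_mean_umi * P[, rep(types, each = n), drop = FALSE]
    colnames(mu) <- sprintf("%s_c%03d", rep(types, each = n),
                            rep(seq_len(n), length(types)))
    m <- .rcounts(mu, config@nb_dispersion)
    cm <- CountMatrix(m, "single_cell",
      colData = S4Vectors::DataFrame(
        cell_type = rep(types, each = n), row.names = colnames(m)))
    metadata(cm)$base_means <- B
    metadata(cm)$expected_profiles <- config@depth_mean_umi * P
    cm
  })
}

.hexOffsets <- matrix(c(0L, 2L, 0L, -2L, 1L, 1L, 1L, -1L, -1L, 1L, -1L, -1L),
                      ncol = 2L, byrow = TRUE,
                      dimnames = list(NULL, c("row", "col")))

## Row band -> zone for a lattice of R rows split into four contiguous bands.
.zoneOfRow <- function(row, n_rows, zone_layout) {
  bounds <- floor(n_rows * (1:3) / 4)
  zone_layout[findInterval(row, bounds) + 1L]
}

#' Simulate an annotated spot lattice with planted spatial structure
#'
#' Builds one hexagonal array per sample (conditions Ctrl and Losa,
#' \code{n_samples} each), splits rows into four contiguous zone bands,
#' places \code{n_glomeruli} single-spot glomeruli in the cortex band with
#' exactly one macula-densa-enriched spot on a free hexagonal neighbour of
#' each (unless \code{md_adjacent} is FALSE, the spatial null, which
#' scatters those spots uniformly), fills every other spot with a
#' zone-affine Dirichlet mixture, and plants the high-responder glomerulus
#' subset of every treated sample.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return \code{list(lattice = SpotLattice, truth = SyntheticTruth)}.
#' @export
makeTissue <- function(config) {
  validObject(config)
  B <- .geneBaseMeans(config)
  .withSeed(config@seed * 13L + 23L, {
    samples <- data.frame(
      sample_id = as.vector(outer(.CONDITIONS, seq_len(config@n_samples),
                                  function(c, i) sprintf("%s_%d", c, i))),
      condition = rep(.CONDITIONS, config@n_samples))
    samples <- samples[order(samples$sample_id), ]

    types <- config@cell_types
    all_spots <- list(); all_frac <- list()
    md_spots <- character(); high_resp <- list()

    for (k in seq_len(nrow(samples))) {
      sid <- samples$sample_id[k]
      rows <- rep(seq_len(config@lattice_rows) - 1L,
                  each = ceiling(config@lattice_cols / 2))
      cols0 <- seq(0L, config@lattice_cols - 1L, by = 2L)
      cols <- as.vector(vapply(seq_len(config@lattice_rows) - 1L,
        function(r) cols0 + r %% 2L, integer(length(cols0))))
      keep <- cols < config@lattice_cols
      rows <- rows[keep]; cols <- cols[keep]
      zone <- .zoneOfRow(rows, config@lattice_rows, config@zone_layout)
      spot_id <- sprintf("%s:%d:%d", sid, rows, cols)
      d <- data.frame(spot_id = spot_id, array_row = rows, array_col = cols,
                      zone = zone, glomerulus_id = NA_character_,
                      sample_id = sid, condition = samples$condition[k],
                      stringsAsFactors = FALSE)
      cortex <- which(d$zone == "Cortex")
      coord <- paste(d$array_row, d$array_col)
      idx_of <- seq_len(nrow(d)); names(idx_of) <- coord
      free <- rep(TRUE, nrow(d))
      is_glom <- is_md <- rep(FALSE, nrow(d))

      neighbours <- function(i) {
        nb <- paste(d$array_row[i] + .hexOffsets[, "row"],
                    d$array_col[i] + .hexOffsets[, "col"])
        unname(idx_of[nb[nb %in% names(idx_of)]])
      }

      placed <- 0L
      for (i in sample(cortex)) {
        if (placed >= config@n_glomeruli) break
        if (!free[i]) next
        nb <- neighbours(i)
        nb <- nb[free[nb] & d$zone[nb] == "Cortex"]
        if (config@md_adjacent && !length(nb)) next
        placed <- placed + 1L
        free[i] <- FALSE; is_glom[i] <- TRUE
        d$glomerulus_id[i] <- sprintf("%s_g%02d", sid, placed)
        if (config@md_adjacent) {
          j <- if (length(nb) == 1L) nb else sample(nb, 1L)
          free[j] <- FALSE; is_md[j] <- TRUE
        }
      }
      if (placed < config@n_glomeruli)
        .stopf(paste("n_glomeruli = %d exceeds the cortical spots with free",
                     "neighbours available in sample %s (placed %d)"),
               config@n_glomeruli, sid, placed)
      if (!config@md_adjacent) {
        pool <- cortex[free[cortex]]
        j <- sample(pool, config@n_glomeruli)
        free[j] <- FALSE; is_md[j] <- TRUE
      }

      ## true fractions
      f <- matrix(0, nrow(d), length(types),
                  dimnames = list(d$spot_id, types))
      gp <- config@glomerulus_profile
      f[is_glom, names(gp)] <- matrix(gp, sum(is_glom), length(gp),
                                      byrow = TRUE)
      for (z in .ZONES) {
        ord <- which(d$zone == z & !is_glom & !is_md)
        if (!length(ord)) next
        aff <- config@zone_affinity[[z]]
        f[ord, aff] <- .rdirichlet(length(ord),
                                   rep(config@dirichlet_conc, length(aff)))
      }
      mdw <- which(is_md)
      if (length(mdw)) {
        aff <- config@zone_affinity[["Cortex"]]
        bg <- .rdirichlet(length(mdw), rep(config@dirichlet_conc, length(aff)))
        f[mdw, ] <- 0
        f[mdw, aff] <- (1 - config@md_fraction) * bg
        f[mdw, config@macula_densa_type] <-
          f[mdw, config@macula_densa_type] + config@md_fraction
      }

      if (samples$condition[k] == "Losa") {
        n_hr <- ceiling(config@high_responder_frac * config@n_glomeruli)
        gids <- sort(d$glomerulus_id[is_glom])
        high_resp[[sid]] <- sort(sample(gids, n_hr))
      }
      md_spots <- c(md_spots, d$spot_id[is_md])
      all_spots[[sid]] <- d
      all_frac[[sid]] <- f
    }

    lattice <- SpotLattice(do.call(rbind, all_spots))
    fr <- do.call(rbind, all_frac)
    truth <- new("SyntheticTruth",
                 fractions = FractionMatrix(fr),
                 high_responders = high_resp,
                 md_spots = md_spots,
                 base_means = B)
    list(lattice = lattice, truth = truth)
  })
}

#' Simulate spot-level counts from a tissue and its planted truth
#'
#' Expected expression of each spot is the true-fraction-weighted mixture of
#' the per-type relative expression profiles, scaled to
#' \code{depth_mean_umi}. Treatment effects are applied component-wise in
#' treated (\code{Losa}) samples only: the Ptgs2 analogue is multiplied by
#' \code{effect_ptgs2_fold} inside the macula densa component of every spot,
#' and the Ren analogue by \code{effect_ren_base_fold} inside every JG
#' component, times a further \code{effect_ren_fold} in the JG component of
#' planted high-responder glomeruli. Counts are then drawn
#' negative-binomially.
#'
#' @param lattice a \linkS4class{SpotLattice} from \code{\link{makeTissue}}.
#' @param truth the matching \linkS4class{SyntheticTruth}.
#' @param config the \linkS4class{SimConfig} used to build them.
#' @return A \linkS4class{CountMatrix} (modality \code{spatial}).
#' @export
makeSpotCounts <- function(lattice, truth, config) {
  validObject(config)
  d <- spotData(lattice)
  f <- fractions(truth@fractions)
  missing <- setdiff(d$spot_id, rownames(f))
  if (length(missing))
    .stopf("truth is missing fractions for %d spot(s), e.g. %s",
           length(missing), missing[1L])
  f <- f[d$spot_id, , drop = FALSE]
  B <- truth@base_means
  P <- .typeShares(B)

  mu <- config@depth_mean_umi * (P %*% t(f))  # genes x spots

  treated <- d$condition == "Losa"
  mdt <- config@macula_densa_type
  jg <- config@response_cell_type
  if (any(treated)) {
    mu["Ptgs2", treated] <- mu["Ptgs2", treated] +
      config@depth_mean_umi * f[treated, mdt] * P["Ptgs2", mdt] *
      (config@effect_ptgs2_fold - 1)
    ren_mult <- rep(1, nrow(d))
    ren_mult[treated] <- config@effect_ren_base_fold
    hr_gloms <- unlist(truth@high_responders, use.names = FALSE)
    hr <- !is.na(d$glomerulus_id) & d$glomerulus_id %in% hr_gloms
    ren_mult[hr & treated] <- config@effect_ren_base_fold * config@effect_ren_fold
    mu["Ren", ] <- mu["Ren", ] +
      config@depth_mean_umi * f[, jg] * P["Ren", jg] * (ren_mult - 1)
  }

  .withSeed(config@seed * 13L + 41L,
            CountMatrix(.rcounts(mu, config@nb_dispersion), "spatial"))
}

#' Draw mixture spot counts from explicit fractions
#'
#' Convenience generator for deconvolution benchmarking: given per-type base
#' means and an arbitrary spots x types fraction matrix, draws counts
#' negative-binomially around the depth-scaled mixture expectation (no
#' spatial structure, no treatment effects).
#'
#' @param base_means genes x types base-mean matrix (any positive scale).
#' @param fracs spots x types fraction matrix, rows on the simplex.
#' @param depth_mean_umi expected total UMIs per spot.
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param seed RNG seed.
#' @return A \linkS4class{CountMatrix} (modality \code{spatial}).
#' @export
makeMixtureCounts <- function(base_means, fracs, depth_mean_umi,
                              nb_dispersion, seed = 1L) {
  stopifnot(all(colnames(fracs) %in% colnames(base_means)),
            all(abs(rowSums(fracs) - 1) < 1e-9))
  P <- .typeShares(base_means)[, colnames(fracs), drop = FALSE]
  mu <- depth_mean_umi * (P %*% t(fracs))
  if (is.null(rownames(fracs)))
    rownames(fracs) <- sprintf("spot%04d", seq_len(nrow(fracs)))
  colnames(mu) <- rownames(fracs)
  .withSeed(seed, CountMatrix(.rcounts(mu, nb_dispersion), "spatial"))
}

#' Simulate a complete synthetic study
#'
#' Runs \code{\link{makeReference}}, \code{\link{makeTissue}} and
#' \code{\link{makeSpotCounts}} under one config.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return \code{list(reference, lattice, truth, spot_counts)}.
#' @export
simulateStudy <- function(config) {
  ref <- makeReference(config)
  tissue <- makeTissue(config)
  sc <- makeSpotCounts(tissue$lattice, tissue$truth, config)
  list(reference = ref, lattice = tissue$lattice, truth = tissue$truth,
       spot_counts = sc)
}
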