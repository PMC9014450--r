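#' PipelineConfig: thresholds and targets of the full analysis
#'
#' Defaults follow the study conventions: QC bounds of 200-5,000 detected
#' genes, under 30,000 UMIs and under 40% mitochondrial reads; a 0.05
#' minimum target-cell fraction for spot selection; the skewness screen's
#' 0.01 mean filter and top-5% flag; the top-25% high-responder rule; and
#' counts-per-10k log normalization.
#'
#' @slot min_genes,max_genes inclusive detected-gene bounds per cell.
#' @slot max_umi strict UMI upper bound per cell.
#' @slot max_mito_frac strict mitochondrial-fraction upper bound.
#' @slot min_fraction inclusive minimum target-cell fraction of a spot.
#' @slot min_mean strict mean-expression filter of the skewness screen.
#' @slot top_skew_frac flagged fraction of the skewness screen.
#' @slot high_resp_frac per-sample fraction selected as high-responding.
#' @slot lognorm_scale library-size target of the total-count step.
#' @slot alpha nominal significance level used in reports.
#' @slot response_gene,response_cell_type the JG response axis (Ren in JG).
#' @slot md_gene,md_cell_type the macula densa response axis (Ptgs2 in
#'   TAL-2).
#' @slot tal1_type the competing TAL type for dominant-score
#'   classification.
#' @slot seed RNG seed echoed into reports.
#' @export
setClass("PipelineConfig", representation(
  min_genes = "integer", max_genes = "integer", max_umi = "numeric",
  max_mito_frac = "numeric", min_fraction = "numeric", min_mean = "numeric",
  top_skew_frac = "numeric", high_resp_frac = "numeric",
  lognorm_scale = "numeric", alpha = "numeric",
  response_gene = "character", response_cell_type = "character",
  md_gene = "character", md_cell_type = "character",
  tal1_type = "character", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@min_genes >= object@max_genes)
    msg <- c(msg, "min_genes must be below max_genes")
  for (f in c("min_fraction", "min_mean", "top_skew_frac",
              "high_resp_frac", "max_mito_frac", "alpha")) {
    v <- slot(object, f)
    if (v <= 0 || v >= 1) msg <- c(msg, sprintf("%s must lie in (0, 1)", f))
  }
  if (object@max_umi <= 0 || object@lognorm_scale <= 0)
    msg <- c(msg, "max_umi and lognorm_scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param min_genes,max_genes,max_umi,max_mito_frac QC thresholds.
#' @param min_fraction,min_mean,top_skew_frac,high_resp_frac selection and
#'   screening thresholds.
#' @param lognorm_scale,alpha,seed normalization scale, report alpha, seed.
#' @param response_gene,response_cell_type,md_gene,md_cell_type,tal1_type
#'   analysis targets.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(min_genes = 200L, max_genes = 5000L,
                           max_umi = 30000, max_mito_frac = 0.40,
                           min_fraction = 0.05, min_mean = 0.01,
                           top_skew_frac = 0.05, high_resp_frac = 0.25,
                           lognorm_scale = 10000, alpha = 0.05,
                           response_gene = "Ren", response_cell_type = "JG",
                           md_gene = "Ptgs2", md_cell_type = "TAL-2",
                           tal1_type = "TAL-1", seed = 1L) {
  new("PipelineConfig", min_genes = as.integer(min_genes),
      max_genes = as.integer(max_genes), max_umi = max_umi,
      max_mito_frac = max_mito_frac, min_fraction = min_fraction,
      min_mean = min_mean, top_skew_frac = top_skew_frac,
      high_resp_frac = high_resp_frac, lognorm_scale = lognorm_scale,
      alpha = alpha, response_gene = response_gene,
      response_cell_type = response_cell_type, md_gene = md_gene,
      md_cell_type = md_cell_type, tal1_type = tal1_type,
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf(" QC: genes [%d, %d], UMI < %g, mito < %g\n", object@min_genes,
              object@max_genes, object@max_umi, object@max_mito_frac))
  cat(sprintf(" min_fraction %g, min_mean %g, top_skew %g, high_resp %g\n",
              object@min_fraction, object@min_mean, object@top_skew_frac,
              object@high_resp_frac))
  cat(sprintf(" axes: %s in %s (response), %s in %s (macula densa) vs %s\n",
              object@response_gene, object@response_cell_type,
              object@md_gene, object@md_cell_type, object@tal1_type))
})

.configString <- function(cfg) {
  fields <- slotNames(cfg)
  paste(vapply(fields, function(f)
    sprintf("%s=%s", f, paste(format(slot(cfg, f)), collapse = ",")),
    character(1)), collapse = "; ")
}

.configHash <- function(cfg)
  sprintf("%08x", sum(utf8ToInt(.configString(cfg)) *
                      (seq_along(utf8ToInt(.configString(cfg))) %% 97 + 1)))

.writeReport <- function(d, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spothet report; config_hash=%s", .configHash(cfg)), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full spot-heterogeneity pipeline
#'
#' Executes the stages in order — reference QC, signature building, spot
#' deconvolution, dominant-score spatial classification with
#' glomerulus-adjacency testing, fraction normalization for the macula
#' densa and JG axes, responder classification and condition test,
#' skewness/KS heterogeneity screen, high-responder selection, and
#' differential expression — and optionally writes TSV reports plus a run
#' log. Every stage failure aborts with the stage name. Re-running with the
#' same inputs and config reproduces the outputs (the only randomness is
#' the tie-free deterministic ordering of selections).
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param reference labelled single-cell \linkS4class{CountMatrix}
#'   (\code{colData(reference)$cell_type}).
#' @param spot_counts spatial \linkS4class{CountMatrix}.
#' @param lattice the matching \linkS4class{SpotLattice}.
#' @param out_dir optional report directory (NULL: no files written).
#' @return Invisibly, a list with the per-stage results: \code{qc},
#'   \code{signature}, \code{fractions}, \code{adjacency}, \code{md_test},
#'   \code{gene_stats}, \code{responders}, \code{responder_test},
#'   \code{high_responding}, \code{de_high}, \code{de_md}.
#' @export
runPipeline <- function(config, reference, spot_counts, lattice,
                        out_dir = NULL) {
  stopifnot(is(config, "PipelineConfig"), is(reference, "CountMatrix"),
            is(spot_counts, "CountMatrix"), is(lattice, "SpotLattice"))
  validObject(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_lines <- c(sprintf("spothet run; seed=%d; config_hash=%s", config@seed,
                         .configHash(config)),
                 .configString(config))
  d <- spotData(lattice)

  qc <- stage("qc", qcFilterCells(
    reference, min_genes = config@min_genes, max_genes = config@max_genes,
    max_umi = config@max_umi, max_mito_frac = config@max_mito_frac))
  log_lines <- c(log_lines, sprintf("qc: %d of %d cells retained",
                                    ncol(qc), ncol(reference)))

  sig <- stage("signature", buildSignature(qc))
  fr <- stage("deconvolve", estimateFractions(spot_counts, sig))

  adjacency <- stage("spatial", {
    f <- fractions(fr)
    cortical <- d$spot_id[d$zone == "Cortex"]
    cortical <- intersect(cortical, rownames(f)[!degenerateSpots(fr)])
    glom <- d$spot_id[!is.na(d$glomerulus_id)]
    lab <- classifyDominant(f[cortical, config@tal1_type],
                            f[cortical, config@md_cell_type],
                            labels = c(config@tal1_type, config@md_cell_type))
    names(lab) <- cortical
    tab <- adjacencyContingency(lab, glom, lattice)
    fish <- fisherExact2x2(tab)
    list(labels = lab, table = tab, p_value = fish$p_value,
         odds_ratio = fish$odds_ratio)
  })

  md_test <- stage("normalize_md", {
    nc <- fractionNormalize(spot_counts, fr, config@md_cell_type,
                            config@min_fraction)
    v <- normValues(lognormalizeTotal(nc, config@lognorm_scale))
    spots <- colnames(v)
    cond <- d$condition[match(spots, d$spot_id)]
    if (length(unique(cond)) == 2L) {
      w <- wilcoxonRankSum(v[config@md_gene, cond == "Losa"],
                           v[config@md_gene, cond == "Ctrl"])
      list(n_spots = length(spots), statistic = w$statistic,
           p_value = w$p_value,
           mean_losa = mean(v[config@md_gene, cond == "Losa"]),
           mean_ctrl = mean(v[config@md_gene, cond == "Ctrl"]),
           spots = spots)
    } else list(n_spots = length(spots), statistic = NA_real_,
                p_value = NA_real_, mean_losa = NA_real_,
                mean_ctrl = NA_real_, spots = spots)
  })

  het <- stage("heterogeneity", {
    nc <- fractionNormalize(spot_counts, fr, config@response_cell_type,
                            config@min_fraction)
    glom <- d$spot_id[!is.na(d$glomerulus_id)]
    keep <- intersect(colnames(normValues(nc)), glom)
    nc_glom <- NormalizedMatrix(normValues(nc)[, keep, drop = FALSE],
                                normMetadata(nc))
    lin <- lognormalizeTotal(nc_glom, config@lognorm_scale, log = FALSE)
    logm <- lognormalizeTotal(nc_glom, config@lognorm_scale, log = TRUE)
    gene_stats <- skewnessScreen(lin, config@min_mean, config@top_skew_frac)
    vals <- normValues(lin)[config@response_gene, ]
    resp <- responderTable(vals, lattice)
    rtest <- tryCatch(responderConditionTest(resp), error = function(e) NULL)
    hi <- selectHighResponding(vals, resp$sample_id, config@high_resp_frac)
    resp$high_responding <- resp$spot_id %in% hi$spot_id
    de_high <- if (nrow(hi) && nrow(hi) < ncol(normValues(logm)))
      deBetweenGroups(logm, hi$spot_id,
                      setdiff(colnames(normValues(logm)), hi$spot_id))
    else NULL
    list(gene_stats = gene_stats, responders = resp,
         responder_test = rtest, high_responding = hi, de_high = de_high,
         norm_log = logm)
  })

  de_md <- stage("de_md", {
    spots <- md_test$spots
    cond <- d$condition[match(spots, d$spot_id)]
    if (length(unique(cond)) == 2L) {
      nc <- fractionNormalize(spot_counts, fr, config@md_cell_type,
                              config@min_fraction)
      logm <- lognormalizeTotal(nc, config@lognorm_scale)
      deBetweenGroups(logm, spots[cond == "Losa"], spots[cond == "Ctrl"])
    } else NULL
  })

  res <- list(qc = qc, signature = sig, fractions = fr,
              adjacency = adjacency, md_test = md_test,
              gene_stats = het$gene_stats, responders = het$responders,
              responder_test = het$responder_test,
              high_responding = het$high_responding,
              de_high = het$de_high, de_md = de_md)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fmat <- fractions(fr)
    .writeReport(data.frame(spot_id = rownames(fmat), fmat,
                            degenerate = degenerateSpots(fr),
                            check.names = FALSE),
                 file.path(out_dir, "fractions.tsv"), config)
    adj <- adjacency$table
    .writeReport(data.frame(group = rownames(adj), adj,
                            odds_ratio = adjacency$odds_ratio,
                            p_value = adjacency$p_value, check.names = FALSE),
                 file.path(out_dir, "adjacency.tsv"), config)
    .writeReport(het$gene_stats,
                 file.path(out_dir, "gene_dist_stats.tsv"), config)
    .writeReport(het$responders,
                 file.path(out_dir, "responders.tsv"), config)
    if (!is.null(het$de_high))
      .writeReport(het$de_high,
                   file.path(out_dir, "de_high_responding.tsv"), config)
    if (!is.null(de_md))
      .writeReport(de_md, file.path(out_dir, "de_macula_densa.tsv"), config)
    log_lines <- c(log_lines,
                   sprintf("spatial: adjacency p=%.3g OR=%.3g",
                           adjacency$p_value, adjacency$odds_ratio),
                   sprintf("md: %d spots, %s p=%.3g", md_test$n_spots,
                           config@md_gene, md_test$p_value),
                   sprintf("responders: %d spots, condition p=%.3g",
                           nrow(het$responders),
                           if (is.null(het$responder_test)) NA else
                             het$responder_test$p_value))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(res)
}
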