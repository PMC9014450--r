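#' Moment skewness of a sample
#'
#' Population-moment skewness \eqn{g_1 = m_3 / m_2^{3/2}} with central
#' moments \eqn{m_k = \frac{1}{n}\sum (x_i - \bar x)^k}; no small-sample
#' bias correction. Used as the long-right-tail index of heterogeneous
#' expression.
#'
#' @param x numeric vector, \code{length(x) >= 3}.
#' @return The skewness; \code{NA} for a constant vector (undefined rather
#'   than NaN).
#' @examples
#' sampleSkewness(c(0, 0, 0, 1))  # 2 / sqrt(3)
#' @export
sampleSkewness <- function(x) {
  if (length(x) < 3L) stop("skewness needs n >= 3")
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' Per-gene distribution summary
#'
#' @param x numeric vector of one gene's expression across spots.
#' @return \code{list(n, mean, sd, skewness)}; skewness is \code{NA} when
#'   undefined (constant input).
#' @export
geneDistributionStats <- function(x) {
  if (length(x) < 3L) stop("distribution stats need n >= 3")
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       skewness = sampleSkewness(x))
}

## Asymptotic two-sided Kolmogorov distribution tail: P(sqrt(n) D > t).
.ksTailAsymptotic <- function(t) {
  if (t < 1e-10) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' One-sample Kolmogorov-Smirnov test against a fitted Gaussian
#'
#' Compares the empirical distribution of \code{x} with the Gaussian whose
#' mean and standard deviation are estimated from the same sample (the
#' random-response null of the heterogeneity screen). The statistic is the
#' usual two-sided supremum distance of the ECDF from the fitted normal
#' CDF; the p-value uses the asymptotic Kolmogorov distribution. Because
#' the null parameters are estimated, this p is anti-conservative; an
#' optional Lilliefors-style correction of the effective statistic is
#' offered.
#'
#' @param x numeric vector, \code{length(x) >= 5}, non-constant.
#' @param lilliefors apply the Lilliefors small-sample adjustment of the
#'   effective statistic (default FALSE, mirroring the plain procedure).
#' @return \code{list(statistic, p_value, n, mean, sd)}.
#' @export
ksGaussianTest <- function(x, lilliefors = FALSE) {
  n <- length(x)
  if (n < 5L) stop("KS Gaussian test needs n >= 5")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("KS Gaussian test is undefined for constant input (sd = 0)")
  u <- stats::pnorm(sort(x), mean = m, sd = s)
  i <- seq_len(n)
  D <- max(i / n - u, u - (i - 1) / n)
  t_eff <- if (lilliefors) (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
           else sqrt(n) * D
  list(statistic = D, p_value = .ksTailAsymptotic(t_eff), n = n,
       mean = m, sd = s)
}

#' Skewness screen for heterogeneously expressed genes
#'
#' Restricts to genes whose mean normalized expression is strictly above
#' \code{min_mean}, computes the per-gene skewness of expression across
#' spots, and flags the top \code{top_frac} fraction (exactly
#' \code{ceiling(top_frac * n_retained)} genes, ranked by skewness with
#' deterministic gene-id tie-break). Genes whose skewness is undefined
#' (constant across spots) are retained in the table but never flagged.
#' Per-gene Gaussian KS results are included where computable.
#'
#' @param nc a \linkS4class{NormalizedMatrix}; the screen is designed for
#'   the linear (pre-log) total-count-scaled values, whose right tails are
#'   not compressed.
#' @param min_mean strict lower bound on mean expression (default 0.01).
#' @param top_frac flagged fraction of retained genes (default 0.05).
#' @param sample_id optional sample label carried into the table.
#' @return data.frame with one row per retained gene: \code{gene_id},
#'   \code{sample_id}, \code{n}, \code{mean}, \code{sd}, \code{skewness},
#'   \code{ks_statistic}, \code{ks_p}, \code{passes_mean_filter},
#'   \code{top_skew}; sorted by skewness descending.
#' @export
skewnessScreen <- function(nc, min_mean = 0.01, top_frac = 0.05,
                           sample_id = NA_character_) {
  stopifnot(is(nc, "NormalizedMatrix"))
  v <- normValues(nc)
  if (ncol(v) < 3L) stop("skewness screen needs >= 3 spots")
  mu <- rowMeans(v)
  keep <- mu > min_mean
  if (sum(keep) < 20L)
    .warnf("only %d genes retained by the mean filter; quantile threshold unstable",
           sum(keep))
  v <- v[keep, , drop = FALSE]
  n <- ncol(v)
  stats_tab <- data.frame(
    gene_id = rownames(v), sample_id = sample_id, n = n,
    mean = rowMeans(v), sd = apply(v, 1L, stats::sd),
    skewness = apply(v, 1L, sampleSkewness),
    ks_statistic = NA_real_, ks_p = NA_real_,
    passes_mean_filter = TRUE, top_skew = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)
  can_ks <- stats_tab$sd > 0 & n >= 5L
  ks <- lapply(which(can_ks), function(i) ksGaussianTest(v[i, ]))
  stats_tab$ks_statistic[can_ks] <- vapply(ks, `[[`, 1, "statistic")
  stats_tab$ks_p[can_ks] <- vapply(ks, `[[`, 1, "p_value")
  defined <- which(!is.na(stats_tab$skewness))
  k <- min(ceiling(top_frac * nrow(stats_tab)), length(defined))
  if (k > 0) {
    ord <- defined[order(-stats_tab$skewness[defined],
                         stats_tab$gene_id[defined])]
    stats_tab$top_skew[ord[seq_len(k)]] <- TRUE
  }
  stats_tab[order(-ifelse(is.na(stats_tab$skewness), -Inf, stats_tab$skewness),
                  stats_tab$gene_id), ]
}

#' Classify spots as responding or non-responding
#'
#' A spot responds when its normalized response-gene value is strictly
#' greater than \code{threshold} (default 0: detected vs not detected).
#'
#' @param values numeric vector of normalized response-gene values.
#' @param threshold strict response threshold.
#' @return Character vector, \code{"Responding"} / \code{"Non-responding"}.
#' @export
classifyResponders <- function(values, threshold = 0) {
  if (anyNA(values)) stop("values must not contain NA")
  ifelse(values > threshold, "Responding", "Non-responding")
}

#' Assemble the per-spot responder table
#'
#' Joins normalized response-gene values with the lattice annotation and
#' applies \code{\link{classifyResponders}}.
#'
#' @param values named numeric vector (names are spot ids).
#' @param lattice a \linkS4class{SpotLattice} containing those spots.
#' @param threshold strict response threshold (default 0).
#' @return data.frame with \code{spot_id}, \code{sample_id},
#'   \code{condition}, \code{glomerulus_id}, \code{value},
#'   \code{responder}, \code{high_responding} (initialized FALSE; see
#'   \code{\link{selectHighResponding}}).
#' @export
responderTable <- function(values, lattice, threshold = 0) {
  stopifnot(is(lattice, "SpotLattice"))
  d <- spotData(lattice)
  idx <- match(names(values), d$spot_id)
  if (anyNA(idx))
    .stopf("spot '%s' not present in the lattice", names(values)[which(is.na(idx))[1L]])
  data.frame(
    spot_id = names(values), sample_id = d$sample_id[idx],
    condition = d$condition[idx], glomerulus_id = d$glomerulus_id[idx],
    value = unname(values),
    responder = classifyResponders(values, threshold),
    high_responding = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher test of responder counts between conditions
#'
#' Builds the 2x2 condition x responder-label table from a responder table
#' and applies \code{\link{fisherExact2x2}}.
#'
#' @param tbl a responder table from \code{\link{responderTable}}.
#' @return \code{list(table, p_value, odds_ratio)}.
#' @export
responderConditionTest <- function(tbl) {
  conds <- sort(unique(tbl$condition))
  if (length(conds) < 2L)
    stop("both conditions must be present for the responder test")
  tab <- matrix(0L, 2L, 2L, dimnames = list(
    conds, c("Responding", "Non-responding")))
  for (cond in conds) for (lab in colnames(tab))
    tab[cond, lab] <- sum(tbl$condition == cond & tbl$responder == lab)
  res <- fisherExact2x2(tab)
  list(table = tab, p_value = res$p_value, odds_ratio = res$odds_ratio)
}

#' Select high-responding spots per sample
#'
#' Within each sample, selects the \code{ceiling(frac * n)} spots with the
#' highest normalized response-gene values (ties broken deterministically
#' by spot id) and returns their union with per-sample provenance.
#'
#' @param values named numeric vector of normalized values (names are spot
#'   ids).
#' @param sample_ids sample of each spot, parallel to \code{values}.
#' @param frac fraction selected per sample (default 0.25).
#' @return data.frame of the selected spots: \code{spot_id},
#'   \code{sample_id}, \code{value}.
#' @export
selectHighResponding <- function(values, sample_ids, frac = 0.25) {
  stopifnot(length(values) == length(sample_ids), !is.null(names(values)))
  if (frac < 0 || frac > 1) stop("frac must lie in [0, 1]")
  out <- lapply(sort(unique(sample_ids)), function(s) {
    v <- values[sample_ids == s]
    if (!length(v)) {
      .warnf("sample %s has no eligible spots; skipped", s)
      return(NULL)
    }
    k <- ceiling(frac * length(v))
    ord <- order(-v, names(v))[seq_len(k)]
    data.frame(spot_id = names(v)[ord], sample_id = s, value = unname(v[ord]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
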