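---
title: "Dissecting heterogeneous drug response in spatial transcriptomics with spothet"
author: "spothet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spothet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A Visium spot captures the mixed transcriptome of the handful of cells it
overlaps. When a drug acts on a minority population — renin-producing
juxtaglomerular (JG) cells at the glomerular vascular pole, or the macula
densa cells of the thick ascending limb (TAL) that sit against each
glomerulus — the response signal is diluted by every other cell in the
spot, and the apparent spot-to-spot variability confounds composition with
biology. `spothet` implements a pipeline for this situation, using the
renin–angiotensin axis in the rat kidney under an angiotensin-receptor
blocker as its running model system: blocking the angiotensin II type 1
receptor releases feedback repression so that Cox-2 (*Ptgs2*) rises in
macula densa cells and renin (*Ren*) rises in JG cells, and individual
glomeruli may respond to very different degrees.

The pipeline has five analytical stages, each exposed as ordinary
functions over small S4 containers:

1. **Reference QC and signature building.** Single cells are kept when
   they show 200–5,000 detected genes (inclusive), under 30,000 total
   UMIs, and under 40% mitochondrial reads. Each surviving cell is scaled
   to counts-per-10k and averaged within its annotated type, giving the
   genes × types `SignatureMatrix`.
2. **Deconvolution.** Each spot's counts-per-10k profile over the shared
   genes is decomposed on the signature columns by non-negative least
   squares and renormalized to the simplex (`estimateFractions`).
   Transcript mixing is linear in counts, so the fit is done in linear,
   library-size-normalized space; the estimate is then invariant to spot
   sequencing depth. Spots with an all-zero shared-gene profile are
   flagged degenerate rather than renormalized.
3. **Fraction normalization.** For a target type with estimated fraction
   $F_j$ in spot $j$, expression is attributed to that type as
   $NC_{ij} = C_{ij} / F_j$ over the spots with $F_j \ge$ `min_fraction`
   (default 0.05 — the data do not dictate a unique value; it is logged in
   the output metadata and configurable). A total-count rescaling to 10,000
   per spot follows, with `log1p` applied for distributional displays, KS
   testing and differential expression.
4. **Spatial context.** Visium's hexagonal packing makes a spot's six
   neighbours the offsets (0, ±2) and (±1, ±1) in 0-based array
   coordinates. Cortical spots with any TAL score are classified by the
   dominant of the TAL-1 / TAL-2 (macula densa) fractions — TAL-1 only
   when strictly higher, ties to the minority group since the eligibility
   rule defines only the strictly-greater branch — and the classified
   groups are cross-tabulated against sharing a hex edge with a glomerulus
   spot. The two-sided Fisher exact p is the hypergeometric mass of tables
   no more probable than the observed one; the sample odds ratio is
   reported alongside.
5. **Heterogeneity screen and responder classification.** On the
   JG-fraction-normalized expression of glomerulus-overlapping spots, each
   gene's distribution is summarized by the population-moment skewness
   $g_1 = m_3/m_2^{3/2}$ and by a one-sample Kolmogorov–Smirnov test
   against the Gaussian fitted by moments (the "random response" null).
   Genes with mean normalized expression strictly above 0.01 are ranked by
   skewness and the top 5% flagged (exactly `ceiling(0.05·n)` genes, ties
   broken by gene id). Spots with normalized response-gene expression
   above a threshold (default 0: detected versus not) are "responding";
   responder counts are compared between conditions by Fisher's exact
   test; and the top 25% of eligible spots per sample (by normalized
   response expression, `ceiling(0.25·n)` with id tie-break) are the
   high-responding set used for differential expression (Wilcoxon rank-sum
   per gene, Benjamini–Hochberg adjustment, ranked by fold change of
   pseudocounted means).

## Scale choices in the skewness screen

The KS display and test operate on the log1p values, matching how such
distributions are plotted against a fitted Gaussian. The skewness ranking,
by contrast, is computed on the *linear* total-count-scaled values: the
screen exists to find long right tails, and the log transform compresses
exactly the tail it is looking for (a gene several-fold induced in a
minority of spots can even appear left-skewed after log because of the
zero class). Printed skewness values of order 5–6 for a strongly
heterogeneous response gene are only attainable on the linear scale, so
`lognormalizeTotal(..., log = FALSE)` feeds `skewnessScreen` while the
logged matrix feeds `ksGaussianTest` and the DE stage.

## KS with estimated parameters

The Gaussian null is fitted with the sample mean and standard deviation of
the same data, so the asymptotic KS p-value is anti-conservative. This
mirrors the plain procedure the screen is based on; a Lilliefors-style
adjustment of the effective statistic is available
(`ksGaussianTest(..., lilliefors = TRUE)`) for users who want the
corrected behaviour. The screen uses the KS result descriptively (the
housekeeping-versus-response contrast), not as a calibrated test.

## The synthetic study

`SimConfig()` describes a complete scaled-down two-condition study whose
planted structure every downstream stage must recover; all defaults were
fixed once, as the package's model of the real design, and the tests run
against them.

* **Design.** Three control and three treated samples (matching the
  triplicated design of the motivating study), each a 40×40 hex array of
  800 in-tissue spots, rows split into four equal zone bands
  (Cortex / OMOS / OMIS / IM).
* **Cell types and genes.** Ten renal types (podocyte, proximal tubule,
  TAL-1, TAL-2/macula densa, distal tubule, JG, mesangial, collecting
  duct, thin limb, inner-medullary collecting duct). The 500-gene panel
  emulates a curated deconvolution panel rather than a whole
  transcriptome: 25 exclusive markers per type plus named biology genes
  (*Ren* in JG, *Ptgs2* and *Pappa2* in TAL-2, *Slc12a1* across TAL,
  *Rplp0* flat everywhere, three mitochondrial genes) and lognormal
  background genes with mild between-type variation. The panel size is
  chosen so that simulated reference cells land inside the standard QC
  window, as real cells do.
* **Tissue.** Glomeruli are single cortical spots (composition: podocyte
  0.5, mesangial 0.3, JG 0.2) — single-spot glomeruli keep the ground
  truth unambiguous. Exactly one macula-densa-enriched spot (TAL-2
  fraction 0.6) is placed on a free hex neighbour of each glomerulus;
  `md_adjacent = FALSE` scatters those spots uniformly instead, giving the
  spatial null used for type-I-error checks. All other spots draw their
  composition from a flat Dirichlet over their zone's resident types.
* **Counts.** Spot expectation is the fraction-weighted mixture of the
  per-type relative profiles scaled to 5,000 UMIs; counts are
  gamma–Poisson with a single shared dispersion (default 0.1, a realistic
  spot-level overdispersion for UMI data; recovery benchmarks also run at
  the much harsher 0.5).
* **Treatment effects.** In treated samples *Ptgs2* is induced 3-fold in
  every macula densa component, and *Ren* 3-fold in every JG component
  (`effect_ren_base_fold`) with an additional 5-fold
  (`effect_ren_fold`) in a planted quarter of glomeruli — the
  high-responders. The global term models the treatment-wide renin
  induction of the biology; the planted subset concentrates it, which is
  what the heterogeneity screen must detect. Setting all folds to 1 gives
  the distributional null.

What the generator deliberately does **not** emulate: transcriptome-wide
co-expression structure, doublets and ambient RNA, multi-spot glomeruli,
segmentation errors in zone annotation, and platform artifacts such as
spot-to-spot bleed. Passing tests therefore demonstrate that the
algorithms recover planted composition and response structure under
realistic count noise — not that they are robust to every artifact of real
Visium data.

## Numerical conventions

* Fisher's exact test includes tables whose probability is within a 1e-7
  relative slack of the observed table's, the conventional guard against
  floating-point ties; a zero margin returns p = 1 with a warning.
* The Wilcoxon rank-sum test uses the exact permutation distribution when
  the smaller group has ≤ 8 observations and the pooled values are
  tie-free, otherwise the normal approximation with tie and continuity
  correction.
* Skewness uses the population-moment form with no small-sample bias
  correction; constant vectors yield a flagged NA, never NaN propagation.
* Deconvolution residual norms are reported per spot; coefficients that
  sum to zero mark the spot degenerate.
* All "top k" selections break ties deterministically by identifier, so
  reruns are bit-identical.
* Fraction normalization divides raw counts, not variance-stabilized
  ones: the variance-stabilization step of the original workflow is out of
  scope here, and the subsequent total-count rescaling absorbs the
  library-size component of the difference. The choice is recorded in the
  `NormalizedMatrix` metadata.

## Problem sizes used by the test-suite simulations

Unit tests run a reduced study (220-gene panel, 3 markers per type, 16×30
lattice, one sample per condition). The acceptance-style end-to-end checks
use the full default conditions: 20 replicate studies for the
heterogeneity recovery (plus 100 null replicates for type-I control), 50
replicates for the adjacency analysis and its spatial null, 10 replicates
of the 1,000-spot deconvolution benchmark at dispersion 0.5, and full
enumeration oracles for the exact tests (every 2×2 table with total ≤ 40;
every tie-free Wilcoxon group size up to 8). These sizes are the package's
own benchmark definition and keep a complete run in the minutes range on a
laptop.

## Known limitations

* NNLS on a mean signature is a transparent stand-in for support-vector
  deconvolution; numerical agreement with CIBERSORTx is not claimed, only
  the same linear-mixture model.
* Fraction-normalized values divide by an *estimated* fraction, so error
  in $F_j$ propagates multiplicatively into $NC_{ij}$; the `min_fraction`
  threshold bounds that error but also censors low-fraction spots.
* The KS p-values are anti-conservative (estimated parameters, ties in
  count data).
* The responder threshold (default 0) is a design choice, not an
  estimate; any claimed responder proportion depends on it.
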