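# spothet

Spot-level heterogeneity analysis for spatial transcriptomics of drug
response.

## What it is for

Each spot of a Visium-style array captures a *mixture* of cells, so the
response of a minority population — renin-producing juxtaglomerular (JG)
cells at the glomerular vascular pole, or macula densa cells of the thick
ascending limb (TAL-2) — is diluted and confounded with composition.
`spothet` is for analysts who want to attribute spot expression to a
target cell type and then ask whether the drug response of that type is
*uniform or heterogeneous* across anatomical units (here: glomeruli of
the kidney under an angiotensin-receptor blocker, where Cox-2/*Ptgs2*
rises in macula densa and renin/*Ren* rises in JG cells).

The core quantities:

* **Cell fractions by NNLS deconvolution.** With signature matrix `S`
  (genes × types, counts-per-10k means of a labelled single-cell
  reference) and a spot's counts-per-10k vector `y`, solve
  `min ||S f − y||₂ s.t. f ≥ 0` and renormalize `f` to the simplex.
* **Fraction-normalized expression.** For target-type fraction `F_j` in
  spot `j` (kept when `F_j ≥ 0.05`):
  `NC_ij = C_ij / F_j`, followed by per-spot total-count scaling to
  10,000 and (where appropriate) `log1p`.
* **Hex adjacency statistics.** A spot's 6 hexagonal neighbours sit at
  array-coordinate offsets (0, ±2), (±1, ±1); TAL-1/TAL-2
  dominant-score groups are tested for glomerulus adjacency with Fisher's
  exact test (two-sided hypergeometric tail mass).
* **Heterogeneity screen.** Per gene over JG-normalized glomerulus
  spots: skewness `g₁ = m₃ / m₂^{3/2}`, a Kolmogorov–Smirnov test
  against the moment-fitted Gaussian ("random response" null), a
  mean > 0.01 filter, a top-5% skewness flag; responder classification and
  the per-sample top-25% "high-responding" spot set, with Wilcoxon/BH
  differential expression against the remaining spots.

A fully tested synthetic-study generator (`SimConfig()`,
`simulateStudy()`) plants zonated mixtures, single-spot glomeruli,
adjacent macula densa spots and condition-dependent inductions, so every
claim the pipeline makes can be checked against known truth.

## Worked example

```r
library(spothet)

cfg   <- SimConfig(seed = 1)          # scaled-down 2-condition renal study
study <- simulateStudy(cfg)           # reference + lattice + spot counts
res   <- runPipeline(PipelineConfig(), study$reference, study$spot_counts,
                     study$lattice)

res$adjacency$table
#>       adjacent not_adjacent
#> TAL-1      454          254
#> TAL-2      247            0
res$adjacency$p_value                 # 3.78e-40
```

Every TAL-2-dominant (macula densa) cortical spot sits next to a
glomerulus, against a 64% background rate for TAL-1 spots — the planted
anatomy, recovered from the estimated fractions alone.

```r
res$responder_test$table
#>      Responding Non-responding
#> Ctrl         59             61
#> Losa        107             13
res$responder_test$p_value            # 1.37e-11
```

Treated samples have far more *Ren*-responding glomerulus spots
(107/120 vs 59/120).

```r
head(res$gene_stats[, c("gene_id", "mean", "skewness", "ks_p", "top_skew")], 3)
#>      gene_id  mean skewness     ks_p top_skew
#> 1        Ren 4.460     2.40 2.22e-13     TRUE
#> 87  gene0007 0.714     1.81 1.32e-38     TRUE
#> 146 gene0066 2.061     1.54 7.12e-10     TRUE
```

*Ren* tops the skewness ranking (2.40, KS rejects the Gaussian null)
while the housekeeping gene *Rplp0* stays symmetric (skewness 0.75, KS
p = 0.37): the JG response is heterogeneous across glomeruli, not a
uniform shift. The planted high-responder glomeruli drive it —
`res$high_responding` recovers them (Jaccard ≈ 0.76 against the planted
set for this seed) and *Ren* ranks first in the high-responder
differential expression table (adjusted p ≈ 4e-16).

A thin CLI over the same functions lives in `inst/scripts/spothet.R`
(`simulate` and `run` subcommands).

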