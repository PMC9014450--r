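# Shared fixtures, all generated in code.

# A reduced simulation for unit tests (full study defaults are exercised in
# the acceptance suite).
smallConfig <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 220L, n_markers_per_type = 3L, n_cells_per_type = 30L,
         lattice_rows = 16L,
         lattice_cols = 30L, n_glomeruli = 10L, n_samples = 1L,
         depth_mean_umi = 2000, seed = seed),
    list(...))
  do.call(SimConfig, args)
}

# Tiny hand-built lattice: one sample, all cortex, explicit coordinates.
toyLattice <- function(coords, glom = rep(NA_character_, nrow(coords)),
                       sample_id = "S1", condition = "Ctrl") {
  SpotLattice(data.frame(
    spot_id = paste0("s", seq_len(nrow(coords))),
    array_row = coords[, 1], array_col = coords[, 2],
    zone = "Cortex", glomerulus_id = glom,
    sample_id = sample_id, condition = condition,
    stringsAsFactors = FALSE))
}

# Six-cell QC fixture violating each filter bound once (sparse, 5200 genes):
#   c_lowgenes  150 detected                      -> out (< 200 genes)
#   c_highgenes 5100 detected                     -> out (> 5000 genes)
#   c_highumi   30000 total UMIs                  -> out (not under 30000)
#   c_mito      mito fraction exactly 0.40        -> out (not under 0.40)
#   c_ok1, c_ok2 inside all bounds                -> retained
qcFixture <- function() {
  n_genes <- 5200L
  genes <- c(sprintf("Mt-%d", 1:10), sprintf("g%04d", seq_len(n_genes - 10)))
  cells <- c("c_lowgenes", "c_highgenes", "c_highumi", "c_mito",
             "c_ok1", "c_ok2")
  entry <- function(cell, gene_idx, value)
    data.frame(i = gene_idx, j = match(cell, cells), x = value)
  tri <- rbind(
    entry("c_lowgenes", 11:160, 5),
    entry("c_highgenes", 11:5110, 1),
    entry("c_highumi", 11:310, 100),
    entry("c_mito", 1:10, 40),          # 400 mito UMIs
    entry("c_mito", 11:310, 2),         # 600 other UMIs -> frac = 0.40
    entry("c_ok1", 11:310, 10),
    entry("c_ok2", 11:1010, 3))
  m <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(n_genes, length(cells)),
                            dimnames = list(genes, cells))
  CountMatrix(m, "single_cell")
}

# Independent enumeration oracle for the two-sided Fisher exact p of a 2x2
# table: hypergeometric probabilities from choose() ratios.
fisherEnumOracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  m <- a + cc; n <- b + dd; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# Independent enumeration oracle for the two-sided exact Wilcoxon rank-sum
# p-value of tie-free samples.
wilcoxEnumOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  ws <- colSums(matrix(seq_len(nx + ny)[sets], nrow = nx)) -
    nx * (nx + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Map selected high-responding spots (treated samples) to glomerulus ids
# and compute the Jaccard index against the planted set.
jaccardPlanted <- function(hi, lattice, truth) {
  d <- spotData(lattice)
  sel <- hi$spot_id[grepl("^Losa", hi$sample_id)]
  sel_gloms <- stats::na.omit(d$glomerulus_id[match(sel, d$spot_id)])
  planted <- unlist(truth@high_responders, use.names = FALSE)
  length(intersect(sel_gloms, planted)) / length(union(sel_gloms, planted))
}
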