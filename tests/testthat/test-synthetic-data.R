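test_that("simulation is deterministic given config and seed", {
  cfg <- smallConfig(seed = 11)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(counts(a$reference), counts(b$reference))
  expect_identical(counts(a$spot_counts), counts(b$spot_counts))
  expect_identical(spotData(a$lattice), spotData(b$lattice))
  expect_identical(fractions(a$truth@fractions), fractions(b$truth@fractions))
  expect_identical(a$truth@high_responders, b$truth@high_responders)
  c2 <- simulateStudy(smallConfig(seed = 12))
  expect_false(identical(counts(a$spot_counts), counts(c2$spot_counts)))
})

test_that("reference cell means converge to the stored base means as dispersion vanishes", {
  cfg <- SimConfig(n_genes = 60L, n_markers_per_type = 3L, n_cells_per_type = 1000L,
                   nb_dispersion = 0, n_samples = 1L, seed = 5)
  ref <- makeReference(cfg)
  expected <- S4Vectors::metadata(ref)$expected_profiles
  labels <- SummarizedExperiment::colData(ref)$cell_type
  for (t in c("JG", "TAL-2", "PT")) {
    mu <- expected[, t]
    obs <- Matrix::rowMeans(counts(ref)[, labels == t])
    big <- mu >= 1
    expect_true(all(abs(obs[big] - mu[big]) / mu[big] < 0.05))
  }
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(SimConfig(n_cells_per_type = 0), "n_cells_per_type")
  expect_error(SimConfig(n_genes = -5), "n_genes")
  expect_error(SimConfig(effect_ren_fold = 0.5), "effect_ren_fold")
  expect_error(SimConfig(high_responder_frac = 1.5), "high_responder_frac")
  expect_error(SimConfig(glomerulus_profile = c(Podo = 0.5, MC = 0.3)),
               "glomerulus_profile")
  expect_error(SimConfig(macula_densa_type = "nope"), "macula_densa_type")
})

test_that("zone bands partition lattice rows in order", {
  cfg <- SimConfig(lattice_rows = 40L, n_samples = 1L, n_genes = 60L, n_markers_per_type = 3L,
                   n_cells_per_type = 5L, seed = 2)
  d <- spotData(makeTissue(cfg)$lattice)
  d <- d[d$sample_id == "Ctrl_1", ]
  expect_setequal(d$zone[d$array_row <= 9], "Cortex")
  expect_setequal(d$zone[d$array_row >= 10 & d$array_row <= 19], "OMOS")
  expect_setequal(d$zone[d$array_row >= 20 & d$array_row <= 29], "OMIS")
  expect_setequal(d$zone[d$array_row >= 30], "IM")
})

test_that("every macula densa spot is a hex neighbour of a glomerulus", {
  st <- makeTissue(smallConfig(seed = 21))
  d <- spotData(st$lattice)
  glom <- d$spot_id[!is.na(d$glomerulus_id)]
  for (md in st$truth@md_spots)
    expect_true(any(hexNeighbors(st$lattice, md) %in% glom))
  # null layout drops the guarantee
  st0 <- makeTissue(smallConfig(seed = 21, md_adjacent = FALSE))
  d0 <- spotData(st0$lattice)
  glom0 <- d0$spot_id[!is.na(d0$glomerulus_id)]
  adj <- vapply(st0$truth@md_spots,
                function(s) any(hexNeighbors(st0$lattice, s) %in% glom0),
                logical(1))
  expect_false(all(adj))
})

test_that("planted high-responders are a quarter of treated glomeruli and exist", {
  cfg <- SimConfig(n_glomeruli = 40L, high_responder_frac = 0.25,
                   n_samples = 1L, n_genes = 60L, n_markers_per_type = 3L, n_cells_per_type = 5L,
                   seed = 3)
  st <- makeTissue(cfg)
  hr <- st$truth@high_responders
  expect_named(hr, "Losa_1")
  expect_length(hr$Losa_1, 10L)
  expect_true(all(hr$Losa_1 %in% spotData(st$lattice)$glomerulus_id))
})

test_that("true fraction rows lie on the simplex", {
  st <- makeTissue(smallConfig(seed = 7))
  f <- fractions(st$truth@fractions)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(abs(rowSums(f) - 1) < 1e-9))
})

test_that("impossible glomerulus placement is a configuration error", {
  expect_error(
    makeTissue(smallConfig(seed = 1, lattice_rows = 8L, lattice_cols = 8L,
                           n_glomeruli = 10L)),
    "n_glomeruli")
})

test_that("a pure single-type spot has the type's depth-scaled expected profile", {
  cfg <- smallConfig(seed = 9)
  B <- spothet:::.geneBaseMeans(cfg)
  fr <- matrix(0, 400, ncol(B), dimnames = list(NULL, colnames(B)))
  fr[, "PT"] <- 1
  cm <- makeMixtureCounts(B, fr, depth_mean_umi = 2000, nb_dispersion = 0,
                          seed = 4)
  mu <- 2000 * B[, "PT"] / sum(B[, "PT"])
  obs <- Matrix::rowMeans(counts(cm))
  big <- mu >= 5           # Poisson SE over 400 spots is ~2% here
  expect_true(all(abs(obs[big] - mu[big]) / mu[big] < 0.1))
})

test_that("null effects leave treated and control response counts exchangeable", {
  cfg <- smallConfig(seed = 31, effect_ptgs2_fold = 1,
                     effect_ren_base_fold = 1, effect_ren_fold = 1,
                     n_samples = 2L)
  st <- simulateStudy(cfg)
  d <- spotData(st$lattice)
  glom <- !is.na(d$glomerulus_id)
  ren <- as.numeric(counts(st$spot_counts)["Ren", d$spot_id[glom]])
  cond <- d$condition[glom]
  # same NB distribution on both arms: rank-sum should not separate them
  p <- wilcoxonRankSum(ren[cond == "Losa"], ren[cond == "Ctrl"])$p_value
  expect_gt(p, 0.001)
})

test_that("planted Ren induction separates high-responder from other glomeruli", {
  ps <- vapply(1:10, function(i) {
    cfg <- smallConfig(seed = 100 + i, n_glomeruli = 20L, n_samples = 1L)
    st <- simulateStudy(cfg)
    d <- spotData(st$lattice)
    g <- d[!is.na(d$glomerulus_id) & d$condition == "Losa", ]
    hr <- g$glomerulus_id %in% unlist(st$truth@high_responders)
    ren <- as.numeric(counts(st$spot_counts)["Ren", g$spot_id])
    stats::wilcox.test(ren[hr], ren[!hr], alternative = "greater",
                       exact = FALSE)$p.value
  }, numeric(1))
  expect_lt(median(ps), 0.05)
})

test_that("config round-trips through YAML", {
  cfg <- smallConfig(seed = 77, effect_ren_fold = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_genes = cfg@n_genes,
                        n_markers_per_type = cfg@n_markers_per_type,
                        n_cells_per_type = cfg@n_cells_per_type,
                        lattice_rows = cfg@lattice_rows,
                        lattice_cols = cfg@lattice_cols,
                        n_glomeruli = cfg@n_glomeruli,
                        n_samples = cfg@n_samples,
                        depth_mean_umi = cfg@depth_mean_umi, seed = 77,
                        effect_ren_fold = 4), path)
  cfg2 <- readSimConfig(path)
  expect_equal(cfg2@effect_ren_fold, 4)
  expect_identical(counts(makeReference(cfg)), counts(makeReference(cfg2)))
  writeLines("n_genes: 10\nbogus_field: 1", path)
  expect_error(readSimConfig(path), "bogus_field")
})
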