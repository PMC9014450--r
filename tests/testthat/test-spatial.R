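# A 5x10 single-sample block of cortex spots with full parity coverage.
fullBlock <- function() {
  coords <- do.call(rbind, lapply(0:4, function(r)
    cbind(r, seq(r %% 2, 9, by = 2))))
  toyLattice(coords)
}

test_that("hex neighbourhoods follow the Visium offset convention", {
  lat <- fullBlock()
  d <- spotData(lat)
  id_at <- function(r, c) d$spot_id[d$array_row == r & d$array_col == c]
  # interior spot: all six neighbours
  nb <- hexNeighbors(lat, id_at(2, 4))
  expect_length(nb, 6L)
  expect_setequal(nb, c(id_at(2, 2), id_at(2, 6), id_at(1, 3), id_at(1, 5),
                        id_at(3, 3), id_at(3, 5)))
  # corner spot (0,0): only (0,2) and (1,1)
  expect_setequal(hexNeighbors(lat, id_at(0, 0)),
                  c(id_at(0, 2), id_at(1, 1)))
  expect_error(hexNeighbors(lat, "nope"), "unknown spot")
})

test_that("spots in different samples are never neighbours", {
  coords <- rbind(c(0, 0), c(0, 2))
  two <- rbind(
    data.frame(spot_id = c("a1", "a2"), array_row = 0L,
               array_col = c(0L, 2L), zone = "Cortex",
               glomerulus_id = NA_character_, sample_id = "S1",
               condition = "Ctrl"),
    data.frame(spot_id = c("b1", "b2"), array_row = 0L,
               array_col = c(0L, 2L), zone = "Cortex",
               glomerulus_id = NA_character_, sample_id = "S2",
               condition = "Losa"))
  lat <- SpotLattice(two)
  expect_identical(hexNeighbors(lat, "a1"), "a2")
  expect_false("b2" %in% hexNeighbors(lat, "a1"))
})

test_that("neighbour relation is symmetric and irreflexive", {
  lat <- fullBlock()
  for (s in sample(spotIds(lat), 10)) {
    nb <- hexNeighbors(lat, s)
    expect_false(s %in% nb)
    for (t in nb) expect_true(s %in% hexNeighbors(lat, t))
  }
})

test_that("dominant-score classification follows the strict-greater rule", {
  expect_identical(classifyDominant(0.3, 0.2), "GroupA")
  expect_identical(classifyDominant(0.2, 0.2), "GroupB")  # tie -> B
  expect_identical(classifyDominant(0, 0), "Unclassified")
  expect_identical(classifyDominant(c(0.3, 0.1, 0), c(0.2, 0.5, 0)),
                   c("GroupA", "GroupB", "Unclassified"))
  expect_error(classifyDominant(-0.1, 0.2), "non-negative")
})

test_that("adjacency contingency counts spots next to glomeruli per group", {
  # row 0: s1 (glomerulus), s2 adjacent to it; s3 far away, s4 unclassified
  coords <- rbind(c(0, 0), c(0, 2), c(0, 8), c(2, 8))
  lat <- toyLattice(coords, glom = c("S1_g01", NA, NA, NA))
  labels <- c(s2 = "GroupB", s3 = "GroupA", s4 = "Unclassified")
  tab <- adjacencyContingency(labels, "s1", lat)
  expect_equal(tab, matrix(c(0L, 1L, 1L, 0L), 2,
                           dimnames = list(c("GroupA", "GroupB"),
                                           c("adjacent", "not_adjacent"))))
  # no glomeruli: adjacent column all zero
  tab0 <- adjacencyContingency(labels, character(0), lat)
  expect_true(all(tab0[, "adjacent"] == 0))
  expect_error(adjacencyContingency(c(s2 = "Unclassified"), "s1", lat),
               "no eligible")
})

test_that("Fisher exact p equals the hypergeometric tail mass", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  res <- fisherExact2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)
  set.seed(5)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisherExact2x2(tab)$p_value, fisherEnumOracle(tab),
                 tolerance = 1e-10)
    expect_equal(fisherExact2x2(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_warning(p0 <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2))$p_value,
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    p <- fisherExact2x2(tab)$p_value
    expect_equal(fisherExact2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisherExact2x2(tab[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("planted macula densa spots enrich the TAL-2 group next to glomeruli", {
  cfg <- smallConfig(seed = 55)
  st <- simulateStudy(cfg)
  sig <- buildSignature(st$reference)
  d <- spotData(st$lattice)
  cortical <- d$spot_id[d$zone == "Cortex"]
  fr <- estimateFractions(st$spot_counts[, cortical], sig)
  f <- fractions(fr)
  glom <- d$spot_id[!is.na(d$glomerulus_id)]
  lab <- classifyDominant(f[, "TAL-1"], f[, "TAL-2"],
                          labels = c("TAL-1", "TAL-2"))
  names(lab) <- rownames(f)
  tab <- adjacencyContingency(lab, glom, st$lattice)
  res <- fisherExact2x2(tab)
  # odds of adjacency higher in the TAL-2 group
  odds <- (tab["TAL-2", 1] / tab["TAL-2", 2]) /
          (tab["TAL-1", 1] / tab["TAL-1", 2])
  expect_gt(odds, 1)
  expect_lt(res$p_value, 0.01)
})
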