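test_that("count matrices round-trip through the MatrixMarket triplet", {
  m <- matrix(c(0, 5, 2, 0, 1, 3), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cm <- CountMatrix(m, "spatial")
  dir <- withr::local_tempdir()
  writeCounts(cm, dir)
  back <- readCounts(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                     file.path(dir, "barcodes.tsv"), modality = "spatial")
  expect_equal(as.matrix(counts(back)), m)
  expect_identical(rownames(back), rownames(cm))
  expect_identical(colnames(back), colnames(cm))
  expect_identical(modality(back), "spatial")
})

test_that("empty (0-gene) matrices still round-trip", {
  m <- matrix(numeric(0), nrow = 0, ncol = 2,
              dimnames = list(character(0), c("s1", "s2")))
  dir <- withr::local_tempdir()
  writeCounts(CountMatrix(m, "spatial"), dir)
  back <- readCounts(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                     file.path(dir, "barcodes.tsv"))
  expect_equal(dim(back), c(0L, 2L))
})

test_that("malformed count input is rejected, not coerced", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  dir <- withr::local_tempdir()
  writeCounts(CountMatrix(m, "spatial"), dir)
  # barcode list longer than the declared column count
  writeLines(c("s1", "s2", "s3"), file.path(dir, "barcodes.tsv"))
  expect_error(readCounts(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "barcodes.tsv")),
               "3 barcodes.*2 columns")
  writeLines(c("s1", "s2"), file.path(dir, "barcodes.tsv"))
  # negative entry
  mm <- readLines(file.path(dir, "matrix.mtx"))
  mm[length(mm)] <- "2 2 -4"
  writeLines(mm, file.path(dir, "matrix.mtx"))
  expect_error(readCounts(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "barcodes.tsv")),
               "non-negative")
  # duplicate gene ids refuse to construct
  expect_error(CountMatrix(matrix(1:4, 2, dimnames = list(c("g1", "g1"),
                                                          c("s1", "s2"))),
                           "spatial"),
               "duplicate gene")
})

test_that("lattices round-trip through CSV and are validated", {
  lat <- toyLattice(rbind(c(0, 0), c(1, 1)), glom = c("S1_g01", NA))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLattice(lat, path)
  back <- readLattice(path)
  expect_identical(spotData(back), spotData(lat))

  bad <- spotData(lat)
  bad$array_col[1] <- 3L  # row 0 / col 3: parity mismatch
  badpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, badpath, row.names = FALSE)
  expect_error(readLattice(badpath), "parity.*s1")

  bad2 <- spotData(lat)
  bad2$zone[2] <- "Medulla"
  utils::write.csv(bad2, badpath, row.names = FALSE)
  expect_error(readLattice(badpath), "Cortex, OMOS, OMIS, IM")

  bad3 <- rbind(spotData(lat), spotData(lat)[1, ])
  bad3$spot_id[3] <- "s3"
  utils::write.csv(bad3, badpath, row.names = FALSE)
  expect_error(readLattice(badpath), "duplicate")
})

test_that("the full pipeline runs, writes reports, and reruns identically", {
  cfg <- smallConfig(seed = 41, n_samples = 2L)
  st <- simulateStudy(cfg)
  pcfg <- PipelineConfig(min_genes = 50L, max_genes = 5000L, seed = 41)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  res1 <- runPipeline(pcfg, st$reference, st$spot_counts, st$lattice, dir1)
  res2 <- runPipeline(pcfg, st$reference, st$spot_counts, st$lattice, dir2)
  for (f in c("fractions.tsv", "adjacency.tsv", "gene_dist_stats.tsv",
              "responders.tsv", "run_log.txt"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  expect_s4_class(res1$fractions, "FractionMatrix")
  expect_true(startsWith(readLines(file.path(dir1, "fractions.tsv"))[1], "#"))
})

test_that("stage failures name the failing stage", {
  cfg <- smallConfig(seed = 42)
  st <- simulateStudy(cfg)
  ref_unlabelled <- CountMatrix(counts(st$reference), "single_cell")
  expect_error(
    runPipeline(PipelineConfig(min_genes = 50L), ref_unlabelled,
                st$spot_counts, st$lattice),
    "stage 'signature'")
})
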