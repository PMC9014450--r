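test_that("skewness evaluates the population-moment formula", {
  expect_equal(sampleSkewness(c(1, 2, 3)), 0)
  expect_equal(sampleSkewness(c(0, 0, 0, 1)), 2 / sqrt(3), tolerance = 1e-12)
  set.seed(2)
  x <- rexp(50)
  expect_equal(sampleSkewness(2 * x + 3), sampleSkewness(x), tolerance = 1e-12)
  expect_equal(sampleSkewness(-2 * x + 3), -sampleSkewness(x),
               tolerance = 1e-12)
  expect_true(is.na(sampleSkewness(rep(4, 10))))
  expect_error(sampleSkewness(c(1, 2)), "n >= 3")
  s <- geneDistributionStats(x)
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sd(x))
})

test_that("skewness matches an independent moment oracle", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(10:200, 1)) + rexp(1) * rlnorm(1)
    expect_equal(sampleSkewness(x), e1071::skewness(x, type = 1),
                 tolerance = 1e-12)
  }
})

test_that("KS Gaussian test accepts near-perfect normal grids and rejects skewed data", {
  n <- 100
  x <- qnorm((seq_len(n) - 0.5) / n)
  res <- ksGaussianTest(x)
  expect_lt(res$statistic, 0.01)
  expect_gt(res$p_value, 0.99)
  expect_error(ksGaussianTest(c(1, 2, 3)), "n >= 5")
  expect_error(ksGaussianTest(rep(1, 10)), "sd = 0")
  # strongly right-skewed: reject in nearly all seeds
  rej <- vapply(1:20, function(i) {
    set.seed(400 + i)
    ksGaussianTest(rexp(200))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  # agrees with the reference implementation on tie-free data
  set.seed(12)
  y <- rnorm(150) + rexp(150)
  ref <- suppressWarnings(stats::ks.test(y, "pnorm", mean(y), sd(y),
                                         exact = FALSE))
  mine <- ksGaussianTest(y)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("the skewness screen filters by mean and flags exactly the top fraction", {
  set.seed(44)
  n_spot <- 40
  v <- matrix(rlnorm(100 * n_spot), 100,
              dimnames = list(sprintf("g%03d", 1:100),
                              sprintf("s%02d", 1:n_spot)))
  low <- matrix(0.0001, 3, n_spot,
                dimnames = list(c("low1", "low2", "low3"), colnames(v)))
  nc <- NormalizedMatrix(rbind(v, low))
  res <- skewnessScreen(nc, min_mean = 0.01, top_frac = 0.05)
  expect_equal(nrow(res), 100)           # low-mean genes excluded
  expect_false(any(startsWith(res$gene_id, "low")))
  expect_equal(sum(res$top_skew), 5)     # ceiling(0.05 * 100)
  expect_true(all(res$skewness[res$top_skew] >=
                  max(res$skewness[!res$top_skew])))
  # ties broken by gene id: duplicate a column of equal-skew genes
  tied <- v[rep(1, 30), ]
  rownames(tied) <- sprintf("t%02d", 1:30)
  res2 <- skewnessScreen(NormalizedMatrix(tied), top_frac = 0.1)
  expect_identical(res2$gene_id[res2$top_skew], sprintf("t%02d", 1:3))
  expect_warning(skewnessScreen(NormalizedMatrix(v[1:10, ])), "quantile")
})

test_that("a planted long-tailed gene is flagged among symmetric genes", {
  hits <- vapply(1:20, function(i) {
    set.seed(600 + i)
    base <- matrix(rnorm(99 * 60, mean = 10), 99)
    tail_gene <- rnorm(60, 10)
    tail_gene[sample(60, 9)] <- 40       # 4-fold right tail in 15% of spots
    v <- rbind(base, planted = tail_gene)
    v[v < 0.02] <- 0.02
    rownames(v) <- c(sprintf("g%03d", 1:99), "planted")
    colnames(v) <- sprintf("s%02d", 1:60)
    res <- skewnessScreen(NormalizedMatrix(v), top_frac = 0.05)
    res$top_skew[res$gene_id == "planted"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("responder classification uses a strict threshold", {
  expect_identical(classifyResponders(c(0, 0.5, 1), 0),
                   c("Non-responding", "Responding", "Responding"))
  expect_identical(unique(classifyResponders(rep(0, 5), 0)),
                   "Non-responding")
  expect_error(classifyResponders(c(1, NA)), "NA")
})

test_that("the responder condition test needs both conditions and detects enrichment", {
  tbl <- data.frame(
    spot_id = sprintf("s%02d", 1:40),
    sample_id = "x",
    condition = rep(c("Ctrl", "Losa"), each = 20),
    glomerulus_id = NA_character_,
    value = c(rep(0, 20), rep(5, 20)),
    responder = c(rep("Non-responding", 20), rep("Responding", 20)),
    high_responding = FALSE)
  res <- responderConditionTest(tbl)
  expect_equal(res$p_value, 2 / choose(40, 20), tolerance = 1e-12)
  expect_error(responderConditionTest(tbl[tbl$condition == "Losa", ]),
               "both conditions")
  # identical proportions: no signal
  tbl2 <- tbl
  tbl2$responder <- rep(c("Responding", "Non-responding"), 20)
  expect_gt(responderConditionTest(tbl2)$p_value, 0.5)
})

test_that("high-responder selection takes ceiling(frac*n) per sample with id tie-break", {
  v <- setNames(as.numeric(1:8), sprintf("s%d", 1:8))
  hi <- selectHighResponding(v, rep("A", 8), 0.25)
  expect_setequal(hi$spot_id, c("s8", "s7"))
  expect_equal(nrow(selectHighResponding(v, rep("A", 8), 1)), 8L)
  # independent selection within samples
  v2 <- setNames(c(1, 2, 3, 100, 4, 5), sprintf("s%d", 1:6))
  samp <- c("A", "A", "A", "A", "B", "B")
  hi2 <- selectHighResponding(v2, samp, 0.25)
  expect_setequal(hi2$spot_id[hi2$sample_id == "A"], "s4")
  expect_setequal(hi2$spot_id[hi2$sample_id == "B"], "s6")
  # per-sample sizes are exactly sum of ceilings
  expect_equal(nrow(hi2), ceiling(0.25 * 4) + ceiling(0.25 * 2))
  # ties broken by spot id
  v3 <- setNames(rep(1, 4), c("d", "c", "b", "a"))
  hi3 <- selectHighResponding(v3, rep("A", 4), 0.5)
  expect_setequal(hi3$spot_id, c("a", "b"))
})
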