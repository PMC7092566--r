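test_that("computeSizeFactors matches the median-of-ratios definition", {
  # identical samples -> all factors 1
  m <- matrix(rep(c(5L, 10L, 20L), 3), 3, dimnames = list(
    c("g1", "g2", "g3"), c("a", "b", "c")))
  expect_equal(unname(computeSizeFactors(m)), rep(1, 3))

  # doubling forces factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(A = c(10L, 20L), B = c(20L, 40L))
  rownames(m2) <- c("g1", "g2")
  expect_equal(unname(computeSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)))

  # random matrix equals an independent brute-force computation, and the
  # DESeq2 implementation of the same convention (odd gene count keeps the
  # ratio-scale and log-scale medians identical)
  set.seed(33)
  m3 <- matrix(rpois(306, 50) + 1L, 51, 6,
               dimnames = list(sprintf("g%02d", 1:51), letters[1:6]))
  geo <- apply(m3, 1, function(x) prod(x)^(1 / length(x)))
  brute <- apply(m3, 2, function(col) median(col / geo))
  expect_equal(unname(computeSizeFactors(m3)), unname(brute),
               tolerance = 1e-10)
  expect_equal(unname(computeSizeFactors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-10)

  # no gene expressed everywhere -> advisory error
  m4 <- cbind(A = c(0L, 5L), B = c(5L, 0L))
  rownames(m4) <- c("g1", "g2")
  expect_error(computeSizeFactors(m4), "filter")
})

test_that("tpm normalizes per length and sums to one million", {
  m <- matrix(c(10L, 90L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  out <- tpm(m, c(g1 = 1000, g2 = 9000))
  expect_equal(unname(out[, 1]), c(5e5, 5e5))

  # all-zero sample yields zero TPM by convention
  m0 <- cbind(a = c(0L, 0L), b = c(3L, 1L))
  rownames(m0) <- c("g1", "g2")
  out0 <- tpm(m0, c(g1 = 100, g2 = 100))
  expect_equal(unname(out0[, "a"]), c(0, 0))

  # random matrix: columns sum to 1e6
  set.seed(5)
  m1 <- matrix(rpois(200, 40), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), letters[1:4]))
  lens <- stats::runif(50, 300, 5000)
  names(lens) <- rownames(m1)
  expect_equal(unname(colSums(tpm(m1, lens))), rep(1e6, 4), tolerance = 1e-9)

  expect_error(tpm(m, c(g1 = 0, g2 = 100)), "positive")
})

test_that("vstTransform is log2(normalized + 1) and flattens the NB trend", {
  m <- cbind(a = c(0L, 7L), b = c(0L, 7L))
  rownames(m) <- c("g1", "g2")
  v <- vstTransform(m, sizeFactors = c(a = 1, b = 1))
  expect_equal(unname(v[, 1]), c(0, 3))

  # sd-vs-mean slope over the top half of expression drops >= 5x
  d <- SimulationDesign(nGenes = 3000L, nTumorsMut = 20L, nTumorsWt = 0L,
                        nNormals = 0L, dispersion = 0.1, fracDeShared = 0,
                        fracDeMutOnly = 0, fracDeWtOnly = 0,
                        fracOpposite = 0, effectLog2fc = 0,
                        hotspots = noHotspots(), seed = 6L)
  cnt <- simulateCounts(d)$counts
  v2 <- vstTransform(cnt)
  mu <- rowMeans(cnt)
  top <- mu >= median(mu)
  slope <- function(x) {
    s <- apply(x[top, ], 1, sd)
    m <- rowMeans(x[top, ])
    unname(coef(lm(s ~ m))[2])
  }
  expect_gt(abs(slope(cnt)) / abs(slope(v2)), 5)
})

test_that("bhAdjust equals the brute-force step-up oracle", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (rep in 1:5) {
    p <- runif(1000)
    q <- bhAdjust(p)
    expect_equal(q, oracleBH(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("callDE applies the study thresholds with inclusive boundary", {
  expect_identical(callDE(1.0, 0.009), "up")
  expect_identical(callDE(0.99, 1e-10), "ns")
  expect_identical(callDE(-1.2, 0.02), "ns")
  expect_identical(callDE(-1.0, 0.0099), "down")
  expect_identical(callDE(c(2, -2, 0), c(0.001, 0.5, 0.001)),
                   c("up", "ns", "ns"))
})

test_that("nbWaldTest is calibrated on null data and recovers planted DE", {
  # zero-effect: small mean |log2fc| and near-nominal type-I rate
  d0 <- testDesign(nGenes = 5000L, nTumorsMut = 8L, nTumorsWt = 0L,
                   nNormals = 5L, seed = 19L)
  sim0 <- simulateCounts(d0)
  de0 <- nbWaldTest(sim0$counts, sim0$samples, "tumor", "normal")
  expect_lt(mean(abs(de0$log2FoldChange)), 0.25)
  expect_gt(mean(de0$pvalue < 0.05), 0.02)
  expect_lt(mean(de0$pvalue < 0.05), 0.08)

  # planted log2FC 2: recovered with high sensitivity and small bias
  d1 <- testDesign(nGenes = 4000L, nTumorsMut = 8L, nTumorsWt = 0L,
                   nNormals = 5L, fracDeMutOnly = 0.05, seed = 23L)
  sim1 <- simulateCounts(d1)
  de1 <- nbWaldTest(sim1$counts, sim1$samples, "tumor", "normal")
  tr <- sim1$truth$genes
  up <- intersect(tr$gene_id[tr$status == "de_mut" & tr$sign == 1],
                  rownames(de1))
  dn <- intersect(tr$gene_id[tr$status == "de_mut" & tr$sign == -1],
                  rownames(de1))
  expect_gt(mean(de1[up, "call"] == "up"), 0.9)
  expect_gt(mean(de1[dn, "call"] == "down"), 0.8)  # lower counts, harder
  expect_lt(mean(abs(de1[up, "log2FoldChange"] - 2)), 0.3)

  # group with fewer than 2 samples is an error
  one <- sim1$samples[sim1$samples$tissue == "tumor", ][1, ]
  few <- rbind(one, sim1$samples[sim1$samples$tissue == "normal", ])
  expect_error(nbWaldTest(sim1$counts[, few$sample_id], few,
                          "tumor", "normal"), "at least 2")
})

test_that("nbWaldTest is invariant to column order and library rescaling", {
  d <- testDesign(nGenes = 1000L, fracDeMutOnly = 0.05, seed = 31L)
  sim <- simulateCounts(d)
  de1 <- nbWaldTest(sim$counts, sim$samples, "tumor", "normal")
  perm <- sample(ncol(sim$counts))
  de2 <- nbWaldTest(sim$counts[, perm], sim$samples, "tumor", "normal")
  expect_equal(de1$log2FoldChange, de2[rownames(de1), "log2FoldChange"],
               tolerance = 1e-12)

  # tripling one sample's library is absorbed by the size factors
  scaled <- sim$counts
  scaled[, 1] <- as.integer(round(scaled[, 1] * 3))
  de3 <- nbWaldTest(scaled, sim$samples, "tumor", "normal")
  common <- intersect(rownames(de1), rownames(de3))
  expect_lt(median(abs(de1[common, "log2FoldChange"] -
                         de3[common, "log2FoldChange"])), 0.01)
})
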