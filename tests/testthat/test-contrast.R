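test_that("fisherExactTest reproduces the worked example and identities", {
  # replication split: 8/8 mut in one cluster, 3/4 wt in the other
  expect_equal(fisherExactTest(matrix(c(8, 0, 1, 3), 2)), 0.0182,
               tolerance = 5e-3)
  expect_equal(fisherExactTest(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_error(fisherExactTest(matrix(0, 2, 2)), "positive margin")
  expect_error(fisherExactTest(matrix(c(-1, 1, 1, 1), 2)), "non-negative")

  set.seed(41)
  for (i in 1:200) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisherExactTest(tab)
    # agreement with the independent base-R implementation
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # invariance to transposition and to simultaneous row/column swaps
    expect_equal(p, fisherExactTest(t(tab)), tolerance = 1e-12)
    expect_equal(p, fisherExactTest(tab[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("classifyGenes implements the discriminating-gene rule", {
  mk <- function(lfc, q) {
    call <- callDE(lfc, q)
    df <- S4Vectors::DataFrame(baseMean = rep(10, length(lfc)),
                               log2FoldChange = lfc, pvalue = q, padj = q,
                               call = call,
                               row.names = sprintf("g%03d", seq_along(lfc)))
    new("DEResult", df)
  }
  # worked cases: significant + unchanged partner -> discriminating;
  # both significant same sign -> shared; opposite signs -> opposite;
  # partner ns outside the band, same sign -> other
  deM <- mk(c(2.0, 1.5, 1.2, 1.4, 0.2), c(1e-5, 1e-4, 1e-4, 1e-4, 0.9))
  deW <- mk(c(0.1, 1.2, -1.3, 0.7, 0.3), c(0.8, 1e-3, 1e-3, 0.2, 0.7))
  cls <- classifyGenes(deM, deW)
  expect_identical(cls$category,
                   c("discriminating", "shared", "opposite", "other",
                     "other"))
  # a partner exactly at the open band edge does not count as unchanged
  deM2 <- mk(c(2.0, 2.0), c(1e-5, 1e-5))
  deW2 <- mk(c(0.5, 0.4999), c(0.5, 0.5))
  expect_identical(classifyGenes(deM2, deW2)$category,
                   c("other", "discriminating"))
  # reverse-signed partner counts even when outside the band
  deW3 <- mk(c(-0.8, -0.2), c(0.5, 0.5))
  expect_identical(classifyGenes(deM2, deW3)$category,
                   rep("discriminating", 2))
  expect_error(classifyGenes(deM, deW[1:3, ]), "universe")
})

test_that("classifyGenes partitions the universe and matches the rule oracle", {
  set.seed(55)
  n <- 2000
  lfcM <- runif(n, -3, 3); lfcW <- runif(n, -3, 3)
  qM <- runif(n); qW <- runif(n)
  # concentrate some mass near the decision boundaries
  lfcW[1:300] <- sample(c(-0.5, 0.5, 0.4999, -0.4999, 1, -1), 300, TRUE)
  qM[1:300] <- sample(c(0.009, 0.01, 0.011), 300, TRUE)
  df <- S4Vectors::DataFrame(baseMean = rep(1, n), log2FoldChange = lfcM,
                             pvalue = qM, padj = qM,
                             call = callDE(lfcM, qM),
                             row.names = sprintf("g%05d", 1:n))
  deM <- new("DEResult", df)
  dfW <- S4Vectors::DataFrame(baseMean = rep(1, n), log2FoldChange = lfcW,
                              pvalue = qW, padj = qW,
                              call = callDE(lfcW, qW),
                              row.names = sprintf("g%05d", 1:n))
  deW <- new("DEResult", dfW)
  cls <- classifyGenes(deM, deW)
  oracle <- mapply(oracleClassify, lfcM, qM, lfcW, qW)
  expect_identical(cls$category, unname(oracle))
  # every gene falls in exactly one category
  expect_identical(sum(table(cls$category)), as.integer(n))
})

test_that("perClusterDE recovers group-private and shared programs", {
  d <- testDesign(nGenes = 3000L, fracDeShared = 0.05, fracDeMutOnly = 0.05,
                  fracDeWtOnly = 0.05, seed = 37L)
  sim <- simulateCounts(d)
  de2 <- perClusterDE(sim$counts, sim$samples)
  expect_identical(rownames(de2$mut), rownames(de2$wt))
  tr <- sim$truth$genes
  mutOnly <- intersect(tr$gene_id[tr$status == "de_mut"], rownames(de2$mut))
  shared <- intersect(tr$gene_id[tr$status == "de_shared"], rownames(de2$mut))
  sgn <- tr$sign[match(mutOnly, tr$gene_id)]
  wantCall <- ifelse(sgn == 1, "up", "down")
  # called in the carrying group, quiet in the other
  expect_gt(mean(de2$mut[mutOnly, "call"] == wantCall), 0.8)
  expect_gt(mean(de2$wt[mutOnly, "call"] == "ns" &
                   abs(de2$wt[mutOnly, "log2FoldChange"]) < 0.5), 0.8)
  # shared genes called with the same sign in both groups
  sgnS <- tr$sign[match(shared, tr$gene_id)]
  wantS <- ifelse(sgnS == 1, "up", "down")
  expect_gt(mean(de2$mut[shared, "call"] == wantS &
                   de2$wt[shared, "call"] == wantS), 0.8)

  # null design: per-cluster calls essentially absent
  d0 <- testDesign(nGenes = 3000L, seed = 39L)
  sim0 <- simulateCounts(d0)
  de0 <- perClusterDE(sim0$counts, sim0$samples)
  expect_lt(mean(de0$mut$call != "ns"), 0.002)
  expect_lt(mean(de0$wt$call != "ns"), 0.002)
})

test_that("replicationClusterTest aligns clusters with genotype", {
  # planted two-program simulation restricted to a signature-like subset
  d <- testDesign(nGenes = 2000L, nTumorsMut = 8L, nTumorsWt = 4L,
                  nNormals = 4L, fracDeMutOnly = 0.05, fracDeWtOnly = 0.05,
                  seed = 47L)
  sim <- simulateCounts(d)
  v <- vstTransform(sim$counts)
  tum <- sim$samples$sample_id[sim$samples$tissue == "tumor"]
  genotypes <- sim$truth$sampleClusters
  tr <- sim$truth$genes
  signature <- head(tr$gene_id[tr$status %in% c("de_mut", "de_wt")], 131)
  res <- replicationClusterTest(v[, tum], genotypes, signature)
  expect_lt(res$p, 0.05)
  expect_identical(sum(res$table), length(tum))
  byClust <- table(genotypes[tum], res$assignments)
  expect_true(all(apply(byClust, 2, max) == colSums(byClust)))  # pure clusters

  # perfectly separated duplicated profiles reach the margin-minimal p
  sep <- cbind(a = c(rep(6, 50), rep(0, 50)), b = c(rep(6, 50), rep(0, 50)),
               c = c(rep(0, 50), rep(6, 50)), d = c(rep(0, 50), rep(6, 50)))
  rownames(sep) <- sprintf("g%02d", 1:100)
  gt <- c(a = "mut", b = "mut", c = "wt", d = "wt")
  r2 <- replicationClusterTest(sep, gt, rownames(sep))
  expect_equal(r2$p, fisherExactTest(matrix(c(2, 0, 0, 2), 2)))
  expect_error(replicationClusterTest(sep[, 1:3], gt[1:3], rownames(sep)),
               "4 samples")
  expect_error(replicationClusterTest(sep, gt, "nope"), "overlap")
})
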