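test_that("assignGenePositions averages transcript midpoints", {
  tx <- data.frame(gene_id = c("g1", "g1", "g2"),
                   chrom = c("chr1", "chr1", "chr2"),
                   start = c(100, 300, 0), end = c(200, 500, 1000))
  pos <- assignGenePositions(tx)
  expect_equal(pos$position[pos$gene_id == "g1"], 275)
  expect_equal(pos$position[pos$gene_id == "g2"], 500)

  # multi-chromosome gene is an error naming the gene
  bad <- rbind(tx, data.frame(gene_id = "g1", chrom = "chr3",
                              start = 5, end = 10))
  expect_error(assignGenePositions(bad), "g1")

  # 50-gene fixture matches an independent per-gene computation
  set.seed(61)
  n <- 50
  ntx <- sample(1:3, n, replace = TRUE)
  fix <- do.call(rbind, lapply(seq_len(n), function(g) {
    s <- sort(sample(0:100000, ntx[g]))
    data.frame(gene_id = sprintf("g%02d", g), chrom = "chrZ",
               start = s, end = s + sample(100:5000, ntx[g], replace = TRUE))
  }))
  got <- assignGenePositions(fix)
  oracle <- vapply(sprintf("g%02d", 1:n), function(g) {
    r <- fix[fix$gene_id == g, ]
    mean((r$start + r$end) / 2)
  }, numeric(1))
  expect_equal(setNames(got$position, got$gene_id), oracle)
})

test_that("makeSlidingWindows tiles per the 1 Mb / 250 kb design", {
  w <- makeSlidingWindows(c(chrA = 1e6))
  expect_equal(w$start, c(0, 2.5e5, 5e5, 7.5e5))
  expect_equal(w$end, rep(1e6, 4))

  # an interior position lies in exactly width/step = 4 windows
  w2 <- makeSlidingWindows(c(chrB = 2e6))
  hit <- sum(w2$start <= 9e5 & w2$end > 9e5)
  expect_identical(hit, 4L)

  # random lengths match a brute-force enumeration
  set.seed(7)
  lens <- setNames(round(runif(4, 3e5, 5e6)), paste0("c", 1:4))
  got <- makeSlidingWindows(lens, width = 1e6, step = 2.5e5)
  brute <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- c()
    s <- 0
    while (s < lens[[ch]]) { starts <- c(starts, s); s <- s + 2.5e5 }
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + 1e6, lens[[ch]]))
  }))
  expect_equal(got, brute, ignore_attr = TRUE)
  expect_error(makeSlidingWindows(c(c1 = -5)), "positive")
  expect_error(makeSlidingWindows(c(c1 = 1e6), width = 1e5, step = 2e5),
               "width > step")
})

test_that("hypergeomTail matches the log-binomial oracle and is monotone", {
  expect_equal(hypergeomTail(0, 10, 50, 1000), 1)
  expect_equal(hypergeomTail(7, 7, 60, 60), 1)  # whole population marked
  expect_equal(hypergeomTail(5, 10, 50, 1000),
               oracleHyperTail(5, 10, 50, 1000), tolerance = 1e-12)
  set.seed(71)
  for (i in 1:100) {
    N <- sample(20:5000, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomTail(k, n, K, N), oracleHyperTail(k, n, K, N),
                 tolerance = 1e-9)
  }
  # monotone non-increasing in k at fixed (n, K, N)
  ks <- 0:20
  ps <- hypergeomTail(ks, 40, 100, 1000)
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(hypergeomTail(5, 4, 10, 100), "k <= n")
})

test_that("scanWindows finds planted hotspots and respects the null", {
  d <- SimulationDesign(nGenes = 8000L, seed = 83L)  # default 45-gene hotspot
  sim <- simulateCounts(d)
  ann <- simulateAnnotation(d, sim$truth)
  pos <- assignGenePositions(ann)
  chromLengths <- setNames(rep(d@chromLength, d@nChroms),
                           paste0("chr", seq_len(d@nChroms)))
  de <- perClusterDE(sim$counts, sim$samples)
  sc <- suppressMessages(scanWindows(pos, de$wt, chromLengths, "up"))
  win <- scanWindowsTable(sc)
  hsWin <- win$chrom == "chr1" & win$start < 38.75e6 & win$end > 36.25e6
  expect_true(any(win$significant[hsWin]))

  # merged into a single region covering the planted interval (within
  # two window steps of its boundaries)
  reg <- mergeSignificantRegions(sc, pos, de$wt)
  expect_identical(nrow(reg), 1L)
  expect_true(reg$chrom == "chr1")
  expect_lte(abs(reg$start - 36.25e6), 5e5)
  expect_lte(abs(reg$end - 38.75e6), 5e5)
  # region p recomputed over the union matches the oracle on region counts
  expect_equal(reg$pRegion,
               oracleHyperTail(reg$nDirection, reg$nGenes, sc@nCalled,
                               sc@universeSize), tolerance = 1e-9)

  # a DE table with zero calls yields no significant window
  deNone <- new("DEResult", S4Vectors::DataFrame(
    baseMean = de$wt$baseMean, log2FoldChange = de$wt$log2FoldChange,
    pvalue = de$wt$pvalue, padj = de$wt$padj,
    call = rep("ns", nrow(de$wt)), row.names = rownames(de$wt)))
  sc0 <- suppressMessages(scanWindows(pos, deNone, chromLengths, "up"))
  expect_false(any(scanWindowsTable(sc0)$significant))
  expect_true(all(scanWindowsTable(sc0)$pHyper == 1))

  # scan invariant to gene input order
  shuf <- pos[sample(nrow(pos)), ]
  sc2 <- suppressMessages(scanWindows(shuf, de$wt, chromLengths, "up"))
  expect_equal(scanWindowsTable(sc2)$pHyper, win$pHyper)
})

test_that("window gene counts over-count interior genes exactly four-fold", {
  set.seed(91)
  pos <- data.frame(gene_id = sprintf("g%03d", 1:300), chrom = "chr1",
                    position = runif(300, 0, 8e6))
  de <- new("DEResult", S4Vectors::DataFrame(
    baseMean = rep(1, 300), log2FoldChange = rep(0, 300),
    pvalue = rep(1, 300), padj = rep(1, 300),
    call = rep(c("up", "ns"), c(30, 270)), row.names = pos$gene_id))
  sc <- scanWindows(pos, de, c(chr1 = 8e6), "up")
  win <- scanWindowsTable(sc)
  interior <- pos$position >= 7.5e5 & pos$position < 8e6 - 7.5e5
  hits <- vapply(seq_len(nrow(pos)), function(i)
    sum(win$start <= pos$position[i] & win$end > pos$position[i]),
    numeric(1))
  expect_true(all(hits[interior] == 4))
  expect_identical(sum(win$nGenes), as.integer(sum(hits)))
})

test_that("mergeSignificantRegions unions overlapping windows only", {
  mkScan <- function(df) new("WindowScan", windows = df, direction = "up",
                             alpha = 0.05, universeSize = 1000L,
                             nCalled = 100L)
  pos <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    position = c(1e5, 6e6))
  de <- new("DEResult", S4Vectors::DataFrame(
    baseMean = c(1, 1), log2FoldChange = c(2, 2), pvalue = c(0, 0),
    padj = c(0, 0), call = c("up", "up"), row.names = c("a", "b")))
  win <- data.frame(chrom = "chr1", start = c(0, 2.5e5, 5e6),
                    end = c(1e6, 1.25e6, 6e6),
                    nGenes = c(5L, 5L, 5L), nDirection = c(3L, 3L, 3L),
                    pHyper = c(1e-9, 1e-9, 1e-9),
                    significant = c(TRUE, TRUE, FALSE))
  reg <- mergeSignificantRegions(mkScan(win), pos, de)
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$start, 0)
  expect_equal(reg$end, 1.25e6)

  # far-apart significant windows stay separate regions
  win2 <- win; win2$significant <- c(TRUE, FALSE, TRUE)
  reg2 <- mergeSignificantRegions(mkScan(win2), pos, de)
  expect_identical(nrow(reg2), 2L)
})
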