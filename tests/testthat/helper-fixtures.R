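# Shared fixtures, built in code at test time.

# empty hotspot table (most small designs do not plant positional structure)
noHotspots <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             nPlanted = integer(0), direction = character(0),
             group = character(0), stringsAsFactors = FALSE)
}

# compact design helper for unit tests
testDesign <- function(nGenes = 2000L, nTumorsMut = 8L, nTumorsWt = 7L,
                       nNormals = 5L, dispersion = 0.1, effectLog2fc = 2,
                       fracDeShared = 0, fracDeMutOnly = 0,
                       fracDeWtOnly = 0, fracOpposite = 0,
                       hotspots = noHotspots(), seed = 1L, ...) {
  SimulationDesign(nGenes = nGenes, nTumorsMut = nTumorsMut,
                   nTumorsWt = nTumorsWt, nNormals = nNormals,
                   dispersion = dispersion, effectLog2fc = effectLog2fc,
                   fracDeShared = fracDeShared,
                   fracDeMutOnly = fracDeMutOnly,
                   fracDeWtOnly = fracDeWtOnly, fracOpposite = fracOpposite,
                   hotspots = hotspots, seed = seed, ...)
}

# sample table for hand-built count matrices
sampleTableFor <- function(counts, nTumor, nNormal,
                           groups = rep("mut", nTumor)) {
  data.frame(sample_id = colnames(counts),
             tissue = c(rep("tumor", nTumor), rep("normal", nNormal)),
             group = c(groups, rep("none", nNormal)),
             stringsAsFactors = FALSE)
}

# independent upper-tail hypergeometric oracle via log-binomial summation
# (kept free of phyper/dhyper so it can stand against them)
oracleHyperTail <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# brute-force BH step-up oracle
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# literal re-application of the discriminating-gene rule for one gene
oracleClassify <- function(lfcM, qM, lfcW, qW, lfcThr = 1, qThr = 0.01,
                           band = 0.5) {
  sigM <- qM < qThr && abs(lfcM) >= lfcThr
  sigW <- qW < qThr && abs(lfcW) >= lfcThr
  if (sigM && sigW) {
    if (sign(lfcM) == sign(lfcW)) return("shared") else return("opposite")
  }
  if (sigM && !sigW) {
    if (sign(lfcW) != sign(lfcM) || abs(lfcW) < band) return("discriminating")
    return("other")
  }
  if (sigW && !sigM) {
    if (sign(lfcM) != sign(lfcW) || abs(lfcM) < band) return("discriminating")
    return("other")
  }
  "other"
}

# tiny GTF written to a temp file; returns path and the hand-parsed records
tinyGtf <- function() {
  path <- tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "%s"; transcript_id "%s";'
  lines <- c(
    sprintf('chr1\tens\ttranscript\t101\t200\t.\t+\t.\t%s',
            sprintf(attr1, "gA", "gA.t1")),
    sprintf('chr1\tens\texon\t101\t150\t.\t+\t.\t%s',
            sprintf(attr1, "gA", "gA.t1")),
    sprintf('chr1\tens\ttranscript\t301\t500\t.\t-\t.\t%s',
            sprintf(attr1, "gA", "gA.t2")),
    sprintf('chr2\tens\ttranscript\t1\t1000\t.\t+\t.\t%s',
            sprintf(attr1, "gB", "gB.t1")),
    sprintf('chr2\tens\ttranscript\t2001\t2600\t.\t+\t.\t%s',
            sprintf(attr1, "gC", "gC.t1"))
  )
  writeLines(lines, path)
  hand <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100, 300, 0, 2000),
    end = c(200, 500, 1000, 2600),
    stringsAsFactors = FALSE)
  list(path = path, hand = hand)
}
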