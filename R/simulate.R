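# Synthetic cohort generator.  Plants every structure the downstream stages
# are designed to detect (group-shared and group-private DE, a small
# opposite-direction fraction, positional hotspots) and returns the ground
# truth alongside, so recovery is testable end to end.

#' Construct a SimulationDesign
#'
#' Defaults emulate the study cohort: 11 mutant-group and 4 wild-type tumors
#' plus 5 normals, ~20k expressed genes with log-normal baseline means
#' (log2 mean 6, sd 2, spanning low-count to saturated genes), NB dispersion
#' 0.1, planted effects of |log2FC| = 2, and one 2.5 Mb hotspot carrying 45
#' up-regulated wild-type-group genes, mirroring the strongest reported
#' positional locus.
#'
#' @param nGenes number of genes.
#' @param nTumorsMut,nTumorsWt,nNormals sample counts per arm.
#' @param baselineLog2Mean,baselineLog2Sd log2-scale parameters of the
#'   log-normal baseline mean distribution.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2);
#'   0 gives Poisson counts.
#' @param fracDeShared,fracDeMutOnly,fracDeWtOnly,fracOpposite fractions of
#'   genes planted as tumor-shared, group-private, or opposite-direction DE.
#' @param effectLog2fc magnitude of planted log2 fold changes (sign random
#'   per gene).
#' @param nChroms number of pseudo-chromosomes (default one per 2000 genes).
#' @param chromLength chromosome length in bp.
#' @param hotspots data.frame with columns `chrom`, `start`, `end`,
#'   `nPlanted`, `direction` (`up`/`down`), `group` (`mut`/`wt`/`shared`).
#' @param librarySizeFactors optional fixed per-sample size factors; if
#'   empty they are drawn log-normal with sd `librarySizeSd`.
#' @param librarySizeSd log-scale sd of drawn library size factors.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a [SimulationDesign-class].
#' @export
SimulationDesign <- function(nGenes = 20000L,
                             nTumorsMut = 11L, nTumorsWt = 4L, nNormals = 5L,
                             baselineLog2Mean = 6, baselineLog2Sd = 2,
                             dispersion = 0.1,
                             fracDeShared = 0.10, fracDeMutOnly = 0.05,
                             fracDeWtOnly = 0.05, fracOpposite = 0.005,
                             effectLog2fc = 2,
                             nChroms = NULL, chromLength = 62.5e6,
                             hotspots = NULL,
                             librarySizeFactors = numeric(0),
                             librarySizeSd = 0.15,
                             seed = 1L) {
  nGenes <- as.integer(nGenes)
  if (is.null(nChroms)) nChroms <- max(1L, as.integer(ceiling(nGenes / 2000)))
  if (is.null(hotspots))
    hotspots <- data.frame(chrom = "chr1", start = 36.25e6, end = 38.75e6,
                           nPlanted = 45L, direction = "up", group = "wt",
                           stringsAsFactors = FALSE)
  if (!is.data.frame(hotspots))  # e.g. a YAML-parsed list
    hotspots <- as.data.frame(hotspots, stringsAsFactors = FALSE)
  hotspots$nPlanted <- as.integer(hotspots$nPlanted)
  new("SimulationDesign",
      nGenes = nGenes, nTumorsMut = as.integer(nTumorsMut),
      nTumorsWt = as.integer(nTumorsWt), nNormals = as.integer(nNormals),
      baselineLog2Mean = baselineLog2Mean, baselineLog2Sd = baselineLog2Sd,
      dispersion = dispersion, fracDeShared = fracDeShared,
      fracDeMutOnly = fracDeMutOnly, fracDeWtOnly = fracDeWtOnly,
      fracOpposite = fracOpposite, effectLog2fc = effectLog2fc,
      nChroms = as.integer(nChroms), chromLength = chromLength,
      hotspots = hotspots, librarySizeFactors = librarySizeFactors,
      librarySizeSd = librarySizeSd, seed = as.integer(seed))
}

#' Simulate a count matrix with planted structure
#'
#' Counts are drawn NB with mean `baseline * sizeFactor * 2^delta`, where
#' `delta` is the signed planted log2 fold change when the sample's group
#' carries the gene's effect, and 0 otherwise.  Normals never carry tumor
#' effects.  Group-private genes (status `de_mut` / `de_wt`) shift only that
#' group's tumors - these are the cluster-discriminating genes.  `opposite`
#' genes carry the effect with flipped sign in the two groups.  Hotspot
#' genes are drawn from (or added to) the matching group/direction pool and
#' tagged for positional placement.
#'
#' @param design a [SimulationDesign-class].
#' @return list with elements `counts` (integer matrix), `samples`
#'   (sample table), `se` (assembled SummarizedExperiment) and `truth`
#'   (list: `genes` per-gene data.frame with `status`, `sign`, `log2fc`,
#'   `hotspot`; `sampleClusters` named group labels; `hotspots` the planted
#'   intervals).
#' @export
simulateCounts <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  set.seed(design@seed)
  nG <- design@nGenes
  nMut <- design@nTumorsMut; nWt <- design@nTumorsWt; nN <- design@nNormals
  nS <- nMut + nWt + nN
  if (nMut + nWt < 1 || nS < 2) stop("design needs at least 2 samples")

  sampleIds <- c(sprintf("mut_T%02d", seq_len(nMut)),
                 sprintf("wt_T%02d", seq_len(nWt)),
                 sprintf("norm_N%02d", seq_len(nN)))
  groups <- c(rep("mut", nMut), rep("wt", nWt), rep("none", nN))
  tissue <- c(rep("tumor", nMut + nWt), rep("normal", nN))
  samples <- data.frame(sample_id = sampleIds, tissue = tissue,
                        group = groups, stringsAsFactors = FALSE)

  geneIds <- sprintf("gene%05d", seq_len(nG))
  baseline <- 2 ^ rnorm(nG, design@baselineLog2Mean, design@baselineLog2Sd)

  status <- rep("null", nG)
  sgn <- rep(0L, nG)
  hotspot <- rep(NA_integer_, nG)
  pool <- sample.int(nG)  # random gene order; assign from the front
  take <- function(n) {
    if (n > length(pool)) stop("design plants more genes than available")
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  hs <- design@hotspots
  if (nrow(hs)) {
    for (i in seq_len(nrow(hs))) {
      idx <- take(hs$nPlanted[i])
      status[idx] <- switch(hs$group[i], mut = "de_mut", wt = "de_wt",
                            shared = "de_shared")
      sgn[idx] <- if (hs$direction[i] == "up") 1L else -1L
      hotspot[idx] <- i
    }
  }
  nShared <- round(design@fracDeShared * nG)
  nMutOnly <- round(design@fracDeMutOnly * nG)
  nWtOnly <- round(design@fracDeWtOnly * nG)
  nOpp <- round(design@fracOpposite * nG)
  for (spec in list(list(n = nShared, st = "de_shared"),
                    list(n = nMutOnly, st = "de_mut"),
                    list(n = nWtOnly, st = "de_wt"),
                    list(n = nOpp, st = "opposite"))) {
    if (spec$n > 0) {
      idx <- take(spec$n)
      status[idx] <- spec$st
      sgn[idx] <- sample(c(-1L, 1L), spec$n, replace = TRUE)
    }
  }
  log2fc <- sgn * design@effectLog2fc

  lsf <- design@librarySizeFactors
  if (!length(lsf)) lsf <- exp(rnorm(nS, 0, design@librarySizeSd))
  lsf <- lsf / exp(mean(log(lsf)))  # geometric mean 1

  # per-gene signed effect carried by each group
  deltaMut <- ifelse(status %in% c("de_shared", "de_mut", "opposite"),
                     log2fc, 0)
  deltaWt <- ifelse(status %in% c("de_shared", "de_wt"), log2fc,
                    ifelse(status == "opposite", -log2fc, 0))
  delta <- cbind(mut = deltaMut, wt = deltaWt, none = rep(0, nG))

  mu <- outer(baseline, lsf) * 2 ^ delta[, groups, drop = FALSE]
  counts <- if (design@dispersion > 0)
    rnbinom(length(mu), mu = mu, size = 1 / design@dispersion)
  else
    rpois(length(mu), lambda = mu)
  counts <- matrix(as.integer(counts), nrow = nG,
                   dimnames = list(geneIds, sampleIds))

  truthGenes <- data.frame(gene_id = geneIds, status = status, sign = sgn,
                           log2fc = log2fc, hotspot = hotspot,
                           stringsAsFactors = FALSE)
  truth <- list(genes = truthGenes,
                sampleClusters = setNames(groups[tissue == "tumor"],
                                          sampleIds[tissue == "tumor"]),
                hotspots = hs)
  list(counts = counts, samples = samples,
       se = CountExperiment(counts, samples), truth = truth)
}

#' Simulate transcript annotation consistent with the planted hotspots
#'
#' Genes are placed uniformly along the synthetic chromosomes with 1-3
#' transcripts each; transcript midpoints are constructed to average exactly
#' to the gene's drawn center, so the assigned gene position is exact.
#' Genes tagged to a hotspot are centered inside the hotspot interval.
#'
#' @param design a [SimulationDesign-class].
#' @param truth truth list from [simulateCounts()].
#' @return data.frame of transcripts (`gene_id`, `chrom`, `start`, `end`),
#'   0-based half-open.
#' @export
simulateAnnotation <- function(design, truth) {
  stopifnot(is(design, "SimulationDesign"))
  genes <- truth$genes
  hs <- truth$hotspots
  set.seed(design@seed + 1001L)
  nG <- nrow(genes)
  L <- design@chromLength
  chroms <- paste0("chr", seq_len(design@nChroms))

  chrom <- sample(chroms, nG, replace = TRUE)
  center <- floor(runif(nG, 0, L))
  inHs <- !is.na(genes$hotspot)
  if (any(inHs)) {
    hi <- genes$hotspot[inHs]
    if (any(hi > nrow(hs))) stop("truth references an unknown hotspot")
    chrom[inHs] <- hs$chrom[hi]
    center[inHs] <- floor(runif(sum(inHs), hs$start[hi], hs$end[hi]))
  }

  # 1-3 transcripts per gene; per-gene midpoint offsets sum to zero so the
  # mean transcript midpoint equals the drawn center exactly.
  nTx <- sample(1:3, nG, replace = TRUE)
  o1 <- sample.int(20000L, nG, replace = TRUE)
  o2 <- sample((-20000L):20000L, nG, replace = TRUE)
  o3 <- sample((-20000L):20000L, nG, replace = TRUE)
  off <- unlist(lapply(seq_len(nG), function(g) {
    switch(nTx[g], 0L, c(o1[g], -o1[g]), c(o2[g], o3[g], -o2[g] - o3[g]))
  }))
  geneIdx <- rep(seq_len(nG), nTx)
  mids <- pmin(pmax(center[geneIdx] + off, 1), L - 1)  # keep on-chromosome
  w <- sample(500:5000, length(mids), replace = TRUE)
  data.frame(gene_id = genes$gene_id[geneIdx], chrom = chrom[geneIdx],
             start = pmax(0, mids - w), end = pmin(L, mids + w),
             stringsAsFactors = FALSE)
}

#' Simulate GMT gene sets with one planted-enriched set
#'
#' The first set (`planted_de_set`) draws 70% of its members from planted DE
#' genes; the remaining sets are uniform draws from the gene universe.
#'
#' @param truth truth list from [simulateCounts()].
#' @param nSets total number of sets.
#' @param setSize size of the enriched set (random sets draw 20-100 members).
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(truth, nSets = 10L, setSize = 50L, seed = 1L) {
  set.seed(seed)
  genes <- truth$genes
  universe <- genes$gene_id
  planted <- universe[genes$status != "null"]
  if (!length(planted)) stop("truth contains no planted DE genes")
  nP <- min(length(planted), ceiling(0.7 * setSize))
  enriched <- c(sample(planted, nP),
                sample(setdiff(universe, planted), setSize - nP))
  sets <- list(planted_de_set = enriched)
  desc <- c(planted_de_set = "set enriched in planted DE genes")
  if (nSets > 1) {
    for (i in seq_len(nSets - 1)) {
      nm <- sprintf("random_set_%02d", i)
      sets[[nm]] <- sample(universe, sample(20:100, 1))
      desc[nm] <- "random draw from the gene universe"
    }
  }
  GeneSetCollection(sets, desc)
}
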