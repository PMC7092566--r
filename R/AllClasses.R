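# Central S4 classes.  Validity methods enforce the structural invariants the
# downstream statistics rely on (no silent NA propagation, matched dimnames).

#' Gene-set collection
#'
#' Named collection of gene sets as read from a GMT file: unique set names,
#' non-empty deduplicated member vectors, one free-text description per set.
#'
#' @slot sets named list of character vectors (gene identifiers).
#' @slot descriptions named character vector, parallel to `sets`.
#' @export
setClass("GeneSetCollection",
         slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  if (length(s) != length(object@descriptions))
    return("sets and descriptions must have equal length")
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      return("set names must be present and unique")
    if (!identical(names(s), names(object@descriptions)))
      return("sets and descriptions must share names")
    if (any(!vapply(s, is.character, logical(1))))
      return("every set must be a character vector")
    if (any(vapply(s, length, integer(1)) == 0L))
      return("member sets must be non-empty")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
      return("member sets must be deduplicated")
  }
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers; members
#'   are deduplicated, preserving first occurrence.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to empty strings).
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C", "D")))
#' length(gsc)
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  else
    descriptions <- setNames(as.character(descriptions), names(sets))
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection-class number of sets
#' @param x a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set names
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Accessors for GeneSetCollection
#'
#' `geneSets()` returns the named list of member vectors; `setDescriptions()`
#' the per-set description strings.
#'
#' @param object a [GeneSetCollection-class]
#' @return list or character vector, named by set.
#' @export
geneSets <- function(object) {
  stopifnot(is(object, "GeneSetCollection"))
  object@sets
}

#' @rdname geneSets
#' @export
setDescriptions <- function(object) {
  stopifnot(is(object, "GeneSetCollection"))
  object@descriptions
}

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object), "sets\n")
  if (length(object)) {
    sz <- vapply(object@sets, length, integer(1))
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
    cat("  names:", paste(head(names(object), 5), collapse = ", "),
        if (length(object) > 5) "..." else "", "\n")
  }
})

#' Differential expression result
#'
#' Per-gene table (rows named by gene) with columns `baseMean`,
#' `log2FoldChange`, `pvalue`, `padj` (Benjamini-Hochberg) and `call`
#' (`"up"`, `"down"`, `"ns"`).  Calls obey the study thresholds stored in
#' `metadata()`: `up` iff `log2FoldChange >= lfcThreshold` and
#' `padj < qThreshold`, symmetrically for `down`.
#'
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
  need <- c("baseMean", "log2FoldChange", "pvalue", "padj", "call")
  if (!all(need %in% colnames(object)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (is.null(rownames(object))) return("rownames (gene ids) required")
  p <- object$pvalue; q <- object$padj
  if (any(q < p - 1e-12, na.rm = TRUE)) return("padj must be >= pvalue")
  if (any(q < 0 | q > 1, na.rm = TRUE)) return("padj must lie in [0,1]")
  if (!all(object$call %in% c("up", "down", "ns")))
    return("call must be up/down/ns")
  TRUE
})

.DEResult <- function(df, case = NA_character_, control = NA_character_,
                      lfcThreshold = 1, qThreshold = 0.01) {
  out <- new("DEResult", DataFrame(df, row.names = rownames(df)))
  metadata(out) <- list(case = case, control = control,
                        lfcThreshold = lfcThreshold, qThreshold = qThreshold)
  out
}

setMethod("show", "DEResult", function(object) {
  md <- metadata(object)
  cat("DEResult:", nrow(object), "genes;",
      sum(object$call == "up"), "up,",
      sum(object$call == "down"), "down",
      sprintf("(|log2FC| >= %g, q < %g)\n", md$lfcThreshold, md$qThreshold))
  if (!is.na(md$case)) cat("  contrast:", md$case, "vs", md$control, "\n")
  callNextMethod()
})

#' Low-dimensional embedding of samples
#'
#' @slot coordinates samples x dims matrix.
#' @slot explainedVariance per-dimension fraction of variance (PCA only;
#'   empty for classical MDS).
#' @slot method `"pca"` or `"mds"`.
#' @export
setClass("EmbeddingResult",
         slots = c(coordinates = "matrix", explainedVariance = "numeric",
                   method = "character"))

setValidity("EmbeddingResult", function(object) {
  ev <- object@explainedVariance
  if (length(ev)) {
    if (any(diff(ev) > 1e-10)) return("explained fractions must be non-increasing")
    if (sum(ev) > 1 + 1e-8) return("explained fractions must sum to <= 1")
  }
  TRUE
})

#' @rdname EmbeddingResult-class
#' @param object an `EmbeddingResult`
#' @export
embeddingCoordinates <- function(object) {
  stopifnot(is(object, "EmbeddingResult"))
  object@coordinates
}

#' @rdname EmbeddingResult-class
#' @export
explainedVariance <- function(object) {
  stopifnot(is(object, "EmbeddingResult"))
  object@explainedVariance
}

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf("EmbeddingResult (%s): %d samples x %d dims\n",
              object@method, nrow(object@coordinates),
              ncol(object@coordinates)))
  if (length(object@explainedVariance))
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * object@explainedVariance),
              collapse = ", "), "\n")
})

#' Consensus clustering result
#'
#' @slot consensusMatrix samples x samples matrix in \[0,1\]: fraction of
#'   co-clustered resamples among co-sampled resamples; diagonal fixed at 1.
#' @slot assignments named integer cluster labels (1..k).
#' @slot itemConsensus named per-sample mean consensus with the other members
#'   of the assigned cluster.
#' @slot k number of clusters.
#' @slot nResamples number of subsampling rounds.
#' @export
setClass("ConsensusResult",
         slots = c(consensusMatrix = "matrix", assignments = "integer",
                   itemConsensus = "numeric", k = "integer",
                   nResamples = "integer"))

setValidity("ConsensusResult", function(object) {
  m <- object@consensusMatrix
  if (nrow(m) != ncol(m)) return("consensus matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) return("consensus matrix must be symmetric")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("consensus entries must lie in [0,1]")
  if (any(abs(diag(m) - 1) > 1e-12)) return("diagonal must be 1")
  if (length(object@assignments) != nrow(m)) return("one assignment per sample")
  ic <- object@itemConsensus
  if (any(ic < -1e-12 | ic > 1 + 1e-12)) return("item consensus must lie in [0,1]")
  TRUE
})

#' Accessors for ConsensusResult
#' @param object a [ConsensusResult-class]
#' @return matrix, named integer vector, or named numeric vector.
#' @export
consensusMatrix <- function(object) {
  stopifnot(is(object, "ConsensusResult"))
  object@consensusMatrix
}

#' @rdname consensusMatrix
#' @export
clusterAssignments <- function(object) {
  stopifnot(is(object, "ConsensusResult"))
  object@assignments
}

#' @rdname consensusMatrix
#' @export
itemConsensus <- function(object) {
  stopifnot(is(object, "ConsensusResult"))
  object@itemConsensus
}

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d samples, k = %d, %d resamples\n",
              nrow(object@consensusMatrix), object@k, object@nResamples))
  cat("  cluster sizes:",
      paste(tabulate(object@assignments, object@k), collapse = ", "), "\n")
  cat(sprintf("  item consensus: mean %.3f (range %.3f-%.3f)\n",
              mean(object@itemConsensus), min(object@itemConsensus),
              max(object@itemConsensus)))
})

#' Per-sample z-score significance against the normal baseline
#'
#' @slot z genes x tumors matrix of z-scores on the VST scale (tumor value
#'   standardized by the normal-tissue mean and sd).
#' @slot threshold absolute z needed to flag a gene (boundary inclusive).
#' @slot upSets,downSets per-tumor character vectors of flagged genes.
#' @export
setClass("SampleSignificance",
         slots = c(z = "matrix", threshold = "numeric",
                   upSets = "list", downSets = "list"))

setValidity("SampleSignificance", function(object) {
  if (object@threshold <= 0) return("threshold must be positive")
  if (length(object@upSets) != ncol(object@z) ||
      length(object@downSets) != ncol(object@z))
    return("one up/down set per tumor column")
  bad <- mapply(function(u, d) length(intersect(u, d)) > 0,
                object@upSets, object@downSets)
  if (any(bad)) return("up and down sets must be disjoint")
  TRUE
})

#' Accessors for SampleSignificance
#'
#' `zscoreMatrix()` returns the genes x tumors z matrix;
#' `significantGeneSets()` the per-tumor flagged-gene sets for one direction
#' (`"all"` is the union of up and down).
#'
#' @param object a [SampleSignificance-class]
#' @param direction `"all"`, `"up"` or `"down"`.
#' @export
zscoreMatrix <- function(object) {
  stopifnot(is(object, "SampleSignificance"))
  object@z
}

#' @rdname zscoreMatrix
#' @export
significantGeneSets <- function(object, direction = c("all", "up", "down")) {
  stopifnot(is(object, "SampleSignificance"))
  direction <- match.arg(direction)
  switch(direction,
         up = object@upSets,
         down = object@downSets,
         all = mapply(function(u, d) c(u, d), object@upSets, object@downSets,
                      SIMPLIFY = FALSE))
}

setMethod("show", "SampleSignificance", function(object) {
  n <- vapply(significantGeneSets(object), length, integer(1))
  cat(sprintf("SampleSignificance: %d genes x %d tumors, |z| >= %g\n",
              nrow(object@z), ncol(object@z), object@threshold))
  cat(sprintf("  flagged genes per tumor: median %d (range %d-%d)\n",
              as.integer(median(n)), min(n), max(n)))
})

#' Jaccard coherence comparison between tumor groups
#'
#' @slot pairScores data.frame of all tumor pairs: sample ids, partition cell
#'   (`within_mut`, `within_wt`, `between`) and the Jaccard score.
#' @slot pWithinMut,pWithinWt one-sided p that within-group scores exceed
#'   between-group scores.
#' @slot method `"permutation"` or `"mwu"`.
#' @slot nPerm number of label permutations (0 for MWU).
#' @export
setClass("JaccardComparison",
         slots = c(pairScores = "data.frame", pWithinMut = "numeric",
                   pWithinWt = "numeric", method = "character",
                   nPerm = "integer"))

setValidity("JaccardComparison", function(object) {
  df <- object@pairScores
  need <- c("sample1", "sample2", "partition", "jaccard")
  if (!all(need %in% colnames(df))) return("pairScores missing columns")
  if (any(df$jaccard < -1e-12 | df$jaccard > 1 + 1e-12))
    return("jaccard scores must lie in [0,1]")
  if (!all(df$partition %in% c("within_mut", "within_wt", "between")))
    return("invalid partition label")
  TRUE
})

setMethod("show", "JaccardComparison", function(object) {
  df <- object@pairScores
  cat("JaccardComparison over", nrow(df), "tumor pairs (", object@method, ")\n")
  for (cell in c("within_mut", "within_wt", "between"))
    cat(sprintf("  %-11s n = %3d  mean J = %.3f\n", cell,
                sum(df$partition == cell),
                mean(df$jaccard[df$partition == cell])))
  cat(sprintf("  p(within mut > between) = %.3g\n", object@pWithinMut))
  cat(sprintf("  p(within wt  > between) = %.3g\n", object@pWithinWt))
})

#' Sliding-window positional scan result
#'
#' @slot windows data.frame with columns chrom, start, end (0-based
#'   half-open), nGenes, nDirection, pHyper, significant (Bonferroni at
#'   `alpha` over the windows tested in this scan).
#' @slot direction `"up"` or `"down"`.
#' @slot alpha family-wise error target before Bonferroni division.
#' @slot universeSize number of genes with both a position and a DE record.
#' @slot nCalled number of universe genes called in `direction`.
#' @export
setClass("WindowScan",
         slots = c(windows = "data.frame", direction = "character",
                   alpha = "numeric", universeSize = "integer",
                   nCalled = "integer"))

setValidity("WindowScan", function(object) {
  w <- object@windows
  need <- c("chrom", "start", "end", "nGenes", "nDirection", "pHyper",
            "significant")
  if (!all(need %in% colnames(w))) return("windows missing columns")
  if (any(w$nDirection > w$nGenes)) return("nDirection cannot exceed nGenes")
  if (any(w$pHyper <= 0 | w$pHyper > 1)) return("pHyper must lie in (0,1]")
  if (!object@direction %in% c("up", "down")) return("direction must be up/down")
  TRUE
})

#' @rdname WindowScan-class
#' @param object a `WindowScan`
#' @export
scanWindowsTable <- function(object) {
  stopifnot(is(object, "WindowScan"))
  object@windows
}

setMethod("show", "WindowScan", function(object) {
  cat(sprintf("WindowScan (%s): %d windows, %d/%d genes called\n",
              object@direction, nrow(object@windows), object@nCalled,
              object@universeSize))
  cat(sprintf("  significant windows (Bonferroni %g): %d\n", object@alpha,
              sum(object@windows$significant)))
})

#' Design of a synthetic expression study
#'
#' Defines the conditions of a simulated tumor/normal cohort: negative
#' binomial counts (variance mu + dispersion * mu^2) on a log-normal baseline,
#' planted differential expression shared between or private to the two
#' mutation-defined tumor groups, a small fraction of opposite-direction
#' genes, and chromosomal hotspot intervals over-populated with planted
#' direction-consistent genes.  Defaults mirror the study cohort (11 mutant
#' and 4 wild-type tumors, 5 normals) and its strongest positional locus
#' (45 up-regulated genes over 2.5 Mb).
#'
#' @export
setClass("SimulationDesign",
         slots = c(nGenes = "integer", nTumorsMut = "integer",
                   nTumorsWt = "integer", nNormals = "integer",
                   baselineLog2Mean = "numeric", baselineLog2Sd = "numeric",
                   dispersion = "numeric", fracDeShared = "numeric",
                   fracDeMutOnly = "numeric", fracDeWtOnly = "numeric",
                   fracOpposite = "numeric", effectLog2fc = "numeric",
                   nChroms = "integer", chromLength = "numeric",
                   hotspots = "data.frame", librarySizeFactors = "numeric",
                   librarySizeSd = "numeric", seed = "integer"))

setValidity("SimulationDesign", function(object) {
  if (object@nGenes < 1) return("nGenes must be positive")
  if (object@nTumorsMut < 0 || object@nTumorsWt < 0 || object@nNormals < 0)
    return("sample counts must be non-negative")
  fr <- c(object@fracDeShared, object@fracDeMutOnly, object@fracDeWtOnly,
          object@fracOpposite)
  if (any(fr < 0) || sum(fr) > 1)
    return("DE fractions must be non-negative and sum to <= 1")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  if (object@effectLog2fc < 0) return("effectLog2fc must be >= 0")
  if (object@nChroms < 1) return("nChroms must be positive")
  if (object@chromLength <= 0) return("chromLength must be positive")
  hs <- object@hotspots
  if (nrow(hs)) {
    need <- c("chrom", "start", "end", "nPlanted", "direction", "group")
    if (!all(need %in% colnames(hs))) return("hotspots missing columns")
    if (any(hs$end <= hs$start)) return("hotspot end must exceed start")
    if (any(hs$start < 0 | hs$end > object@chromLength))
      return("hotspot intervals must lie within chromosome bounds")
    if (!all(hs$chrom %in% paste0("chr", seq_len(object@nChroms))))
      return("hotspot chrom outside the simulated genome")
    if (!all(hs$direction %in% c("up", "down"))) return("hotspot direction must be up/down")
    if (!all(hs$group %in% c("mut", "wt", "shared"))) return("hotspot group must be mut/wt/shared")
    if (any(hs$nPlanted < 0)) return("nPlanted must be non-negative")
  }
  lsf <- object@librarySizeFactors
  nSamples <- object@nTumorsMut + object@nTumorsWt + object@nNormals
  if (length(lsf) && (length(lsf) != nSamples || any(lsf <= 0)))
    return("librarySizeFactors must be positive, one per sample")
  TRUE
})

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: %d genes; %d mut + %d wt tumors + %d normals\n",
    object@nGenes, object@nTumorsMut, object@nTumorsWt, object@nNormals))
  cat(sprintf("  NB dispersion %.3g, planted |log2FC| %.2g\n",
              object@dispersion, object@effectLog2fc))
  cat(sprintf("  DE fractions: shared %.3g, mut-only %.3g, wt-only %.3g, opposite %.3g\n",
              object@fracDeShared, object@fracDeMutOnly, object@fracDeWtOnly,
              object@fracOpposite))
  cat(sprintf("  genome: %d chromosomes of %.3g bp; %d hotspot(s)\n",
              object@nChroms, object@chromLength, nrow(object@hotspots)))
})
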