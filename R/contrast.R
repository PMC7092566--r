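# Per-cluster differential expression, the discriminating-gene
# classification rule, and the replication hierarchical-clustering test.

#' Per-cluster differential expression against normals
#'
#' Runs the NB Wald test independently for each mutation-defined tumor group
#' against the normal samples, on a common gene universe (genes expressed in
#' any of the involved samples).
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @param samples sample table with `sample_id`, `tissue`, `group`.
#' @param ... further arguments passed to [nbWaldTest()] (thresholds etc.).
#' @return named list with `DEResult` elements `mut` and `wt`.
#' @export
perClusterDE <- function(counts, samples, ...) {
  counts <- .countsFrom(counts)
  .validateSampleTable(samples)
  involved <- samples$sample_id[samples$tissue == "normal" |
                                  samples$group %in% c("mut", "wt")]
  involved <- intersect(colnames(counts), involved)
  keep <- rowSums(counts[, involved, drop = FALSE]) > 0
  universe <- counts[keep, , drop = FALSE]
  list(mut = nbWaldTest(universe, samples, "mut", "normal",
                        dropAllZero = FALSE, ...),
       wt = nbWaldTest(universe, samples, "wt", "normal",
                       dropAllZero = FALSE, ...))
}

#' Classify genes by their behavior in the two tumor clusters
#'
#' Applies the discriminating-gene rule to a pair of per-cluster DE tables
#' on the same gene universe:
#' \describe{
#'   \item{shared}{significant in both clusters, same sign.}
#'   \item{opposite}{significant in both clusters, opposite signs.}
#'   \item{discriminating}{significant in exactly one cluster while the
#'     other cluster's log2 fold change is reverse-signed or lies strictly
#'     inside the unchanged band `(-band, band)` (default 0.5, open).}
#'   \item{other}{everything else (including a one-sided significant gene
#'     whose partner sits same-signed at or beyond the band edge).}
#' }
#'
#' @param deMut,deWt [DEResult-class] tables over the same genes.
#' @param band half-width of the open unchanged band on log2FC.
#' @return data.frame with per-gene effects, q-values, calls and `category`.
#' @export
classifyGenes <- function(deMut, deWt, band = 0.5) {
  if (!setequal(rownames(deMut), rownames(deWt)))
    stop("the two DE tables must cover the same gene universe")
  deWt <- deWt[rownames(deMut), ]
  lfcM <- deMut$log2FoldChange; lfcW <- deWt$log2FoldChange
  sigM <- deMut$call != "ns"; sigW <- deWt$call != "ns"
  sgnM <- sign(lfcM); sgnW <- sign(lfcW)

  category <- rep("other", nrow(deMut))
  category[sigM & sigW & sgnM == sgnW] <- "shared"
  category[sigM & sigW & sgnM != sgnW] <- "opposite"
  oneM <- sigM & !sigW
  oneW <- sigW & !sigM
  category[oneM & (sgnW != sgnM | abs(lfcW) < band)] <- "discriminating"
  category[oneW & (sgnM != sgnW | abs(lfcM) < band)] <- "discriminating"

  data.frame(gene_id = rownames(deMut),
             log2fc_mut = lfcM, q_mut = deMut$padj, call_mut = deMut$call,
             log2fc_wt = lfcW, q_wt = deWt$padj, call_wt = deWt$call,
             category = category, row.names = rownames(deMut),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability rule: the p-value is the sum, over all tables with the
#' observed margins, of hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows = genotype, columns = cluster).
#' @return two-sided p-value.
#' @examples
#' fisherExactTest(matrix(c(8, 0, 1, 3), 2))  # 0.0182
#' @export
fisherExactTest <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("cells must be non-negative integers")
  if (sum(tab) == 0) stop("table must have at least one positive margin")
  tab <- round(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(support, c1, c2, r1)
  pObs <- dhyper(tab[1, 1], c1, c2, r1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Replication test: hierarchical clustering versus genotype
#'
#' Clusters samples by Euclidean distance on a gene subset (agglomerative,
#' average linkage by default), cuts the tree at k = 2, cross-tabulates the
#' two clusters against the genotype labels, and evaluates the association
#' with the two-sided Fisher exact test.
#'
#' @param exprVst transformed expression matrix (genes x samples).
#' @param genotypes named character vector (`"mut"`/`"wt"`) covering the
#'   columns of `exprVst`.
#' @param geneSubset gene identifiers to cluster on (e.g. a signature set);
#'   intersected with the matrix rows.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list with `assignments` (named cluster ids), `table` (2x2
#'   genotype x cluster contingency table) and `p` (Fisher exact p-value).
#' @export
replicationClusterTest <- function(exprVst, genotypes, geneSubset,
                                   linkage = "average") {
  ids <- colnames(exprVst)
  if (length(ids) < 4) stop("need at least 4 samples")
  g <- genotypes[ids]
  if (anyNA(g)) stop("genotypes missing for some samples")
  if (!all(g %in% c("mut", "wt"))) stop("genotypes must be 'mut' or 'wt'")
  if (length(unique(g)) < 2) stop("both genotypes must be present")
  genes <- intersect(geneSubset, rownames(exprVst))
  if (!length(genes)) stop("gene subset does not overlap the expression matrix")
  cl <- cutree(hclust(dist(t(exprVst[genes, , drop = FALSE])),
                      method = linkage), k = 2)
  if (length(unique(cl)) < 2)
    stop("degenerate clustering: one cluster is empty")
  tab <- table(factor(g, c("mut", "wt")), factor(cl, 1:2),
               dnn = c("genotype", "cluster"))
  list(assignments = setNames(as.integer(cl), ids),
       table = unclass(tab), p = fisherExactTest(tab))
}
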