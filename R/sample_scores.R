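# Per-tumor significance against the normal baseline, and the Jaccard
# coherence comparison between mutation-defined tumor groups.

#' Per-sample z-scores against the normal-tissue baseline
#'
#' For every tumor and gene, `z = (value - mean(normals)) / sd(normals)` on
#' the VST scale, using the sample standard deviation (n - 1).  Per-gene sds
#' are floored at the 5th percentile of all positive per-gene normal sds so
#' near-constant genes cannot produce unbounded z.  A gene is flagged when
#' `|z| >= zThreshold` (boundary inclusive; study threshold 2.5).
#'
#' @param exprVst transformed expression matrix (genes x samples), e.g. from
#'   [vstTransform()].
#' @param samples sample table with `sample_id`, `tissue`, `group`.
#' @param zThreshold absolute z needed to flag a gene.
#' @return a [SampleSignificance-class] for the tumor samples.
#' @export
perSampleZscores <- function(exprVst, samples, zThreshold = 2.5) {
  .validateSampleTable(samples)
  if (zThreshold <= 0) stop("zThreshold must be positive")
  normIds <- intersect(colnames(exprVst),
                       samples$sample_id[samples$tissue == "normal"])
  tumIds <- intersect(colnames(exprVst),
                      samples$sample_id[samples$tissue == "tumor"])
  if (length(normIds) < 3)
    stop("need at least 3 normal samples for the baseline (found ",
         length(normIds), ")")
  if (!length(tumIds)) stop("no tumor samples in the expression matrix")
  xb <- exprVst[, normIds, drop = FALSE]
  mn <- rowMeans(xb)
  sdn <- apply(xb, 1, sd)
  if (all(sdn == 0))
    stop("all genes have zero variance across normals; cannot standardize")
  sdFloor <- quantile(sdn[sdn > 0], 0.05, names = FALSE)
  sdn <- pmax(sdn, sdFloor)
  z <- (exprVst[, tumIds, drop = FALSE] - mn) / sdn
  up <- lapply(seq_along(tumIds), function(j) rownames(z)[z[, j] >= zThreshold])
  dn <- lapply(seq_along(tumIds), function(j) rownames(z)[z[, j] <= -zThreshold])
  new("SampleSignificance", z = z, threshold = zThreshold,
      upSets = setNames(up, tumIds), downSets = setNames(dn, tumIds))
}

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty (documented
#' convention).
#'
#' @param a,b character vectors of gene identifiers.
#' @return numeric scalar in \[0,1\].
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Pairwise Jaccard for a logical membership matrix (genes x samples).
.pairwiseJaccard <- function(memb) {
  inter <- crossprod(memb)
  sizes <- colSums(memb)
  uni <- outer(sizes, sizes, "+") - inter
  J <- ifelse(uni > 0, inter / pmax(uni, 1), 0)
  diag(J) <- 1
  J
}

#' Compare within-group and between-group Jaccard coherence
#'
#' Computes the Jaccard similarity of flagged-gene sets for every tumor
#' pair, partitions the pairs into within-mut, within-wt and between cells,
#' and tests - one-sidedly, for each group - whether within-group scores
#' exceed between-group scores.  The default is a group-label permutation
#' test (statistic: mean within minus mean between), which respects the
#' dependence among pairwise scores; Mann-Whitney U on the pair scores is
#' available as a legacy option.
#'
#' @param sig a [SampleSignificance-class].
#' @param samples sample table with `sample_id`, `tissue`, `group`.
#' @param setType which flagged sets to compare: `"all"` (union), `"up"`,
#'   or `"down"`.
#' @param method `"permutation"` or `"mwu"`.
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutation draw.
#' @return a [JaccardComparison-class].
#' @export
compareGroupSimilarity <- function(sig, samples,
                                   setType = c("all", "up", "down"),
                                   method = c("permutation", "mwu"),
                                   nPerm = 999, seed = 1L) {
  stopifnot(is(sig, "SampleSignificance"))
  .validateSampleTable(samples)
  setType <- match.arg(setType)
  method <- match.arg(method)
  z <- zscoreMatrix(sig); thr <- sig@threshold
  ids <- colnames(z)
  grp <- samples$group[match(ids, samples$sample_id)]
  if (anyNA(grp)) stop("tumor samples missing from the sample table")
  if (sum(grp == "mut") < 2 || sum(grp == "wt") < 2)
    stop("need at least 2 tumors per group")

  memb <- switch(setType,
                 all = abs(z) >= thr,
                 up = z >= thr,
                 down = z <= -thr)
  J <- .pairwiseJaccard(memb)
  n <- length(ids)
  pr <- which(upper.tri(J), arr.ind = TRUE)
  jac <- J[upper.tri(J)]

  partitionOf <- function(g) {
    gi <- g[pr[, 1]]; gj <- g[pr[, 2]]
    ifelse(gi == "mut" & gj == "mut", "within_mut",
           ifelse(gi == "wt" & gj == "wt", "within_wt", "between"))
  }
  statOf <- function(part) {
    btw <- mean(jac[part == "between"])
    c(mut = mean(jac[part == "within_mut"]) - btw,
      wt = mean(jac[part == "within_wt"]) - btw)
  }
  part <- partitionOf(grp)
  obs <- statOf(part)

  if (method == "permutation") {
    set.seed(seed)
    hits <- c(mut = 0L, wt = 0L)
    for (b in seq_len(nPerm)) {
      ps <- statOf(partitionOf(sample(grp)))
      hits <- hits + (ps >= obs - 1e-12)
    }
    pMut <- (1 + hits[["mut"]]) / (nPerm + 1)
    pWt <- (1 + hits[["wt"]]) / (nPerm + 1)
  } else {
    pMut <- wilcox.test(jac[part == "within_mut"], jac[part == "between"],
                        alternative = "greater", exact = FALSE)$p.value
    pWt <- wilcox.test(jac[part == "within_wt"], jac[part == "between"],
                       alternative = "greater", exact = FALSE)$p.value
    nPerm <- 0L
  }
  pairScores <- data.frame(sample1 = ids[pr[, 1]], sample2 = ids[pr[, 2]],
                           partition = part, jaccard = jac,
                           stringsAsFactors = FALSE)
  new("JaccardComparison", pairScores = pairScores,
      pWithinMut = pMut, pWithinWt = pWt, method = method,
      nPerm = as.integer(nPerm))
}
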