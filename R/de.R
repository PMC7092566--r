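# Normalization, transforms, and the negative-binomial Wald test.  The DE
# test is a deliberately simple NB fit: per-group means on normalized counts,
# method-of-moments dispersion shrunk halfway toward a fitted 1/mu trend,
# and a Wald p-value on the log2 fold change.  No outlier replacement,
# independent filtering, or fold-change shrinkage.

.countsFrom <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
}

#' Median-of-ratios size factors
#'
#' Per-sample factor: the median, over genes with non-zero counts in every
#' sample, of the ratio of the sample's count to the gene's geometric mean
#' across samples.
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @return named numeric vector of positive size factors.
#' @examples
#' m <- cbind(A = c(10L, 20L), B = c(20L, 40L))
#' rownames(m) <- c("g1", "g2")
#' computeSizeFactors(m)  # (1/sqrt(2), sqrt(2))
#' @export
computeSizeFactors <- function(counts) {
  counts <- .countsFrom(counts)
  allPos <- rowSums(counts == 0) == 0
  if (!any(allPos))
    stop("no gene has non-zero counts in every sample; ",
         "filter samples or genes before normalization")
  pos <- counts[allPos, , drop = FALSE]
  geo <- exp(rowMeans(log(pos)))
  sf <- apply(pos / geo, 2, median)
  setNames(sf, colnames(counts))
}

#' Transcripts per million
#'
#' Length-corrected relative expression: per sample,
#' `(count / length) / sum(count / length) * 1e6`.  Columns sum to 1e6
#' whenever the sample has any count; an all-zero sample yields all-zero
#' TPM (documented convention).
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @param lengths per-gene lengths in bp, named or ordered as `counts` rows.
#' @return numeric matrix of TPM values.
#' @export
tpm <- function(counts, lengths) {
  counts <- .countsFrom(counts)
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
      stop("lengths missing for genes: ",
           paste(head(miss, 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop("need one length per gene")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  out <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  out[, tot == 0] <- 0
  out
}

#' Variance-stabilizing transform
#'
#' `log2(count / sizeFactor + 1)`: monotone in the count, flattens the NB
#' mean-variance relationship at high expression; used for clustering,
#' embeddings and per-sample z-scores.
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @param sizeFactors per-sample size factors; computed by
#'   [computeSizeFactors()] when omitted.
#' @return numeric matrix on the log2 scale.
#' @export
vstTransform <- function(counts, sizeFactors = NULL) {
  counts <- .countsFrom(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (length(sizeFactors) != ncol(counts) || any(sizeFactors <= 0))
    stop("need one positive size factor per sample")
  log2(sweep(counts, 2, sizeFactors, "/") + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted q-values, capped at 1, order-preserving on ties.
#'
#' @param p vector of p-values in \[0,1\] (no NAs).
#' @return vector of q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Significance call from effect size and q-value
#'
#' A gene is `up` iff `log2fc >= lfcThreshold` and `q < qThreshold`
#' (boundary log2fc inclusive), `down` symmetrically, otherwise `ns`.
#' Defaults are the study thresholds: |log2FC| >= 1 and q < 0.01.
#'
#' @param log2fc,q vectors of effects and FDR-adjusted p-values.
#' @param lfcThreshold,qThreshold call thresholds.
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
callDE <- function(log2fc, q, lfcThreshold = 1, qThreshold = 0.01) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0,1]")
  out <- rep("ns", length(log2fc))
  out[q < qThreshold & log2fc >= lfcThreshold] <- "up"
  out[q < qThreshold & log2fc <= -lfcThreshold] <- "down"
  out
}

# Method-of-moments dispersion with 50/50 shrinkage toward a fitted
# alpha(mu) = a0 + a1/mu trend, floored.
.dispersionEstimate <- function(mom, mu, floor = 1e-8) {
  ok <- is.finite(mom) & mom > 0 & mu > 0.5
  trend <- if (sum(ok) >= 10) {
    fit <- tryCatch(lm(mom[ok] ~ I(1 / mu[ok])), error = function(e) NULL)
    if (is.null(fit)) rep(median(mom[ok]), length(mu))
    else coef(fit)[1] + coef(fit)[2] / mu
  } else {
    rep(if (any(ok)) median(mom[ok]) else floor, length(mu))
  }
  trend <- pmax(trend, floor)
  pmax(0.5 * pmax(mom, 0) + 0.5 * trend, floor)
}

#' Negative-binomial Wald test for differential expression
#'
#' Compares two sample groups on median-of-ratios-normalized counts.  Per
#' gene: group means, a method-of-moments NB dispersion shrunk 50/50 toward
#' a least-squares `a0 + a1/mu` trend (floored at `dispersionFloor`), the
#' log2 fold change `log2((caseMean + eps) / (controlMean + eps))` with
#' pseudocount `eps = 0.5` normalized counts, and a Wald p-value from the
#' delta-method standard error of the log2 fold change.  q-values are
#' Benjamini-Hochberg; calls use [callDE()] with the study thresholds.
#'
#' Genes with zero counts in all selected samples are removed before
#' testing (set `dropAllZero = FALSE` to keep a fixed gene universe, e.g.
#' for per-cluster contrasts; such genes get log2fc 0 and p 1).
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @param samples sample table with `sample_id`, `tissue`, `group`.
#' @param case,control labels selecting the two groups; a sample matches a
#'   label through either its `tissue` or its `group` column (so `"tumor"`,
#'   `"normal"`, `"mut"`, `"wt"` all work).
#' @param lfcThreshold,qThreshold call thresholds (study defaults 1, 0.01).
#' @param pseudocount `eps` added to group means in the fold change.
#' @param dispersionFloor lower bound on the shrunk dispersion.
#' @param dropAllZero drop genes with all-zero counts across the selected
#'   samples before testing.
#' @return a [DEResult-class] with one row per tested gene.
#' @export
nbWaldTest <- function(counts, samples, case, control,
                       lfcThreshold = 1, qThreshold = 0.01,
                       pseudocount = 0.5, dispersionFloor = 1e-8,
                       dropAllZero = TRUE) {
  counts <- .countsFrom(counts)
  .validateSampleTable(samples)
  pick <- function(label) {
    samples$sample_id[samples$tissue == label | samples$group == label]
  }
  caseIds <- intersect(colnames(counts), pick(case))
  ctrlIds <- intersect(colnames(counts), pick(control))
  if (length(intersect(caseIds, ctrlIds)))
    stop("case and control groups overlap")
  if (length(caseIds) < 2 || length(ctrlIds) < 2)
    stop("need at least 2 samples per group (case '", case, "': ",
         length(caseIds), ", control '", control, "': ", length(ctrlIds), ")")
  m <- counts[, c(caseIds, ctrlIds), drop = FALSE]
  if (dropAllZero) m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("no genes left after removing unexpressed genes")

  sf <- computeSizeFactors(m)
  norm <- sweep(m, 2, sf, "/")
  isCase <- colnames(m) %in% caseIds
  n1 <- sum(isCase); n0 <- sum(!isCase)
  x1 <- norm[, isCase, drop = FALSE]; x0 <- norm[, !isCase, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1, var); v0 <- apply(x0, 1, var)
  s2w <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  muBar <- (n1 * m1 + n0 * m0) / (n1 + n0)
  cbar <- mean(1 / sf)  # counting-noise inflation of normalized counts
  mom <- (s2w - muBar * cbar) / muBar^2
  alpha <- .dispersionEstimate(mom, muBar, floor = dispersionFloor)

  lfc <- log2((m1 + pseudocount) / (m0 + pseudocount))
  c1 <- sum(1 / sf[isCase]); c0 <- sum(1 / sf[!isCase])
  mm1 <- m1 + pseudocount; mm0 <- m0 + pseudocount
  varMean1 <- mm1 * c1 / n1^2 + alpha * mm1^2 / n1
  varMean0 <- mm0 * c0 / n0^2 + alpha * mm0^2 / n0
  seLfc <- sqrt(varMean1 / mm1^2 + varMean0 / mm0^2) / log(2)
  z <- lfc / seLfc
  p <- 2 * pnorm(-abs(z))
  p[rowSums(m) == 0] <- 1  # untested fixed-universe genes
  q <- bhAdjust(p)
  call <- callDE(lfc, q, lfcThreshold, qThreshold)

  df <- DataFrame(baseMean = muBar, log2FoldChange = lfc, pvalue = p,
                  padj = q, call = call, row.names = rownames(m))
  .DEResult(df, case = case, control = control,
            lfcThreshold = lfcThreshold, qThreshold = qThreshold)
}
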