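# Sample embeddings and resampling-based consensus clustering.

.checkExpr <- function(expr, nDims = NULL) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (!is.null(nDims) && nDims > ncol(expr) - 1)
    stop("nDims must be at most samples - 1")
  expr
}

#' Principal component embedding of samples
#'
#' Samples are the observations, genes the variables (centered per gene,
#' unscaled).  Deterministic up to the sign of each component.
#'
#' @param expr transformed expression matrix, genes x samples.
#' @param nDims number of components to keep (at most samples - 1).
#' @return an [EmbeddingResult-class] with per-dimension explained-variance
#'   fractions.
#' @export
pcaEmbed <- function(expr, nDims = 2) {
  expr <- .checkExpr(expr, nDims)
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("EmbeddingResult",
      coordinates = pc$x[, seq_len(nDims), drop = FALSE],
      explainedVariance = ev[seq_len(nDims)], method = "pca")
}

#' Classical multidimensional scaling of samples
#'
#' Classical (Torgerson) MDS on Euclidean sample-sample distances; for
#' Euclidean input this reproduces PCA coordinates up to rotation and sign.
#'
#' @inheritParams pcaEmbed
#' @return an [EmbeddingResult-class] (no explained-variance fractions).
#' @export
mdsEmbed <- function(expr, nDims = 2) {
  expr <- .checkExpr(expr, nDims)
  coords <- cmdscale(dist(t(expr)), k = nDims)
  if (ncol(coords) < nDims) {  # degenerate geometry: pad zero dimensions
    pad <- matrix(0, nrow(coords), nDims - ncol(coords))
    coords <- cbind(coords, pad)
  }
  rownames(coords) <- colnames(expr)
  new("EmbeddingResult", coordinates = coords,
      explainedVariance = numeric(0), method = "mds")
}

#' Consensus clustering by repeated subsampling
#'
#' Repeats agglomerative clustering (Euclidean distance, configurable
#' linkage) on random sample subsets and records, for every sample pair, the
#' fraction of co-sampled resamples in which the pair co-clustered.  Final
#' assignments cut an agglomerative tree of `1 - consensus` into `k` groups;
#' the item consensus of a sample is its mean consensus with the other
#' members of its assigned cluster (1 for singletons).
#'
#' Features are restricted to the `nFeatures` most variable rows, a
#' stability aid for small cohorts; set `nFeatures = Inf` for genome-wide
#' clustering.
#'
#' @param expr transformed expression matrix, genes x samples.
#' @param k number of clusters (samples must exceed k).
#' @param nResamples number of subsampling rounds (study default 1000).
#' @param subsampleFrac fraction of samples drawn (without replacement)
#'   per round.
#' @param seed integer seed.
#' @param nFeatures number of top-variance feature rows used.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(expr, k, nResamples = 1000, subsampleFrac = 0.8,
                             seed = 1L, nFeatures = 2000,
                             linkage = "average") {
  expr <- .checkExpr(expr)
  n <- ncol(expr)
  k <- as.integer(k)
  if (n < k + 1) stop("need more samples than clusters")
  m <- as.integer(ceiling(subsampleFrac * n))
  if (m < k) stop("subsample of ", m, " samples is too small to cut into ",
                  k, " clusters")
  if (is.finite(nFeatures) && nrow(expr) > nFeatures) {
    rv <- apply(expr, 1, var)
    expr <- expr[order(rv, decreasing = TRUE)[seq_len(nFeatures)], ,
                 drop = FALSE]
  }
  x <- t(expr)

  set.seed(seed)
  coSampled <- matrix(0, n, n)
  coClustered <- matrix(0, n, n)
  for (b in seq_len(nResamples)) {
    idx <- sample.int(n, m)
    cl <- cutree(hclust(dist(x[idx, , drop = FALSE]), method = linkage), k)
    coSampled[idx, idx] <- coSampled[idx, idx] + 1
    coClustered[idx, idx] <- coClustered[idx, idx] + outer(cl, cl, "==")
  }
  cons <- ifelse(coSampled > 0, coClustered / pmax(coSampled, 1), 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(expr), colnames(expr))

  assign <- cutree(hclust(as.dist(1 - cons), method = linkage), k)
  ic <- vapply(seq_len(n), function(i) {
    mates <- which(assign == assign[i] & seq_len(n) != i)
    if (!length(mates)) 1 else mean(cons[i, mates])
  }, numeric(1))
  new("ConsensusResult", consensusMatrix = cons,
      assignments = setNames(as.integer(assign), colnames(expr)),
      itemConsensus = setNames(ic, colnames(expr)),
      k = k, nResamples = as.integer(nResamples))
}
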