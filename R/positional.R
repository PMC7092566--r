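# Positional scan: gene positions, sliding windows, hypergeometric
# over-representation of directional DE calls, Bonferroni control, and
# merging of significant windows into regions.  All coordinates 0-based
# half-open; a gene exactly at a window end belongs to the next window.

#' Assign each gene a single genomic position
#'
#' Position = mean, over the gene's transcripts, of the transcript midpoint
#' `(start + end) / 2`.  A gene with transcripts on more than one chromosome
#' is an error.
#'
#' @param transcripts data.frame from [readAnnotation()] (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @return data.frame (`gene_id`, `chrom`, `position`), one row per gene,
#'   ordered by gene id.
#' @export
assignGenePositions <- function(transcripts) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% colnames(transcripts)))
    stop("transcripts must have columns: ", paste(need, collapse = ", "))
  nChrom <- tapply(transcripts$chrom, transcripts$gene_id,
                   function(x) length(unique(x)))
  multi <- names(nChrom)[nChrom > 1]
  if (length(multi))
    stop("gene(s) with transcripts on multiple chromosomes: ",
         paste(head(multi, 10), collapse = ", "))
  mid <- (transcripts$start + transcripts$end) / 2
  pos <- tapply(mid, transcripts$gene_id, mean)
  chrom <- tapply(transcripts$chrom, transcripts$gene_id, `[`, 1)
  ord <- sort(names(pos))
  data.frame(gene_id = ord, chrom = as.character(chrom[ord]),
             position = as.numeric(pos[ord]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Tile chromosomes with overlapping sliding windows
#'
#' Windows of `width` starting every `step` bp from 0 while the start lies
#' inside the chromosome; trailing windows are truncated at the chromosome
#' end, not dropped.  The study design is 1 Mb windows overlapping by
#' 750 kb, i.e. a 250 kb step, so every interior base lies in exactly
#' `width / step = 4` windows.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param width window width in bp.
#' @param step distance between window starts in bp (`width - overlap`).
#' @return data.frame (`chrom`, `start`, `end`), 0-based half-open.
#' @export
makeSlidingWindows <- function(chromLengths, width = 1e6, step = 2.5e5) {
  if (!(width > step && step > 0)) stop("need width > step > 0")
  if (is.null(names(chromLengths)) || any(chromLengths <= 0))
    stop("chromLengths must be a named vector of positive lengths")
  out <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(0, by = step, length.out = ceiling(len / step))
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N population, K marked, n drawn)`;
#' `P(X >= 0) = 1`.  Vectorized over its arguments.
#'
#' @param k observed marked items in the draw.
#' @param n draw size.
#' @param K marked items in the population.
#' @param N population size.
#' @return upper-tail probability in (0, 1\].
#' @export
hypergeomTail <- function(k, n, K, N) {
  v <- cbind(k = k, n = n, K = K, N = N)
  if (any(v < 0) || any(v[, "k"] > v[, "n"]) || any(v[, "n"] > v[, "N"]) ||
      any(v[, "k"] > v[, "K"]) || any(v[, "K"] > v[, "N"]))
    stop("require 0 <= k <= n <= N and k <= K <= N")
  unname(phyper(v[, "k"] - 1, v[, "K"], v[, "N"] - v[, "K"], v[, "n"],
                lower.tail = FALSE))
}

# Shared universe bookkeeping for scan and region merging.
.scanUniverse <- function(positions, de, direction) {
  universe <- intersect(positions$gene_id, rownames(de))
  if (!length(universe))
    stop("no gene has both a position and a DE record")
  dropped <- length(positions$gene_id) - length(universe)
  if (dropped > 0)
    message(dropped, " positioned gene(s) absent from the DE table were dropped")
  called <- intersect(rownames(de)[de$call == direction], universe)
  pos <- positions[positions$gene_id %in% universe, ]
  pos$called <- pos$gene_id %in% called
  list(pos = pos, N = length(universe), K = length(called))
}

#' Sliding-window scan for positional over-representation
#'
#' For each window: `n` = genes whose assigned position falls in
#' `[start, end)`, `k` = those called in the given direction; the p-value is
#' the hypergeometric upper tail against the scan universe (genes with both
#' a position and a DE record, `K` of them called).  A window is significant
#' when `p < alpha / (number of windows in this scan)` (Bonferroni).
#'
#' @param positions data.frame from [assignGenePositions()].
#' @param de a [DEResult-class].
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param direction `"up"` or `"down"`.
#' @param alpha family-wise error target (default 0.05).
#' @param width,step window geometry (defaults 1 Mb / 250 kb).
#' @return a [WindowScan-class].
#' @export
scanWindows <- function(positions, de, chromLengths,
                        direction = c("up", "down"), alpha = 0.05,
                        width = 1e6, step = 2.5e5) {
  direction <- match.arg(direction)
  miss <- setdiff(unique(positions$chrom), names(chromLengths))
  if (length(miss))
    stop("no length provided for chromosome(s): ", paste(miss, collapse = ", "))
  u <- .scanUniverse(positions, de, direction)
  win <- makeSlidingWindows(chromLengths, width, step)

  win$nGenes <- 0L
  win$nDirection <- 0L
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    p <- u$pos$position[u$pos$chrom == ch]
    pc <- u$pos$position[u$pos$chrom == ch & u$pos$called]
    win$nGenes[wi] <- vapply(wi, function(i)
      sum(p >= win$start[i] & p < win$end[i]), integer(1))
    win$nDirection[wi] <- vapply(wi, function(i)
      sum(pc >= win$start[i] & pc < win$end[i]), integer(1))
  }
  win$pHyper <- hypergeomTail(win$nDirection, win$nGenes, u$K, u$N)
  nTested <- nrow(win)
  win$significant <- win$pHyper < alpha / nTested
  new("WindowScan", windows = win, direction = direction, alpha = alpha,
      universeSize = as.integer(u$N), nCalled = as.integer(u$K))
}

#' Merge overlapping significant windows into regions
#'
#' Significant windows on one chromosome that overlap or are adjacent are
#' merged into their union interval; gene and directional counts are
#' re-counted over the union and the region p-value is recomputed from the
#' hypergeometric tail with the same scan universe.
#'
#' @param scan a [WindowScan-class].
#' @param positions,de the inputs the scan was run on.
#' @return data.frame (`chrom`, `start`, `end`, `nGenes`, `nDirection`,
#'   `pRegion`, `direction`); zero rows when no window is significant.
#' @export
mergeSignificantRegions <- function(scan, positions, de) {
  stopifnot(is(scan, "WindowScan"))
  u <- suppressMessages(.scanUniverse(positions, de, scan@direction))
  sig <- scan@windows[scan@windows$significant, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), nGenes = integer(0),
                      nDirection = integer(0), pRegion = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    curS <- s$start[1]; curE <- s$end[1]
    flush <- function(S, E) {
      inR <- u$pos$chrom == ch & u$pos$position >= S & u$pos$position < E
      n <- sum(inR); k <- sum(inR & u$pos$called)
      data.frame(chrom = ch, start = S, end = E, nGenes = n, nDirection = k,
                 pRegion = hypergeomTail(k, n, u$K, u$N),
                 direction = scan@direction, stringsAsFactors = FALSE)
    }
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        if (s$start[i] <= curE) {
          curE <- max(curE, s$end[i])
        } else {
          out[[length(out) + 1]] <- flush(curS, curE)
          curS <- s$start[i]; curE <- s$end[i]
        }
      }
    }
    out[[length(out) + 1]] <- flush(curS, curE)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write merged regions as BED
#'
#' Columns: chrom, start, end, name (`group_direction`), score
#' (`-log10 pRegion`, capped at 1000).
#'
#' @param regions data.frame from [mergeSignificantRegions()].
#' @param path output path.
#' @param group label used in the name column.
#' @export
writeRegionsBed <- function(regions, path, group = "tumor") {
  lines <- if (nrow(regions)) {
    sprintf("%s\t%d\t%d\t%s_%s\t%.4g", regions$chrom,
            as.integer(regions$start), as.integer(regions$end),
            group, regions$direction,
            pmin(1000, -log10(pmax(regions$pRegion, 1e-300))))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
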