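# Hypergeometric over-representation of a dysregulated-gene list against a
# GMT collection, with Benjamini-Hochberg control across sets.

#' Gene-set over-representation analysis
#'
#' For each set: members are restricted to the universe, and the p-value is
#' the hypergeometric upper tail of drawing at least the observed overlap
#' when `|query|` genes are drawn from the universe containing the
#' restricted set.  q-values are Benjamini-Hochberg across all sets; rows
#' are sorted by q, then p, then set name.  Query genes outside the
#' universe are dropped with a warning.  Matching is exact and
#' case-sensitive; set `uppercase = TRUE` to match human-ortholog
#' collections case-insensitively.
#'
#' @param query character vector of gene identifiers (e.g. DE calls).
#' @param sets a [GeneSetCollection-class].
#' @param universe character vector of background gene identifiers
#'   (typically the tested gene universe of the DE table).
#' @param uppercase uppercase query, sets and universe before matching.
#' @return data.frame with one row per set: `setName`, `setSize` (raw),
#'   `setSizeInUniverse`, `overlapSize`, `universeSize`, `querySize`,
#'   `pHyper`, `q`, and list-column `overlapMembers`.
#' @export
overrepresentation <- function(query, sets, universe, uppercase = FALSE) {
  stopifnot(is(sets, "GeneSetCollection"))
  if (!length(universe)) stop("universe must be non-empty")
  toKey <- if (uppercase) toupper else identity
  universe <- unique(toKey(universe))
  query <- unique(toKey(query))
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe were dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("query is empty (after universe restriction)")
  n <- length(query); N <- length(universe)
  members <- lapply(geneSets(sets), function(m) intersect(toKey(m), universe))
  K <- vapply(members, length, integer(1))
  overlap <- lapply(members, intersect, query)
  k <- vapply(overlap, length, integer(1))
  p <- hypergeomTail(k, rep(n, length(K)), K, rep(N, length(K)))
  q <- bhAdjust(p)
  res <- data.frame(setName = names(geneSets(sets)),
                    setSize = vapply(geneSets(sets), length, integer(1)),
                    setSizeInUniverse = K, overlapSize = k,
                    universeSize = N, querySize = n,
                    pHyper = p, q = q, stringsAsFactors = FALSE,
                    row.names = NULL)
  res$overlapMembers <- unname(lapply(overlap, sort))
  res[order(res$q, res$pHyper, res$setName), , drop = FALSE]
}

#' Top-k enrichment rows
#'
#' First `min(k, nrow)` rows of an over-representation table (already
#' sorted by q, then p, then name - the study reports the top ten by
#' q-value).
#'
#' @param rows data.frame from [overrepresentation()].
#' @param k number of rows to keep.
#' @return truncated data.frame.
#' @export
topEnrichment <- function(rows, k = 10) {
  if (k < 0) stop("k must be non-negative")
  head(rows, min(k, nrow(rows)))
}
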