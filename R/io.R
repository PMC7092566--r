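# Readers and writers for the external formats the pipeline touches.
# Internal coordinate convention: 0-based half-open everywhere; GTF (1-based
# inclusive) is converted on read.  Strand is ignored throughout.

.validateCounts <- function(counts, where = "count matrix") {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(where, ": gene and sample identifiers are required")
  dupg <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dupg))
    stop(where, ": duplicated gene ids: ", paste(dupg, collapse = ", "))
  dups <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dups))
    stop(where, ": duplicated sample ids: ", paste(dups, collapse = ", "))
  if (nrow(counts) < 1 || ncol(counts) < 2)
    stop(where, ": need at least 1 gene and 2 samples")
  if (any(is.na(counts)))
    stop(where, ": missing values are not allowed")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(where, sprintf(": negative count at gene '%s', sample '%s'",
                        rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  invisible(counts)
}

.validateSampleTable <- function(samples) {
  need <- c("sample_id", "tissue", "group")
  if (!all(need %in% colnames(samples)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup))
    stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  if (!all(samples$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if (!all(samples$group[samples$tissue == "normal"] == "none"))
    stop("normal samples must have group 'none'")
  if (!all(samples$group[samples$tissue == "tumor"] %in% c("mut", "wt")))
    stop("tumor samples must have group 'mut' or 'wt'")
  invisible(samples)
}

#' Read a gene-level count matrix
#'
#' Reads a tab-delimited table whose first column holds gene identifiers and
#' whose header row holds sample identifiers.  Entries are validated
#' (numeric, non-negative, no duplicated identifiers) and coerced to integer.
#'
#' @param path path to a TSV file.
#' @return integer matrix, genes x samples, with dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0\t5", "g2\t3\t7"), tf)
#' readCounts(tf)
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("count table needs a gene column plus >= 2 samples")
  ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                   ids[bad], colnames(vals)[j]))
    }
  }
  counts <- as.matrix(vals)
  storage.mode(counts) <- "double"
  rownames(counts) <- ids
  .validateCounts(counts, where = path)
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `tissue` (`tumor`/`normal`), `group` (`mut`/`wt`
#' for tumors, `none` for normals).
#'
#' @param path path to a TSV file.
#' @return data.frame with the three validated columns.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  samples <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  .validateSampleTable(samples)
  samples
}

#' Assemble counts and sample metadata into a SummarizedExperiment
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample table (`sample_id`, `tissue`, `group`) covering
#'   every column of `counts`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` and `tissue`/`group` columns in `colData`.
#' @export
CountExperiment <- function(counts, samples) {
  .validateCounts(counts)
  .validateSampleTable(samples)
  m <- match(colnames(counts), samples$sample_id)
  if (anyNA(m))
    stop("samples missing from metadata: ",
         paste(colnames(counts)[is.na(m)], collapse = ", "))
  cd <- DataFrame(tissue = samples$tissue[m], group = samples$group[m],
                  row.names = colnames(counts))
  SummarizedExperiment(assays = list(counts = counts), colData = cd)
}

.tsv4colAnnotation <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% colnames(tab)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  tab[need]
}

.gtfAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"type" %in% colnames(md)) stop("GTF lacks a feature type column")
  tx <- gr[md$type %in% c("transcript", "mRNA")]
  if (length(tx) == 0) stop("GTF contains no transcript features")
  gid <- S4Vectors::mcols(tx)$gene_id
  if (is.null(gid) || anyNA(gid) || any(gid == ""))
    stop("GTF transcript feature lacks a gene_id attribute")
  # GTF is 1-based inclusive; internal convention is 0-based half-open.
  data.frame(gene_id = as.character(gid),
             chrom = as.character(GenomicRanges::seqnames(tx)),
             start = GenomicRanges::start(tx) - 1L,
             end = GenomicRanges::end(tx),
             stringsAsFactors = FALSE)
}

#' Read transcript annotation
#'
#' Accepts Ensembl-flavor GTF (one record per `transcript` feature, the
#' `gene_id` attribute is required; coordinates converted from 1-based
#' inclusive to the internal 0-based half-open convention) or a 4-column TSV
#' dialect (`gene_id`, `chrom`, `start`, `end`, already 0-based half-open).
#'
#' @param path annotation file.
#' @param dialect `"auto"` (by extension), `"gtf"`, or `"tsv"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`; one
#'   row per transcript.
#' @export
readAnnotation <- function(path, dialect = c("auto", "gtf", "tsv")) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(gtf|gff[23]?)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  tab <- if (dialect == "gtf") .gtfAnnotation(path) else .tsv4colAnnotation(path)
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (any(tab$chrom == "" | is.na(tab$chrom))) stop("empty chromosome name")
  bad <- tab$end <= tab$start
  if (any(bad))
    stop("transcript with end <= start for gene(s): ",
         paste(unique(tab$gene_id[bad]), collapse = ", "))
  tab
}

#' Mean transcript length per gene
#'
#' Average of transcript lengths (`end - start`) per gene, the length used
#' for TPM normalization.
#'
#' @param annotation data.frame from [readAnnotation()].
#' @return named numeric vector of mean lengths in bp.
#' @export
geneLengths <- function(annotation) {
  len <- annotation$end - annotation$start
  out <- tapply(len, annotation$gene_id, mean)
  setNames(as.numeric(out), names(out))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  Members are deduplicated.
#'
#' @param path path to the GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(GeneSetCollection(setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicated set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), nms)
  GeneSetCollection(sets, setNames(desc, nms))
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGmt <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, setDescriptions(gsc)[[nm]], geneSets(gsc)[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result as TSV
#'
#' Tab-delimited with header, no quoting.  Row names, when informative, are
#' emitted as a leading `gene_id` column so that the file round-trips.  List
#' columns (e.g. overlap members) are collapsed with `","`.  Output is
#' deterministic: two writes of the same object are byte-identical.
#'
#' @param x data.frame or DataFrame.
#' @param path output path.
#' @param rowNamesAs column name under which to emit row names (default
#'   `"gene_id"`; set `NULL` to drop).
#' @export
writeResultTable <- function(x, path, rowNamesAs = "gene_id") {
  df <- as.data.frame(x, optional = TRUE)
  isList <- vapply(df, is.list, logical(1))
  for (j in which(isList))
    df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","),
                      character(1))
  hasNames <- !is.null(rownames(x)) &&
    !identical(rownames(x), as.character(seq_len(nrow(df))))
  if (hasNames && !is.null(rowNamesAs)) {
    df <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                         rowNamesAs), df)
  }
  con <- file(path, open = "wb")  # fixed EOL across platforms
  on.exit(close(con))
  write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
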