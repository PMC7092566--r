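# Config-driven orchestration: simulate or ingest -> DE -> cluster ->
# z-score/Jaccard -> discriminate -> scan -> enrich, with a machine-readable
# run summary (file checksums) and deterministic behavior under a single
# global seed fanned out to fixed per-stage offsets.

.stageOrder <- c("simulate", "de", "cluster", "zscore", "jaccard",
                 "discriminate", "scan", "enrich")
.stageSeedOffset <- c(simulate = 0L, de = 101L, cluster = 202L,
                      zscore = 303L, jaccard = 404L, discriminate = 505L,
                      scan = 606L, enrich = 707L)

.defaultConfig <- function() {
  list(
    out_dir = ".",
    seed = 1L,
    stages = .stageOrder,
    inputs = list(counts = NULL, samples = NULL, annotation = NULL,
                  gmt = NULL),
    simulation = list(),
    thresholds = list(lfc = 1, q = 0.01, z = 2.5, unchanged_band = 0.5,
                      alpha = 0.05),
    clustering = list(k = 2L, resamples = 1000L, subsample_frac = 0.8,
                      n_features = 2000L),
    jaccard = list(n_perm = 999L, method = "permutation"),
    scan = list(width = 1e6, step = 2.5e5),
    enrich = list(top = 10L)
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else
      base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Unset fields take the study defaults (thresholds |log2FC| >= 1,
#' q < 0.01, |z| >= 2.5, unchanged band 0.5, alpha 0.05, k = 2, 1000
#' resamples).  When the `simulate` stage is disabled, the referenced input
#' files must exist.
#'
#' @param path path to a YAML file.
#' @return validated config list (class `RunConfig`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .mergeConfig(.defaultConfig(), user)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as produced by YAML parsing).
#' @export
validateRunConfig <- function(cfg) {
  cfg <- .mergeConfig(.defaultConfig(), cfg)
  bad <- setdiff(cfg$stages, .stageOrder)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$stages <- .stageOrder[.stageOrder %in% cfg$stages]
  th <- cfg$thresholds
  if (th$q <= 0 || th$q > 1) stop("q threshold must lie in (0,1]")
  if (th$alpha <= 0 || th$alpha > 1) stop("alpha must lie in (0,1]")
  if (th$lfc < 0 || th$z <= 0 || th$unchanged_band < 0)
    stop("thresholds out of range")
  if (!"simulate" %in% cfg$stages) {
    for (nm in c("counts", "samples")) {
      if (is.null(cfg$inputs[[nm]]))
        stop("input '", nm, "' required when simulation is disabled")
      if (!file.exists(cfg$inputs[[nm]]))
        stop("input file not found: ", cfg$inputs[[nm]])
    }
  }
  if (is.null(cfg$seed)) stop("a seed is required")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.needs <- function(state, what, stage) {
  if (is.null(state[[what]]))
    stop("stage '", stage, "' requires missing artifact '", what,
         "' (enable the producing stage or provide it as input)")
  state[[what]]
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order:
#' `simulate` (or ingest the configured inputs), `de` (tumor-vs-normal and
#' per-cluster NB Wald tests), `cluster` (consensus clustering of tumors on
#' the VST scale), `zscore`, `jaccard`, `discriminate`, `scan` (positional
#' windows per cluster and direction, merged regions as BED), `enrich`.
#' Every output file is written under `out_dir` and check-summed into
#' `run_summary.json`; identical config and seed reproduce identical
#' checksums.  A stage failure aborts the run with the stage named and
#' leaves a `<stage>.partial` marker.
#'
#' @param config a config list (see [readRunConfig()]); may be a path to a
#'   YAML file.
#' @return (invisibly) the run summary list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- validateRunConfig(config)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  state <- new.env(parent = emptyenv())
  summary <- list(seed = cfg$seed, stages = list(), files = list())
  outPath <- function(f) file.path(outDir, f)
  record <- function(stage, files) {
    summary$stages[[stage]] <<- list(outputs = basename(files))
    for (f in files)
      summary$files[[basename(f)]] <<- unname(md5sum(f))
  }
  runStage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      file.create(outPath(paste0(stage, ".partial")))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))
    record(stage, files)
  }
  stageSeed <- function(stage) cfg$seed + .stageSeedOffset[[stage]]

  ## ingest or simulate -----------------------------------------------------
  if ("simulate" %in% cfg$stages) {
    runStage("simulate", function() {
      design <- do.call(SimulationDesign,
                        c(cfg$simulation, list(seed = stageSeed("simulate"))))
      sim <- simulateCounts(design)
      state$counts <- sim$counts
      state$samples <- sim$samples
      state$truth <- sim$truth
      state$annotation <- simulateAnnotation(design, sim$truth)
      state$gmt <- simulateGeneSets(sim$truth, seed = stageSeed("simulate"))
      state$chromLengths <- setNames(rep(design@chromLength, design@nChroms),
                                     paste0("chr", seq_len(design@nChroms)))
      writeCounts(sim$counts, outPath("counts.tsv"))
      writeResultTable(sim$samples, outPath("samples.tsv"), rowNamesAs = NULL)
      writeResultTable(state$annotation, outPath("annotation.tsv"),
                       rowNamesAs = NULL)
      writeResultTable(sim$truth$genes, outPath("truth.tsv"),
                       rowNamesAs = NULL)
      writeGmt(state$gmt, outPath("sets.gmt"))
      outPath(c("counts.tsv", "samples.tsv", "annotation.tsv", "truth.tsv",
                "sets.gmt"))
    })
  } else {
    state$counts <- readCounts(cfg$inputs$counts)
    state$samples <- readSampleTable(cfg$inputs$samples)
    if (!is.null(cfg$inputs$annotation))
      state$annotation <- readAnnotation(cfg$inputs$annotation)
    if (!is.null(cfg$inputs$gmt))
      state$gmt <- readGmt(cfg$inputs$gmt)
    if (!is.null(cfg$inputs$chrom_lengths)) {
      cl <- read.delim(cfg$inputs$chrom_lengths, header = FALSE,
                       stringsAsFactors = FALSE)
      state$chromLengths <- setNames(as.numeric(cl[[2]]), cl[[1]])
    } else if (!is.null(state$annotation)) {
      state$chromLengths <- tapply(state$annotation$end,
                                   state$annotation$chrom, max)
    }
  }

  ## differential expression ------------------------------------------------
  if ("de" %in% cfg$stages) {
    runStage("de", function() {
      counts <- .needs(state, "counts", "de")
      samples <- .needs(state, "samples", "de")
      state$deAll <- nbWaldTest(counts, samples, "tumor", "normal",
                                lfcThreshold = th$lfc, qThreshold = th$q)
      files <- outPath("de_tumor_vs_normal.tsv")
      writeResultTable(state$deAll, files[1])
      if (all(c("mut", "wt") %in% samples$group)) {
        de2 <- perClusterDE(counts, samples, lfcThreshold = th$lfc,
                            qThreshold = th$q)
        state$deMut <- de2$mut
        state$deWt <- de2$wt
        writeResultTable(de2$mut, outPath("de_mut_vs_normal.tsv"))
        writeResultTable(de2$wt, outPath("de_wt_vs_normal.tsv"))
        files <- c(files, outPath(c("de_mut_vs_normal.tsv",
                                    "de_wt_vs_normal.tsv")))
      }
      files
    })
  }

  vstOf <- function() {
    if (is.null(state$vst))
      state$vst <- vstTransform(.needs(state, "counts", "transform"))
    state$vst
  }

  ## consensus clustering ---------------------------------------------------
  if ("cluster" %in% cfg$stages) {
    runStage("cluster", function() {
      samples <- .needs(state, "samples", "cluster")
      v <- vstOf()
      tum <- samples$sample_id[samples$tissue == "tumor"]
      cc <- consensusCluster(v[, tum, drop = FALSE], k = cfg$clustering$k,
                             nResamples = cfg$clustering$resamples,
                             subsampleFrac = cfg$clustering$subsample_frac,
                             nFeatures = cfg$clustering$n_features,
                             seed = stageSeed("cluster"))
      state$consensus <- cc
      emb <- pcaEmbed(v[, tum, drop = FALSE],
                      nDims = min(3, length(tum) - 1))
      writeResultTable(as.data.frame(consensusMatrix(cc)),
                       outPath("consensus_matrix.tsv"),
                       rowNamesAs = "sample_id")
      writeResultTable(data.frame(sample_id = tum,
                                  cluster = clusterAssignments(cc),
                                  item_consensus = itemConsensus(cc)),
                       outPath("cluster_assignments.tsv"), rowNamesAs = NULL)
      writeResultTable(as.data.frame(embeddingCoordinates(emb)),
                       outPath("embedding_pca.tsv"), rowNamesAs = "sample_id")
      outPath(c("consensus_matrix.tsv", "cluster_assignments.tsv",
                "embedding_pca.tsv"))
    })
  }

  ## per-sample z-scores ----------------------------------------------------
  if ("zscore" %in% cfg$stages) {
    runStage("zscore", function() {
      samples <- .needs(state, "samples", "zscore")
      state$zscores <- perSampleZscores(vstOf(), samples, zThreshold = th$z)
      writeResultTable(as.data.frame(zscoreMatrix(state$zscores)),
                       outPath("zscores.tsv"))
      sets <- significantGeneSets(state$zscores)
      writeLines(vapply(names(sets), function(s)
        paste(c(s, sets[[s]]), collapse = "\t"), character(1)),
        outPath("significant_sets.tsv"))
      outPath(c("zscores.tsv", "significant_sets.tsv"))
    })
  }

  ## Jaccard coherence ------------------------------------------------------
  if ("jaccard" %in% cfg$stages) {
    runStage("jaccard", function() {
      sig <- .needs(state, "zscores", "jaccard")
      samples <- .needs(state, "samples", "jaccard")
      jc <- compareGroupSimilarity(sig, samples,
                                   method = cfg$jaccard$method,
                                   nPerm = cfg$jaccard$n_perm,
                                   seed = stageSeed("jaccard"))
      state$jaccard <- jc
      writeResultTable(jc@pairScores, outPath("jaccard_pairs.tsv"),
                       rowNamesAs = NULL)
      jsonlite::write_json(
        list(p_within_mut_vs_between = jc@pWithinMut,
             p_within_wt_vs_between = jc@pWithinWt,
             method = jc@method, n_perm = jc@nPerm),
        outPath("jaccard_comparison.json"), auto_unbox = TRUE, digits = NA)
      outPath(c("jaccard_pairs.tsv", "jaccard_comparison.json"))
    })
  }

  ## discriminating genes ---------------------------------------------------
  if ("discriminate" %in% cfg$stages) {
    runStage("discriminate", function() {
      deMut <- .needs(state, "deMut", "discriminate")
      deWt <- .needs(state, "deWt", "discriminate")
      cls <- classifyGenes(deMut, deWt, band = th$unchanged_band)
      state$classification <- cls
      writeResultTable(cls, outPath("gene_classification.tsv"),
                       rowNamesAs = NULL)
      outPath("gene_classification.tsv")
    })
  }

  ## positional scan --------------------------------------------------------
  if ("scan" %in% cfg$stages) {
    runStage("scan", function() {
      ann <- .needs(state, "annotation", "scan")
      chromLengths <- .needs(state, "chromLengths", "scan")
      pos <- assignGenePositions(ann)
      deTables <- list()
      if (!is.null(state$deMut)) deTables$mut <- state$deMut
      if (!is.null(state$deWt)) deTables$wt <- state$deWt
      if (!length(deTables))
        deTables$tumor <- .needs(state, "deAll", "scan")
      files <- character(0)
      state$regions <- list()
      for (grp in names(deTables)) {
        for (dir in c("up", "down")) {
          sc <- suppressMessages(
            scanWindows(pos, deTables[[grp]], chromLengths, direction = dir,
                        alpha = th$alpha, width = cfg$scan$width,
                        step = cfg$scan$step))
          reg <- mergeSignificantRegions(sc, pos, deTables[[grp]])
          state$regions[[paste(grp, dir, sep = "_")]] <- reg
          f1 <- outPath(sprintf("scan_%s_%s.tsv", grp, dir))
          f2 <- outPath(sprintf("regions_%s_%s.bed", grp, dir))
          writeResultTable(scanWindowsTable(sc), f1, rowNamesAs = NULL)
          writeRegionsBed(reg, f2, group = grp)
          files <- c(files, f1, f2)
        }
      }
      files
    })
  }

  ## gene-set enrichment ----------------------------------------------------
  if ("enrich" %in% cfg$stages) {
    runStage("enrich", function() {
      gmt <- .needs(state, "gmt", "enrich")
      de <- .needs(state, "deAll", "enrich")
      query <- rownames(de)[de$call != "ns"]
      res <- overrepresentation(query, gmt, universe = rownames(de))
      state$enrichment <- res
      writeResultTable(topEnrichment(res, cfg$enrich$top),
                       outPath("enrichment_top.tsv"), rowNamesAs = NULL)
      writeResultTable(res, outPath("enrichment_all.tsv"), rowNamesAs = NULL)
      outPath(c("enrichment_top.tsv", "enrichment_all.tsv"))
    })
  }

  jsonlite::write_json(summary, outPath("run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
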