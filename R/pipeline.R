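#' End-to-end selection-scan pipeline
#'
#' Chains the stages (align/filter -> branch-model dN/dS, MK test,
#' property test -> consensus -> dual-set enrichment) over a set of
#' ortholog clusters, with per-cluster failure isolation and a manifest
#' recording inputs, seed and outputs.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param study a [simulateStudy()] result providing in-memory inputs;
#'   alternatively supply `clustersDir`/`speciesMap`/`treePath` (and
#'   optionally `polyPath`, `goMapPath`) to read from files.
#' @param clustersDir directory of per-cluster FASTA files.
#' @param speciesMap named character (pattern -> species) for
#'   [readClusterFasta()].
#' @param treePath Newick file.
#' @param polyPath polymorphism TSV (optional; enables the MK stage).
#' @param goMapPath GO map TSV (optional; enables enrichment).
#' @param mkPair character(2): species pair for the MK test; defaults to
#'   the first cherry (two leaves sharing a parent) of the tree.
#' @param divergenceMax divergence filter threshold (default 0.10).
#' @param fdr FDR threshold for the branch-model calls (default 0.05).
#' @param minDepth,minMaf MK SNP-calling thresholds.
#' @param window,impactMin,minCodons,pMax property-test parameters.
#' @param step property-test window step (default 1).
#' @param alpha enrichment FDR threshold (default 0.05).
#' @param starts optimizer starts per codon-model fit.
#' @param outDir optional output directory for stage TSVs + manifest.
#' @param seed run-level seed recorded in the manifest and applied before
#'   any stochastic stage.
#' @return configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(study = NULL, clustersDir = NULL,
                           speciesMap = NULL, treePath = NULL,
                           polyPath = NULL, goMapPath = NULL,
                           mkPair = NULL, divergenceMax = 0.10,
                           fdr = 0.05, minDepth = 10, minMaf = 0.2,
                           window = 20L, step = 1L, impactMin = 6L,
                           minCodons = 2L, pMax = 0.001, alpha = 0.05,
                           starts = 3L, outDir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(study) && (is.null(clustersDir) || is.null(treePath)))
    stop("either a study object or clustersDir + treePath is required")
  cfg
}

.firstCherry <- function(tree) {
  tr <- treePhylo(tree)
  ntip <- length(tr$tip.label)
  par <- tr$edge[tr$edge[, 2] <= ntip, ]
  tabs <- table(par[, 1])
  cherries <- as.integer(names(tabs)[tabs == 2L])
  if (!length(cherries)) return(NULL)
  kids <- sort(tr$tip.label[tr$edge[tr$edge[, 1] == cherries[1] &
                                      tr$edge[, 2] <= ntip, 2]])
  kids
}

#' Run the selection-scan pipeline
#'
#' Executes the stages in dependency order. A failure inside one cluster
#' (alignment error, internal stop, non-fitting model) marks that cluster
#' failed in the manifest without aborting the run.
#'
#' @param config a [pipelineConfig()].
#' @return list with `alignments`, `divergence`, `paml` (tests + calls),
#'   `treesaap` (calls, windows kept per cluster), `mk` (table), `calls`
#'   (merged call rows), `consensus`, `enrichment`, `failed`
#'   (data.frame cluster/stage/message) and `manifest`.
#' @export
runPipeline <- function(config) {
  set.seed(config$seed)
  failed <- data.frame(cluster_id = character(), stage = character(),
                       message = character())
  fail <- function(id, stage, e) {
    failed <<- rbind(failed, data.frame(cluster_id = id, stage = stage,
                                        message = conditionMessage(e)))
    NULL
  }

  # ---- inputs ----
  if (!is.null(config$study)) {
    st <- config$study
    clusters <- st$clusters
    tree <- st$tree
    poly <- st$poly
    annotations <- st$annotations
  } else {
    tree <- readSpeciesTree(config$treePath)
    files <- sort(list.files(config$clustersDir, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
    spMap <- config$speciesMap
    if (is.null(spMap)) {
      sp <- speciesNames(tree)
      spMap <- setNames(sp, sp)
    }
    clusters <- list()
    for (f in files) {
      cl <- tryCatch(readClusterFasta(f, spMap),
                     error = function(e) fail(basename(f), "read", e))
      if (!is.null(cl)) clusters[[clusterId(cl)]] <- cl
    }
    poly <- if (!is.null(config$polyPath))
      readPolymorphismTable(config$polyPath) else NULL
    annotations <- if (!is.null(config$goMapPath))
      readGoAnnotations(config$goMapPath) else NULL
  }

  # ---- align + filter ----
  alignments <- list()
  for (cl in clusters) {
    a <- tryCatch(alignCluster(cl),
                  error = function(e) fail(clusterId(cl), "align", e))
    if (!is.null(a)) alignments[[clusterId(a)]] <- a
  }
  flt <- filterClusters(alignments, config$divergenceMax)
  kept <- flt$kept
  divergence <- data.frame(
    cluster_id = vapply(alignments, clusterId, character(1)),
    divergence = vapply(alignments, meanDivergence, numeric(1)),
    kept = names(alignments) %in% names(kept), row.names = NULL)

  treeSpecies <- sort(speciesNames(tree))

  # ---- branch-model fits ----
  fits <- list()
  for (aln in kept) {
    if (!setequal(speciesNames(aln), treeSpecies)) next
    f <- tryCatch({
      one <- fitCodonModel(aln, tree, "one_ratio", starts = config$starts)
      free <- fitCodonModel(aln, tree, "free_ratio",
                            starts = config$starts, init = one)
      list(one = one, free = free)
    }, error = function(e) fail(clusterId(aln), "dnds", e))
    if (!is.null(f)) fits[[clusterId(aln)]] <- f
  }
  paml <- if (length(fits)) callPamlPositive(fits, config$fdr) else
    list(tests = NULL, calls = NULL)

  # ---- property test ----
  tsCalls <- list(); tsWindows <- list()
  for (id in names(fits)) {
    ts <- tryCatch(
      treesaapScan(alignments[[id]], tree, fits[[id]]$one,
                   window = config$window, step = config$step,
                   minCodons = config$minCodons, pMax = config$pMax,
                   impactMin = config$impactMin),
      error = function(e) fail(id, "aaprops", e))
    if (!is.null(ts)) {
      tsCalls[[id]] <- ts$calls
      tsWindows[[id]] <- ts$windows
    }
  }
  treesaap <- list(calls = if (length(tsCalls)) do.call(rbind, tsCalls),
                   windows = tsWindows)

  # ---- MK test ----
  mk <- NULL
  if (!is.null(poly)) {
    pair <- config$mkPair
    if (is.null(pair)) pair <- .firstCherry(tree)
    if (!is.null(pair)) {
      mkAlns <- list()
      for (aln in kept) {
        if (!all(pair %in% speciesNames(aln))) next
        mkAlns[[clusterId(aln)]] <- restrictAlignment(aln, pair)
      }
      if (length(mkAlns))
        mk <- mkTestClusters(mkAlns, poly, pair,
                             minDepth = config$minDepth,
                             minMaf = config$minMaf)
    }
  }

  # ---- consensus ----
  callRows <- list()
  if (!is.null(paml$calls))
    callRows$paml <- paml$calls[, c("cluster_id", "method", "branch", "positive")]
  if (!is.null(treesaap$calls))
    callRows$treesaap <- treesaap$calls[, c("cluster_id", "method", "branch", "positive")]
  if (!is.null(mk))
    callRows$mk <- mk[, c("cluster_id", "method", "branch", "positive")]
  calls <- if (length(callRows)) do.call(rbind, c(callRows, make.row.names = FALSE))
  consensus <- if (!is.null(calls)) mergeCalls(calls)

  # ---- enrichment ----
  enrichment <- NULL
  if (!is.null(annotations) && !is.null(consensus)) {
    universe <- names(alignments)
    selectedIds <- consensus$perCluster$cluster_id
    enrichment <- dualSetEnrichment(selectedIds, universe, annotations,
                                    config$alpha)
  }

  res <- list(alignments = alignments, divergence = divergence,
              paml = paml, treesaap = treesaap, mk = mk, calls = calls,
              consensus = consensus, enrichment = enrichment,
              failed = failed)
  res$manifest <- .writeOutputs(res, config)
  res
}

.writeOutputs <- function(res, config) {
  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("orthoselect")),
                   n_clusters = nrow(res$divergence),
                   n_kept = sum(res$divergence$kept),
                   n_failed = nrow(res$failed),
                   params = config[c("divergenceMax", "fdr", "minDepth",
                                     "minMaf", "window", "step", "impactMin",
                                     "minCodons", "pMax", "alpha", "starts")])
  out <- config$outDir
  if (is.null(out)) return(manifest)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(NULL)
    p <- file.path(out, name)
    data.table::fwrite(df, p, sep = "\t")
    p
  }
  paths <- c(
    divergence = wr(res$divergence, "divergence.tsv"),
    paml_tests = wr(res$paml$tests, "paml_tests.tsv"),
    paml_calls = wr(res$paml$calls, "paml_calls.tsv"),
    treesaap_calls = wr(res$treesaap$calls, "treesaap_calls.tsv"),
    mk = wr(res$mk, "mk.tsv"),
    calls = wr(res$calls, "calls.tsv"),
    failed = wr(res$failed, "failed.tsv"))
  if (!is.null(res$consensus)) {
    p <- file.path(out, "consensus.json")
    jsonlite::write_json(res$consensus$summary, p, auto_unbox = TRUE)
    paths <- c(paths, consensus = p)
    wr(res$consensus$perCluster, "consensus_clusters.tsv")
  }
  if (!is.null(res$enrichment)) {
    wr(res$enrichment$selected, "enrichment_selected.tsv")
    wr(res$enrichment$unselected, "enrichment_unselected.tsv")
    p <- file.path(out, "enrichment_filter.json")
    jsonlite::write_json(res$enrichment$filter, p)
    paths <- c(paths, enrichment_filter = p)
  }
  manifest$outputs <- as.list(paths)
  manifest$digests <- as.list(tools::md5sum(unlist(paths)))
  mPath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE)
  manifest
}
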