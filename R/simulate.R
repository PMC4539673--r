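#' Synthetic study generator
#'
#' Simulates the inputs the pipeline consumes with the statistical
#' structure the analysis assumes: codon sequences evolved along a fixed
#' species tree under branch-specific omega, within-species polymorphism
#' overlaid at the leaves (with allele frequencies and read depths), and
#' GO annotations with planted enrichment among the selected clusters.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults describe a four-species study: a sister pair plus two
#' successively deeper outgroups, background purifying selection
#' (omega = 0.2), a designated branch under positive selection
#' (omega = 4) in a fraction of clusters, moderate transcriptome-like
#' read depths (negative-binomial, mean 30) and a nucleotide polymorphism
#' density of one heterozygous site per ~100 nt.
#'
#' @param nClusters number of ortholog clusters.
#' @param codonsPerCluster codons per cluster.
#' @param tree Newick string with branch lengths in expected
#'   substitutions per codon; internal nodes may be labelled.
#' @param kappa transition/transversion ratio.
#' @param omegaBackground omega on all branches of unselected clusters
#'   (and non-selected branches of selected ones).
#' @param omegaSelected omega on the selected branch of selected clusters.
#' @param selectedBranch branch label carrying the elevated omega;
#'   defaults to the terminal branch of the first species.
#' @param selectedFraction fraction of clusters carrying the elevated
#'   omega.
#' @param theta expected polymorphic nucleotide sites per codon and
#'   species.
#' @param mafRange range of simulated minor allele frequencies.
#' @param depthMean,depthDispersion negative-binomial read-depth model
#'   (mean and size).
#' @param termPoolSize,termsPerCluster GO model: pool size and uniform
#'   terms drawn per cluster.
#' @param plantedTerms GO ids planted preferentially in selected clusters.
#' @param plantedBaseRate probability of a planted term in an unselected
#'   cluster.
#' @param plantedOdds multiplier on that probability (capped at 1) for
#'   selected clusters.
#' @param codonFreqs stationary codon frequencies (default uniform over
#'   the sense codons).
#' @param seed run-level random seed.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nClusters = 100L,
                             codonsPerCluster = 150L,
                             tree = "(((sp1:0.06,sp2:0.06)n7:0.03,sp3:0.09)n6:0.02,sp4:0.11)n5;",
                             kappa = 2,
                             omegaBackground = 0.2,
                             omegaSelected = 4,
                             selectedBranch = NULL,
                             selectedFraction = 0.1,
                             theta = 0.03,
                             mafRange = c(0.1, 0.5),
                             depthMean = 30,
                             depthDispersion = 5,
                             termPoolSize = 50L,
                             termsPerCluster = 3L,
                             plantedTerms = "GO:0000001",
                             plantedBaseRate = 0.08,
                             plantedOdds = 10,
                             codonFreqs = NULL,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$nClusters >= 1, cfg$codonsPerCluster >= 1,
            cfg$kappa > 0, cfg$omegaBackground >= 0, cfg$omegaSelected >= 0,
            cfg$selectedFraction >= 0, cfg$selectedFraction <= 1,
            cfg$theta >= 0, cfg$depthMean > 0, cfg$depthDispersion > 0)
  phy <- ape::read.tree(text = cfg$tree)
  if (is.null(phy)) stop("invalid Newick in config")
  cfg$speciesTree <- speciesTreeFromPhylo(phy)
  labs <- branchLabels(cfg$speciesTree)
  if (is.null(cfg$selectedBranch)) {
    firstTip <- sort(treePhylo(cfg$speciesTree)$tip.label)[1]
    cfg$selectedBranch <- labs[endsWith(labs, paste0("-> ", firstTip))][1]
  }
  if (!cfg$selectedBranch %in% labs)
    stop("selectedBranch not a branch of the tree: ", cfg$selectedBranch)
  if (is.null(cfg$codonFreqs)) {
    sc <- senseCodons()
    cfg$codonFreqs <- setNames(rep(1 / length(sc), length(sc)), sc)
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

# sample child states along one branch given parent states
.evolveBranch <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- states == s
    out[idx] <- sample.int(ncol(P), sum(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate one ortholog cluster
#'
#' Draws root codons from the stationary distribution, evolves them along
#' the rooted tree under the branch-specific omega map, overlays
#' within-species polymorphism at the leaves and emits the consensus
#' sequences plus depth/allele-count rows. Uses the current RNG state
#' (seed management belongs to [simulateStudy()]).
#'
#' @param config a [simulationConfig()].
#' @param clusterIndex index used to build the cluster id.
#' @param selected logical: does this cluster carry the elevated omega on
#'   the selected branch?
#' @return list with `cluster` ([OrthologCluster]), `polyRows`
#'   (data.frame of polymorphism-table rows) and `truth` (one-row
#'   data.frame).
#' @export
simulateCluster <- function(config, clusterIndex = 1L, selected = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  cid <- sprintf("cluster%04d", clusterIndex)
  tre <- treePhylo(config$speciesTree)
  prep <- .prepTree(tre, unroot = FALSE)
  sc <- names(config$codonFreqs)
  pi <- config$codonFreqs
  ncod <- config$codonsPerCluster

  omega <- setNames(rep(config$omegaBackground, length(prep$labels)),
                    prep$labels)
  if (selected && config$selectedBranch %in% prep$labels)
    omega[config$selectedBranch] <- config$omegaSelected

  # transition matrices per edge (cached per distinct omega x length)
  states <- vector("list", prep$nNode)
  states[[prep$root]] <- sample.int(length(sc), ncod, replace = TRUE,
                                    prob = pi)
  for (e in rev(seq_len(nrow(prep$edge)))) {   # parent-first order
    par <- prep$edge[e, 1]; ch <- prep$edge[e, 2]
    P <- codonTransitionMatrix(config$kappa, unname(omega[prep$labels[e]]),
                               pi, prep$edgeLen[e])
    states[[ch]] <- .evolveBranch(states[[par]], P)
  }

  tips <- prep$phylo$tip.label
  seqs <- vapply(seq_along(tips), function(t)
    paste(sc[states[[t]]], collapse = ""), character(1))
  names(seqs) <- tips

  # polymorphism overlay: infinite-sites style, independent across
  # positions and species
  polyRows <- list()
  nPoly <- 0L
  nNt <- 3L * ncod
  for (sp in tips) {
    isPoly <- runif(nNt) < config$theta / 3
    pos <- which(isPoly)
    if (!length(pos)) next
    chars <- strsplit(seqs[[sp]], "")[[1]]
    depth <- rnbinom(length(pos), mu = config$depthMean,
                     size = config$depthDispersion)
    maf <- runif(length(pos), config$mafRange[1], config$mafRange[2])
    minorCount <- rbinom(length(pos), depth, maf)
    minorCount <- pmin(minorCount, depth %/% 2L)  # consensus stays major
    majorCount <- depth - minorCount
    # minor alleles arise from the same kappa-biased mutation process as
    # divergence, so the MK test's neutral expectation holds by design
    minorNt <- vapply(pos, function(p) {
      alt <- setdiff(.NUCS, chars[p])
      w <- ifelse(.isTransition(chars[p], alt), config$kappa, 1)
      sample(alt, 1L, prob = w)
    }, character(1))
    cnt <- matrix(0L, length(pos), 4L, dimnames = list(NULL, .NUCS))
    cnt[cbind(seq_along(pos), match(chars[pos], .NUCS))] <- majorCount
    cnt[cbind(seq_along(pos), match(minorNt, .NUCS))] <-
      cnt[cbind(seq_along(pos), match(minorNt, .NUCS))] + minorCount
    polyRows[[length(polyRows) + 1L]] <- data.frame(
      species = sp, cluster_id = cid, column_index = pos - 1L,
      depth = depth, count_A = cnt[, "A"], count_C = cnt[, "C"],
      count_G = cnt[, "G"], count_T = cnt[, "T"], row.names = NULL)
    nPoly <- nPoly + length(pos)
  }
  polyRows <- if (length(polyRows)) do.call(rbind, polyRows)
    else data.frame(species = character(), cluster_id = character(),
                    column_index = integer(), depth = integer(),
                    count_A = integer(), count_C = integer(),
                    count_G = integer(), count_T = integer())

  truth <- data.frame(cluster_id = cid, selected = selected,
                      selected_branch = config$selectedBranch,
                      omega_background = config$omegaBackground,
                      omega_selected = if (selected) config$omegaSelected
                                       else config$omegaBackground,
                      n_poly_sites = nPoly, row.names = NULL)
  list(cluster = orthologCluster(cid, seqs), polyRows = polyRows,
       truth = truth)
}

#' Simulate GO annotations with planted enrichment
#'
#' Every cluster receives a uniform draw of background terms; each
#' planted term is additionally assigned with probability
#' `plantedBaseRate` to unselected and `min(1, plantedBaseRate *
#' plantedOdds)` to selected clusters.
#'
#' @param clusterIds all cluster ids.
#' @param selectedIds ids of the selected clusters.
#' @param termPoolSize,termsPerCluster,plantedTerms,plantedBaseRate,plantedOdds
#'   see [simulationConfig()].
#' @return named list: cluster id -> GO ids.
#' @export
simulateGoAnnotations <- function(clusterIds, selectedIds,
                                  termPoolSize = 50L, termsPerCluster = 3L,
                                  plantedTerms = "GO:0000001",
                                  plantedBaseRate = 0.08,
                                  plantedOdds = 10) {
  pool <- setdiff(sprintf("GO:%07d", seq_len(termPoolSize + length(plantedTerms))),
                  plantedTerms)[seq_len(termPoolSize)]
  pSel <- min(1, plantedBaseRate * plantedOdds)
  ann <- lapply(clusterIds, function(id) {
    terms <- sample(pool, min(termsPerCluster, length(pool)))
    p <- if (id %in% selectedIds) pSel else plantedBaseRate
    planted <- plantedTerms[runif(length(plantedTerms)) < p]
    sort(unique(c(terms, planted)))
  })
  setNames(ann, clusterIds)
}

#' Simulate a full study
#'
#' Simulates `nClusters` clusters (a seeded random fraction carrying the
#' elevated omega on the designated branch), the polymorphism table, GO
#' annotations with planted enrichment, and the truth table. All
#' randomness flows from `config$seed`. With `dir` set, the exact file
#' formats the pipeline consumes are written (per-cluster FASTA,
#' polymorphism TSV, GO map TSV, tree Newick, truth TSV).
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory.
#' @return list with `clusters` (list of [OrthologCluster]), `poly`
#'   ([PolymorphismTable]), `annotations`, `truth` (data.frame),
#'   `tree` ([SpeciesTree]) and `config`; with `dir`, also `paths`.
#' @export
simulateStudy <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$nClusters
  nSel <- round(config$selectedFraction * n)
  selected <- rep(FALSE, n)
  if (nSel > 0) selected[sample.int(n, nSel)] <- TRUE

  sims <- lapply(seq_len(n), function(i)
    simulateCluster(config, i, selected[i]))
  clusters <- lapply(sims, `[[`, "cluster")
  names(clusters) <- vapply(clusters, clusterId, character(1))
  polyRows <- do.call(rbind, lapply(sims, `[[`, "polyRows"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  ann <- simulateGoAnnotations(truth$cluster_id,
                               truth$cluster_id[truth$selected],
                               config$termPoolSize, config$termsPerCluster,
                               config$plantedTerms, config$plantedBaseRate,
                               config$plantedOdds)
  poly <- suppressWarnings(polymorphismTable(polyRows))
  out <- list(clusters = clusters, poly = poly, annotations = ann,
              truth = truth, tree = config$speciesTree, config = config)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "clusters"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(
      clusters = vapply(clusters, function(cl)
        writeClusterFasta(cl, file.path(dir, "clusters",
                                        paste0(clusterId(cl), ".fasta"))),
        character(1)),
      poly = writePolymorphismTable(poly, file.path(dir, "poly.tsv")),
      annotations = writeGoAnnotations(ann, file.path(dir, "go_map.tsv")),
      tree = {
        p <- file.path(dir, "tree.nwk")
        ape::write.tree(treePhylo(config$speciesTree), p)
        p
      },
      truth = {
        p <- file.path(dir, "truth.tsv")
        data.table::fwrite(truth, p, sep = "\t")
        p
      })
    out$paths <- paths
  }
  out
}
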