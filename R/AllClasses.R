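#' @title Core data containers
#' @description S4 classes holding the units the pipeline operates on:
#' an ortholog cluster of unaligned coding sequences, a labelled species
#' tree, an in-frame codon alignment, a per-position polymorphism table,
#' McDonald-Kreitman count cells, and a fitted codon model.
#' @name orthoselect-classes
NULL

#' Ortholog cluster of coding sequences
#'
#' One cluster of putatively orthologous, unaligned coding nucleotide
#' sequences, one per species, optionally annotated with GO terms.
#'
#' @slot clusterId single cluster identifier.
#' @slot sequences [Biostrings::DNAStringSet] named by species; ungapped
#'   5'->3' coding sequence, alphabet restricted to A,C,G,T,N.
#' @slot goTerms character vector of GO identifiers (may be empty).
#' @exportClass OrthologCluster
setClass("OrthologCluster",
  representation(clusterId = "character",
                 sequences = "DNAStringSet",
                 goTerms   = "character"))

setValidity("OrthologCluster", function(object) {
  msg <- character()
  if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
    msg <- c(msg, "clusterId must be a single non-empty string")
  if (length(object@sequences) < 2L)
    msg <- c(msg, "cluster must contain sequences for at least 2 species")
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "sequences must be uniquely named by species")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "all sequences must have length > 0")
  bad <- .badAlphabet(object@sequences, c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence alphabet outside {A,C,G,T,N} for: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

.badAlphabet <- function(xss, allowed) {
  freq <- Biostrings::alphabetFrequency(xss)
  extra <- setdiff(colnames(freq), allowed)
  names(xss)[rowSums(freq[, extra, drop = FALSE]) > 0]
}

#' Species tree with labelled branches
#'
#' A rooted binary tree over the species under analysis. Internal nodes
#' carry labels (auto-assigned n1, n2, ... in post-order when missing) and
#' every edge has a derived label "parent -> child".
#'
#' @slot tree an [ape::phylo] object with complete internal node labels.
#' @exportClass SpeciesTree
setClass("SpeciesTree", representation(tree = "ANY"))

setValidity("SpeciesTree", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("tree must be an ape 'phylo' object")
  if (length(tr$tip.label) < 2L) return("tree must have at least 2 leaves")
  if (anyDuplicated(c(tr$tip.label, tr$node.label)))
    return("tip and node labels must be unique")
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label)))
    return("all internal nodes must be labelled")
  TRUE
})

#' In-frame codon alignment of one ortholog cluster
#'
#' Gapped coding sequences of equal length, a multiple of 3, with gaps only
#' in whole-codon triples; codon k spans columns [3k, 3k+3) (0-based).
#'
#' @slot clusterId single cluster identifier.
#' @slot rows [Biostrings::DNAStringSet] named by species, over
#'   {A,C,G,T,N,-}.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(clusterId = "character", rows = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  w <- Biostrings::width(object@rows)
  if (length(object@rows) < 2L)
    msg <- c(msg, "alignment needs at least 2 rows")
  if (length(unique(w)) > 1L)
    msg <- c(msg, "all rows must have equal length")
  if (length(w) && w[1] %% 3L != 0L)
    msg <- c(msg, "alignment length must be a multiple of 3")
  nm <- names(object@rows)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "rows must be uniquely named by species")
  bad <- .badAlphabet(object@rows, c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    msg <- c(msg, paste0("row alphabet outside {A,C,G,T,N,-} for: ",
                         paste(bad, collapse = ", ")))
  # gaps only in whole-codon triples
  if (length(w) && w[1] %% 3L == 0L) {
    m <- .alnCharMatrix(object)
    nc <- ncol(m) / 3L
    for (r in seq_len(nrow(m))) {
      g <- matrix(m[r, ] == "-", nrow = 3L)
      part <- colSums(g)
      if (any(part > 0L & part < 3L)) {
        msg <- c(msg, paste0("row ", nm[r], " has a partial-codon gap"))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

.alnCharMatrix <- function(aln) {
  rows <- if (is(aln, "CodonAlignment")) aln@rows else aln
  m <- do.call(rbind, strsplit(as.character(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Per-position polymorphism table
#'
#' Read depth and allele counts per (species, cluster, alignment column);
#' alignment columns are 0-based. Positions absent from the table are
#' treated as monomorphic with unknown depth by consumers.
#'
#' @slot data a `data.table` with columns `species`, `cluster_id`,
#'   `column_index`, `depth`, `count_A`, `count_C`, `count_G`, `count_T`,
#'   keyed by the first three.
#' @exportClass PolymorphismTable
setClass("PolymorphismTable", representation(data = "ANY"))

setValidity("PolymorphismTable", function(object) {
  d <- object@data
  need <- c("species", "cluster_id", "column_index", "depth",
            "count_A", "count_C", "count_G", "count_T")
  if (!data.table::is.data.table(d)) return("data must be a data.table")
  if (!all(need %in% names(d)))
    return(paste0("missing columns: ", paste(setdiff(need, names(d)), collapse = ", ")))
  num <- d[, c("depth", "count_A", "count_C", "count_G", "count_T")]
  if (any(vapply(num, function(x) any(x < 0), logical(1))))
    return("negative depths or allele counts")
  TRUE
})

#' McDonald-Kreitman count cells
#'
#' The four cells of the codon-level MK test: fixed non-synonymous (Dn),
#' fixed synonymous (Ds), polymorphic non-synonymous (Pn) and polymorphic
#' synonymous (Ps). Multi-hit codons are counted by averaging over minimal
#' mutational pathways, so cells may be fractional.
#'
#' @slot dn,ds,pn,ps non-negative numeric counts.
#' @slot nCodons number of complete codons inspected.
#' @slot noDataFrac fraction of inspected positions with sub-threshold
#'   read depth.
#' @exportClass MKCounts
setClass("MKCounts",
  representation(dn = "numeric", ds = "numeric",
                 pn = "numeric", ps = "numeric",
                 nCodons = "numeric", noDataFrac = "numeric"),
  prototype(dn = 0, ds = 0, pn = 0, ps = 0, nCodons = 0, noDataFrac = 0))

setValidity("MKCounts", function(object) {
  v <- c(object@dn, object@ds, object@pn, object@ps)
  if (any(v < 0)) "all MK counts must be >= 0" else TRUE
})

#' Fitted branch codon model
#'
#' Maximum-likelihood fit of a GY94-style codon model on a fixed tree,
#' either with a single shared omega (one-ratio) or one omega per branch
#' (free-ratio).
#'
#' @slot mode "one_ratio" or "free_ratio".
#' @slot kappa transition/transversion rate ratio.
#' @slot omega named numeric, one entry per branch label (identical values
#'   in one-ratio mode).
#' @slot branchLengths named numeric, expected substitutions per codon.
#' @slot codonFreqs stationary codon frequencies (F3x4), named 61-vector.
#' @slot lnL maximized log-likelihood.
#' @slot converged optimizer convergence flag.
#' @slot nSites number of usable codon columns.
#' @exportClass CodonModelFit
setClass("CodonModelFit",
  representation(mode = "character", kappa = "numeric", omega = "numeric",
                 branchLengths = "numeric", codonFreqs = "numeric",
                 lnL = "numeric", converged = "logical", nSites = "numeric"))

setMethod("show", "OrthologCluster", function(object) {
  cat("OrthologCluster", object@clusterId, "\n")
  cat(" ", length(object@sequences), "species:",
      paste(names(object@sequences), collapse = ", "), "\n")
  cat("  lengths:", paste(Biostrings::width(object@sequences), collapse = ", "), "nt\n")
  if (length(object@goTerms))
    cat("  GO terms:", paste(object@goTerms, collapse = ";"), "\n")
})

setMethod("show", "SpeciesTree", function(object) {
  tr <- object@tree
  cat("SpeciesTree with", length(tr$tip.label), "leaves:",
      paste(tr$tip.label, collapse = ", "), "\n")
  cat("  branches:", paste(branchLabels(object), collapse = " | "), "\n")
})

setMethod("show", "CodonAlignment", function(object) {
  w <- Biostrings::width(object@rows)[1]
  cat("CodonAlignment", object@clusterId, ":",
      length(object@rows), "rows x", w, "columns (",
      w %/% 3L, "codons )\n")
})

setMethod("show", "PolymorphismTable", function(object) {
  d <- object@data
  cat("PolymorphismTable:", nrow(d), "positions,",
      length(unique(d$species)), "species,",
      length(unique(d$cluster_id)), "clusters\n")
})

setMethod("show", "MKCounts", function(object) {
  cat(sprintf("MKCounts: Dn=%.3g Ds=%.3g Pn=%.3g Ps=%.3g (%d codons, %.1f%% no-data positions)\n",
              object@dn, object@ds, object@pn, object@ps,
              as.integer(object@nCodons), 100 * object@noDataFrac))
})

setMethod("show", "CodonModelFit", function(object) {
  cat("CodonModelFit [", object@mode, "] lnL =", format(object@lnL, digits = 10),
      if (!object@converged) "(NOT converged)" else "", "\n")
  cat("  kappa =", signif(object@kappa, 4), "\n")
  om <- signif(object@omega, 4)
  if (object@mode == "one_ratio") {
    cat("  omega =", om[1], "\n")
  } else {
    cat("  omega:\n")
    for (b in names(om)) cat("    ", b, "=", om[b], "\n")
  }
})
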